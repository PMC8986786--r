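# Shared fixtures built in code.

# A loop table in the shape read_loops() returns.
make_loops <- function(chrom1, start1, end1, chrom2, start2, end2,
                       wt1, wt2, kd1, kd2, fdr = 0.001) {
  data.frame(chrom1 = chrom1, start1 = start1, end1 = end1,
             chrom2 = chrom2, start2 = start2, end2 = end2,
             wt_rep1 = wt1, wt_rep2 = wt2, kd_rep1 = kd1, kd_rep2 = kd2,
             fdr = fdr, stringsAsFactors = FALSE)
}

# Six loops, each tripping at most one filter rule; exactly 3 survive.
# Anchors are 10 kb wide; a gap below 10 kb marks a self-ligated pair.
filter_audit_fixture <- function() {
  make_loops(
    chrom1 = "chr1",
    start1 = c(100e3, 200e3, 300e3, 400e3, 500e3, 600e3),
    end1   = c(110e3, 210e3, 310e3, 410e3, 510e3, 610e3),
    chrom2 = "chr1",
    start2 = c(150e3, 215e3, 350e3, 450e3, 550e3, 650e3),
    end2   = c(160e3, 225e3, 360e3, 460e3, 560e3, 660e3),
    #         ok      self    ok      fdr     rep     ok
    wt1 = c(8, 8, 8, 8, 5, 8), wt2 = c(6, 6, 6, 6, 0, 6),
    kd1 = c(9, 9, 9, 9, 9, 9), kd2 = c(7, 7, 7, 7, 7, 7),
    fdr = c(0.001, 0.001, 0.001, 0.02, 0.001, 0.001))
}

# Five genes on a toy chromosome; genes g1 and g2 are wired to satisfy all
# three direct-target criteria, the rest each miss at least one.
target_fixture <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    chrom = "chr1",
    tss = c(10e3, 50e3, 90e3, 130e3, 170e3),
    expr_log2fc = c(2, -1.5, 1.8, 0.1, 2.2),
    expr_fdr = c(0.001, 0.002, 0.003, 0.8, 0.004),
    stringsAsFactors = FALSE)
  # lost STAG2 peaks at promoters of g1, g2, g4, g5 (not g3)
  lost <- data.frame(chrom = "chr1",
                     start = c(9.5e3, 49.5e3, 129.5e3, 169.5e3),
                     end = c(10.5e3, 50.5e3, 130.5e3, 170.5e3))
  # differential loops anchored at promoters of g1, g2, g4 (not g5)
  dl <- make_loops("chr1", c(9e3, 49e3, 129e3), c(11e3, 51e3, 131e3),
                   "chr1", c(300e3, 340e3, 380e3), c(302e3, 342e3, 382e3),
                   10, 10, 40, 40)
  dl$klass <- c("enhanced", "impaired", "enhanced")
  list(genes = genes, lost = lost, diff_loops = dl)
}

# One shared default synthetic bundle per test session (generation is a
# few seconds; many tests only read from it).
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "loopswitch-shared-bundle")
      cache <<- generate_scenario(scenario_config(seed = 20260927L), dir)
    }
    cache
  }
})
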