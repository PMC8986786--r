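test_that("boundary extraction flanks TAD edges and merges shared edges", {
  tads <- intervals("chr1", c(100e3, 500e3), c(500e3, 900e3))
  b <- extract_boundaries(tads, flank = 10000)
  expect_equal(b$start, c(90e3, 490e3, 890e3))
  expect_equal(b$end, c(110e3, 510e3, 910e3))

  one <- extract_boundaries(intervals("chr1", 200e3, 400e3), 10000)
  expect_equal(one$start, c(190e3, 390e3))

  # per-base oracle on a random TAD layout
  set.seed(41)
  for (rep in 1:20) {
    starts <- sort(sample(seq(10e3, 900e3, by = 1e3), 8))
    tads <- intervals("chr1", starts, starts + 5e3)
    b <- extract_boundaries(tads, 3000)
    edges <- c(starts, starts + 5e3)
    raw <- data.frame(chrom = "chr1", start = edges - 3000,
                      end = edges + 3000)
    expect_equal(brute_union_bases(b, 1e6), brute_union_bases(raw, 1e6))
    expect_lte(nrow(b), 2 * nrow(tads))
  }

  # well-separated TADs give exactly 2n boundaries
  wide <- intervals("chr1", c(0, 100e3, 200e3) + 10e3,
                    c(0, 100e3, 200e3) + 50e3)
  expect_equal(nrow(extract_boundaries(wide, 10000)), 6)
  expect_error(extract_boundaries(wide, 0), "flank")

  # clipping at the chromosome start and end
  g <- genome_spec("chr1", 300e3)
  cb <- extract_boundaries(intervals("chr1", 5e3, 298e3), 10000, genome = g)
  expect_equal(cb$start[1], 0)
  expect_equal(cb$end[nrow(cb)], 300e3)
})

test_that("boundary matching separates stable from variable at the tolerance", {
  wt <- intervals("chr1", 490e3, 510e3)
  kd <- intervals("chr1", 495e3, 515e3)
  m <- classify_boundaries(wt, kd, tolerance = 10000)
  expect_equal(m$klass, "stable")
  expect_equal(m$displacement, 5000)

  kd_far <- intervals("chr1", 590e3, 610e3)
  m2 <- classify_boundaries(wt, kd_far, tolerance = 10000)
  expect_setequal(m2$klass, "variable")
  expect_setequal(m2$side, c("wt_only", "kd_only"))
})

test_that("stable-pair count equals exhaustive optimal matching", {
  set.seed(42)
  for (rep in 1:100) {
    nw <- sample(1:6, 1); nk <- sample(1:6, 1)
    wm <- sort(sample(seq(0, 200e3, by = 1e3), nw))
    km <- sort(sample(seq(0, 200e3, by = 1e3), nk))
    wt <- intervals("chr1", wm, wm + 100)
    kd <- intervals("chr1", km, km + 100)
    tol <- sample(c(5e3, 10e3, 20e3), 1)
    m <- classify_boundaries(wt, kd, tol)
    expect_equal(sum(m$klass == "stable"),
                 brute_max_matching(wm + 50, km + 50, tol))
    # stable + wt-side variable partitions the WT set (same for KD)
    expect_equal(sum(m$klass == "stable") + sum(m$side == "wt_only"), nw)
    expect_equal(sum(m$klass == "stable") + sum(m$side == "kd_only"), nk)
  }
})

test_that("TAD change classification covers merges, expansions, shifts", {
  wt <- intervals("chr1", c(0, 400e3), c(400e3, 800e3))
  kd <- intervals("chr1", 0, 800e3)
  ch <- classify_tad_changes(wt, kd)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$klass, "expanded")
  expect_equal(ch$vb_category, "merged")
  expect_equal(ch$n_wt_tads, 2L)

  ch2 <- classify_tad_changes(intervals("chr1", 0, 400e3),
                              intervals("chr1", 0, 450e3))
  expect_equal(ch2$klass, "expanded")
  expect_equal(ch2$size_delta, 50e3)
  # 50-kb outward move overlaps no 10-kb WT boundary region
  expect_equal(ch2$vb_category, "new_boundary")

  # a 15-kb move lands inside no-man's land only if beyond the flank;
  # 15 kb with 10-kb flanks still overlaps the WT boundary region
  ch3 <- classify_tad_changes(intervals("chr1", 0, 400e3),
                              intervals("chr1", 0, 415e3))
  expect_equal(ch3$klass, "expanded")
  expect_equal(ch3$vb_category, "shifted")

  ch4 <- classify_tad_changes(intervals("chr1", 0, 400e3),
                              intervals("chr1", 0, 360e3))
  expect_equal(ch4$klass, "shrinked")
  expect_equal(ch4$size_delta, -40e3)

  ch5 <- classify_tad_changes(intervals("chr1", 0, 400e3),
                              intervals("chr1", 2e3, 398e3))
  expect_equal(ch5$klass, "stable")
})

test_that("planted TAD changes are recovered from the synthetic scenario", {
  b <- shared_bundle()
  ch <- classify_tad_changes(b$wt_tads, b$kd_tads)
  # match each planted change to the call on the same WT TAD
  recall <- function(planted_class, expect_klass, expect_vb = NULL) {
    idx <- which(b$tad_class == planted_class)
    hits <- 0
    for (i in idx) {
      row <- ch[ch$wt_start == b$wt_tads$start[i], , drop = FALSE]
      if (nrow(row) == 1 &&
            row$klass == expect_klass &&
            (is.null(expect_vb) || row$vb_category == expect_vb))
        hits <- hits + 1
    }
    hits / length(idx)
  }
  expect_gte(recall("expanded", "expanded"), 0.9)
  expect_gte(recall("shrinked", "shrinked"), 0.9)
  # merged pairs: the max-overlap constituent carries the call
  mi <- which(b$tad_class == "merged")
  merged_calls <- ch[ch$vb_category == "merged", , drop = FALSE]
  expect_gte(nrow(merged_calls) / b$truth$n_merge_events, 0.9)
  expect_true(all(merged_calls$n_wt_tads >= 2))
})

test_that("TAD size comparison uses the two-sided rank-sum test", {
  set.seed(43)
  lens <- sample(seq(100e3, 400e3, by = 1e3), 200)
  wt <- intervals("chr1", seq_along(lens) * 1e6, seq_along(lens) * 1e6 + lens)
  st <- tad_size_stats(wt, wt)
  expect_gte(st$p_value, 0.99)
  expect_equal(st$median_wt, median(lens))
  expect_equal(unname(st$quantiles_wt[3]), median(lens))

  kd <- intervals("chr1", seq_along(lens) * 1e6,
                  seq_along(lens) * 1e6 + lens + 100e3)
  sh <- tad_size_stats(wt, kd)
  expect_lt(sh$p_value, 1e-6)
  expect_lt(brute_rank_sum_p(lens, lens + 100e3), 1e-6)
  expect_error(tad_size_stats(wt[0, ], kd), "non-empty")
})

test_that("stable boundaries carry stronger cohesin/CTCF signal than variable", {
  b <- shared_bundle()
  mean_at <- function(track, edges) {
    reg <- intervals(b$config$chrom, pmax(edges - 10e3, 0), edges + 10e3)
    p <- signal_metaprofile(reg, track, "scaled_region", n_bins = 1)
    mean(p$profile)
  }
  expect_gt(mean_at(b$track_stag2, b$stable_edges),
            mean_at(b$track_stag2, b$variable_edges))
  expect_gt(mean_at(b$track_ctcf, b$stable_edges),
            mean_at(b$track_ctcf, b$variable_edges))
})
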