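test_that("compute_delta follows the log2 pseudocount definition", {
  expect_equal(compute_delta(4, 8, epsilon = 1e-9), 1.0, tolerance = 1e-6)
  expect_equal(compute_delta(3.7, 3.7, epsilon = 0.5), 0)
  expect_equal(compute_delta(3.7, 3.7, epsilon = 2), 0)
  # wt=0, kd=3 with eps=1: log2(4/1)
  expect_equal(compute_delta(0, 3, epsilon = 1), 2.0)
  expect_error(compute_delta(-1, 2), "non-negative")

  # antisymmetry under condition swap
  set.seed(21)
  wt <- runif(50, 0, 20); kd <- runif(50, 0, 20)
  expect_equal(compute_delta(wt, kd), -compute_delta(kd, wt))
})

test_that("switch classification is the optimal 1-D two-group partition", {
  # exhaustive check of all 2-partitions for minimal within-cluster SS
  d <- c(2.1, 1.9, 0.05, -0.1)
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^4 - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:3)))
    ss <- sum((d[grp] - mean(d[grp]))^2) + sum((d[!grp] - mean(d[!grp]))^2)
    if (ss < best_ss) { best_ss <- ss; best <- grp }
  }
  labels <- classify_switch_sites(d, seed = 1)
  expect_setequal(d[labels == "switch"],
                  d[if (mean(d[best]) > mean(d[!best])) best else !best])
  expect_equal(labels, c("switch", "switch", "non_switch", "non_switch"))

  expect_equal(classify_switch_sites(c(1, 0)), c("switch", "non_switch"))
  expect_error(classify_switch_sites(rep(0.3, 5)), "identical")
  expect_error(classify_switch_sites(0.5), "2 sites")
})

test_that("switch classification is deterministic and order-invariant", {
  set.seed(22)
  d <- c(rnorm(60, 1.5, 0.3), rnorm(90, 0, 0.3))
  l1 <- classify_switch_sites(d, seed = 7)
  l2 <- classify_switch_sites(d, seed = 7)
  expect_identical(l1, l2)
  perm <- sample(length(d))
  expect_identical(classify_switch_sites(d[perm], seed = 7), l1[perm])
})

test_that("planted switch sites are recovered with high accuracy", {
  set.seed(23)
  truth <- rep(c(TRUE, FALSE), c(400, 600))
  d <- ifelse(truth, rnorm(1000, 1.5, 0.3), rnorm(1000, 0, 0.3))
  labels <- classify_switch_sites(d, seed = 1)
  expect_gte(mean((labels == "switch") == truth), 0.95)
})

test_that("degree of switch is the sum of STAG1 and STAG2 deltas", {
  expect_equal(degree_of_switch(1, -1), 0)
  expect_equal(degree_of_switch(3, -2), 1)
  expect_error(degree_of_switch(c(1, 2), c(1, NA)), "missing")
  expect_error(degree_of_switch(1:3, 1:2), "equal length")
})

test_that("mean degree of switch is higher at enhanced- than impaired-loop anchors", {
  b <- shared_bundle()
  st <- b$sites
  D <- degree_of_switch(st$STAG1_delta, st$STAG2_delta)
  anchors <- function(kl) {
    sub <- b$loops[b$loop_class == kl, ]
    rbind(data.frame(chrom = sub$chrom1, start = sub$start1, end = sub$end1),
          data.frame(chrom = sub$chrom2, start = sub$start2, end = sub$end2))
  }
  at_enh <- overlaps_any(st[, c("chrom", "start", "end")], anchors("enhanced"))
  at_imp <- overlaps_any(st[, c("chrom", "start", "end")], anchors("impaired"))
  expect_gt(mean(D[at_enh]), mean(D[at_imp]))
})

test_that("signal metaprofile averages a step track into bins", {
  sites <- intervals("chr1", c(10e3, 40e3), c(12e3, 42e3))
  const <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = 3.5)
  p <- signal_metaprofile(sites, const, "fixed_window", window_bp = 5000,
                          n_bins = 10)
  expect_true(all(p$profile == 3.5))
  expect_equal(p$meta, rep(3.5, 10))

  # single 1-bp spike at a site center lights only the central bin
  spike <- data.frame(chrom = "chr1", start = 11000, end = 11001, value = 9)
  p1 <- signal_metaprofile(sites[1, ], spike, "fixed_window",
                           window_bp = 500, n_bins = 5)
  expect_true(p1$profile[1, 3] > 0)
  expect_equal(p1$profile[1, -3], rep(0, 4))

  # linearity in the track values
  tr <- data.frame(chrom = "chr1", start = seq(0, 9e4, 1e4),
                   end = seq(1e4, 1e5, 1e4), value = 1:10)
  pa <- signal_metaprofile(sites, tr, "fixed_window", 5000, 8)
  tr2 <- tr; tr2$value <- tr$value * 2
  pb <- signal_metaprofile(sites, tr2, "fixed_window", 5000, 8)
  expect_equal(pb$profile, 2 * pa$profile)

  # sites too close to the chromosome edge are dropped with a warning
  g <- genome_spec("chr1", 50e3)
  expect_warning(
    pd <- signal_metaprofile(intervals("chr1", c(1e3, 20e3), c(2e3, 21e3)),
                             const, "fixed_window", 5000, 4, genome = g),
    "dropped")
  expect_equal(pd$kept, 2L)
})

test_that("scaled-region metaprofile spans region plus flanks", {
  sites <- intervals("chr1", 20e3, 40e3)
  tr <- data.frame(chrom = "chr1", start = c(10e3, 20e3, 40e3),
                   end = c(20e3, 40e3, 50e3), value = c(1, 5, 2))
  p <- signal_metaprofile(sites, tr, "scaled_region", n_bins = 4,
                          flank_bp = 10e3)
  # 40-kb span in 4 bins of 10 kb: flank, body, body, flank
  expect_equal(p$profile[1, ], c(1, 5, 5, 2))
})

test_that("permutation enrichment p-values are calibrated and bounded", {
  g <- genome_spec("chr1", 1e5)
  sites <- intervals("chr1", seq(0, 9e4, 1e4), seq(0, 9e4, 1e4) + 500)
  tiling <- intervals("chr1", 0, 1e5)
  e <- permutation_enrichment(sites, tiling, g, n_perm = 50, seed = 3)
  expect_equal(e$observed, 10)
  expect_true(all(e$null_counts == 10))
  expect_equal(e$p_enrich, 1.0)
  expect_gte(e$p_enrich, 1 / 51)
  expect_gte(e$p_enrich + e$p_deplete, 1)

  expect_error(
    permutation_enrichment(intervals("chrX", 0, 10), tiling, g, 10),
    "chromosome")
  expect_error(
    permutation_enrichment(intervals("chr1", 0, 2e5), tiling, g, 10),
    "longer")
})

test_that("permutation p-values are near-uniform under a uniform null", {
  g <- genome_spec("chr1", 1e6)
  feats <- intervals("chr1", seq(0, 990000, by = 5000),
                     seq(0, 990000, by = 5000) + 2000)
  pv <- vapply(1:500, function(r) {
    set.seed(1000 + r)
    st <- floor(runif(100, 0, 1e6 - 400))
    sites <- intervals("chr1", st, st + 400)
    permutation_enrichment(sites, feats, g, n_perm = 199,
                           seed = 2000 + r)$p_enrich
  }, 1)
  expect_gte(mean(pv < 0.05), 0.03)
  expect_lte(mean(pv < 0.05), 0.07)
})

test_that("permutation test detects planted 3x enrichment", {
  g <- genome_spec("chr1", 1e6)
  feats <- intervals("chr1", seq(0, 990000, by = 10000),
                     seq(0, 990000, by = 10000) + 2000)  # 20% coverage
  set.seed(31)
  n <- 150
  inside <- runif(n) < 0.6   # 3x the uniform 20% rate
  fi <- sample(nrow(feats), n, replace = TRUE)
  pos <- ifelse(inside,
                feats$start[fi] + 500,
                floor(runif(n, 0, 1e6 - 400)))
  sites <- intervals("chr1", pos, pos + 400)
  e <- permutation_enrichment(sites, feats, g, n_perm = 1000, seed = 5)
  expect_lte(e$p_enrich, 0.005)
  expect_gt(e$enrichment_ratio, 1.5)
})

test_that("H3K27ac gains concentrate at classified switch sites", {
  b <- shared_bundle()
  labels <- classify_switch_sites(b$sites$STAG1_delta, seed = 1)
  sw <- labels == "switch"
  expect_gt(mean(b$sites$H3K27ac_delta[sw]),
            mean(b$sites$H3K27ac_delta[!sw]))
})
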