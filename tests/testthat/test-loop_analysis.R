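test_that("loop filters drop self-ligated, high-FDR and 5-vs-0 loops", {
  base <- function(...) make_loops("chr1", 100e3, 110e3,
                                   "chr1", 200e3, 210e3, ...)
  expect_equal(nrow(filter_loops(base(8, 6, 9, 7, fdr = 0.02))$loops), 0)
  expect_equal(nrow(filter_loops(base(5, 0, 9, 7))$loops), 0)
  expect_equal(nrow(filter_loops(base(5, 1, 9, 7))$loops), 1)
  expect_equal(nrow(filter_loops(base(4, 0, 9, 7))$loops), 1)  # 4 < strong

  fx <- filter_audit_fixture()
  res <- filter_loops(fx)
  expect_equal(nrow(res$loops), 3)
  expect_equal(res$loops$start1, c(100e3, 300e3, 600e3))
  expect_equal(res$removed$rule,
               c("self_ligated", "caller_fdr", "strong_vs_zero_replicate"))

  # idempotent and order preserving
  again <- filter_loops(res$loops)
  expect_equal(again$loops, res$loops)
})

test_that("differential loops match a per-loop quasi-Poisson GLM oracle", {
  df <- make_loops("chr1", c(1e5, 3e5), c(1.1e5, 3.1e5),
                   "chr1", c(2e5, 5e5), c(2.1e5, 5.1e5),
                   wt1 = c(10, 30), wt2 = c(10, 25),
                   kd1 = c(40, 28), kd2 = c(40, 33))
  out <- differential_loops(df, fdr_threshold = 0.05)
  lib <- colSums(df[, c("wt_rep1", "wt_rep2", "kd_rep1", "kd_rep2")])
  for (i in 1:2) {
    y <- unlist(df[i, c("wt_rep1", "wt_rep2", "kd_rep1", "kd_rep2")])
    g <- data.frame(y = y, cond = factor(c("wt", "wt", "kd", "kd"),
                                         levels = c("wt", "kd")),
                    off = log(lib))
    fit <- stats::glm(y ~ cond + offset(off), family = stats::quasipoisson(),
                      data = g)
    expect_equal(out$log2fc[i], unname(stats::coef(fit)[2]) / log(2),
                 tolerance = 1e-6)
    # the Wald z agrees once the same pooled dispersion is plugged in
    se_glm <- summary(fit, dispersion = out$dispersion[1])$coefficients[2, 2]
    z_ours <- stats::qnorm(out$p_value[i] / 2, lower.tail = FALSE)
    expect_equal(z_ours, abs(stats::coef(fit)[2]) / se_glm,
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("differential classification follows fold change and threshold", {
  same <- make_loops("chr1", 1e5, 1.1e5, "chr1", 2e5, 2.1e5,
                     10, 12, 10, 12)
  o <- differential_loops(same)
  expect_equal(o$log2fc, 0)
  expect_equal(o$klass, "unchanged")

  # equal library sizes via a balancing second loop
  df <- make_loops("chr1", c(1e5, 4e5), c(1.1e5, 4.1e5),
                   "chr1", c(2e5, 6e5), c(2.1e5, 6.1e5),
                   wt1 = c(10, 40), wt2 = c(10, 40),
                   kd1 = c(40, 10), kd2 = c(40, 10))
  o2 <- differential_loops(df, fdr_threshold = 0.05)
  expect_equal(o2$log2fc, c(2, -2))
  expect_equal(o2$klass, c("enhanced", "impaired"))

  zero <- make_loops("chr1", c(1e5, 4e5), c(1.1e5, 4.1e5),
                     "chr1", c(2e5, 6e5), c(2.1e5, 6.1e5),
                     wt1 = c(0, 10), wt2 = c(0, 10),
                     kd1 = c(0, 10), kd2 = c(0, 10))
  oz <- differential_loops(zero)
  expect_equal(oz$p_value[1], 1)
  expect_equal(oz$log2fc[1], 0)
  expect_equal(oz$klass[1], "unchanged")
})

test_that("swapping conditions negates every log2 fold change", {
  set.seed(61)
  n <- 100
  df <- make_loops("chr1", seq_len(n) * 1e4, seq_len(n) * 1e4 + 5e3,
                   "chr1", seq_len(n) * 1e4 + 5e4, seq_len(n) * 1e4 + 5.5e4,
                   rpois(n, 20), rpois(n, 20),
                   rpois(n, 30), rpois(n, 30))
  a <- differential_loops(df)
  sw <- df
  sw[, c("wt_rep1", "wt_rep2", "kd_rep1", "kd_rep2")] <-
    sw[, c("kd_rep1", "kd_rep2", "wt_rep1", "wt_rep2")]
  bsw <- differential_loops(sw)
  expect_equal(bsw$log2fc, -a$log2fc)
  expect_equal(bsw$p_value, a$p_value)
  expect_equal(sum(bsw$klass == "enhanced"), sum(a$klass == "impaired"))
})

test_that("anchor classification matches the all-pairs oracle", {
  prom <- intervals("chr1", c(10e3, 60e3), c(12e3, 62e3))
  enh <- intervals("chr1", c(30e3, 60.5e3), c(32e3, 61.5e3))
  pe <- make_loops("chr1", 10.5e3, 11.5e3, "chr1", 30.5e3, 31.5e3,
                   1, 1, 1, 1)
  expect_equal(classify_loop_anchors(pe, prom, enh), "PE")
  # an anchor on both annotations takes the promoter label
  both <- make_loops("chr1", 60.8e3, 61.2e3, "chr1", 10.5e3, 11.5e3,
                     1, 1, 1, 1)
  expect_equal(classify_loop_anchors(both, prom, enh), "PP")

  set.seed(62)
  for (rep in 1:30) {
    pr <- random_intervals(5, chroms = "chr1")
    en <- random_intervals(5, chroms = "chr1")
    a <- random_intervals(8, chroms = "chr1")
    b <- random_intervals(8, chroms = "chr1")
    lp <- make_loops(a$chrom, a$start, a$end, b$chrom, b$start, b$end,
                     1, 1, 1, 1)
    got <- classify_loop_anchors(lp, pr, en)
    want <- vapply(seq_len(nrow(lp)),
                   function(i) brute_anchor_type(lp[i, ], pr, en), "")
    expect_equal(got, want)
  }
})

test_that("loop TAD relation uses anchor midpoints", {
  tads <- intervals("chr1", c(0, 500e3), c(500e3, 1e6))
  w <- make_loops("chr1", 100e3, 110e3, "chr1", 300e3, 310e3, 1, 1, 1, 1)
  expect_equal(loops_vs_tads(w, tads), "within")
  a <- make_loops("chr1", 400e3, 410e3, "chr1", 600e3, 610e3, 1, 1, 1, 1)
  expect_equal(loops_vs_tads(a, tads), "across")
  o <- make_loops("chr1", 100e3, 110e3, "chr1", 1.2e6, 1.21e6, 1, 1, 1, 1)
  expect_equal(loops_vs_tads(o, tads), "outside")

  # planted 80% within recovered exactly: deterministic geometry
  n <- 50
  within <- seq_len(n) <= 40
  a1 <- ifelse(within, 100e3, 450e3)
  a2 <- ifelse(within, 200e3, 550e3)
  lp <- make_loops("chr1", a1, a1 + 1e4, "chr1", a2, a2 + 1e4, 1, 1, 1, 1)
  rel <- loops_vs_tads(lp, tads)
  expect_equal(mean(rel == "within"), 0.8)
  set.seed(63)
  for (rep in 1:20) {
    td <- intervals("chr1", c(0, 3000, 7000), c(2500, 6500, 9500))
    x <- random_intervals(10, chroms = "chr1", max_pos = 9500, max_len = 300)
    y <- random_intervals(10, chroms = "chr1", max_pos = 9500, max_len = 300)
    lp <- canonicalize_loops(make_loops(x$chrom, x$start, x$end,
                                        y$chrom, y$start, y$end, 1, 1, 1, 1))
    got <- loops_vs_tads(lp, td)
    want <- vapply(seq_len(nrow(lp)),
                   function(i) brute_tad_relation(lp[i, ], td), "")
    expect_equal(got, want)
  }
})

test_that("loop length comparison reports medians and rank-sum p", {
  mk <- function(d, n) {
    s <- seq_len(n) * 1e4
    make_loops("chr1", s, s + 1e3, "chr1", s + d, s + d + 1e3, 1, 1, 1, 1)
  }
  d0 <- seq(3e4, 8e4, length.out = 50)
  same <- loop_length_stats(mk(d0, 50), mk(d0, 50))
  expect_gte(same$p_value, 0.99)

  set.seed(64)
  de <- round(runif(300, 8e4, 1.6e5)); di <- round(runif(300, 4e4, 8e4))
  s <- seq_len(300) * 1e4
  enh <- make_loops("chr1", s, s + 1e3, "chr1", s + de, s + de + 1e3,
                    1, 1, 1, 1)
  imp <- make_loops("chr1", s, s + 1e3, "chr1", s + di, s + di + 1e3,
                    1, 1, 1, 1)
  st <- loop_length_stats(enh, imp)
  expect_lt(st$p_value, 1e-10)
  expect_lt(brute_rank_sum_p(loop_lengths(enh), loop_lengths(imp)), 1e-10)
  expect_equal(st$median_enhanced, median(loop_lengths(enh)))
  expect_error(loop_length_stats(enh[0, ], imp), "non-empty")
})
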