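# Brute-force oracles, deliberately independent of the package internals:
# everything here works per base pair or per pair of items.

# per-base union membership on a small domain
brute_union_bases <- function(df, domain_max) {
  covered <- rep(FALSE, domain_max)
  for (i in seq_len(nrow(df))) {
    if (df$start[i] < domain_max) {
      hi <- min(df$end[i], domain_max)
      if (df$start[i] + 1 <= hi) covered[(df$start[i] + 1):hi] <- TRUE
    }
  }
  covered
}

brute_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# number of query intervals overlapping any subject (all-pairs)
brute_count_overlapping <- function(query, subject) {
  n <- 0L
  for (i in seq_len(nrow(query))) {
    hit <- FALSE
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
            brute_overlap(query$start[i], query$end[i],
                          subject$start[j], subject$end[j])) {
        hit <- TRUE
        break
      }
    }
    n <- n + hit
  }
  n
}

# transitive closure of the pairwise stitch relation (gap <= d)
brute_stitch_groups <- function(peaks, d) {
  n <- nrow(peaks)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gap <- max(peaks$start[j] - peaks$end[i], peaks$start[i] - peaks$end[j])
    adj[i, j] <- peaks$chrom[i] == peaks$chrom[j] && gap <= d
  }
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && grp[j] != grp[i]) {
        g <- min(grp[i], grp[j])
        grp[grp == grp[i] | grp == grp[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# maximum number of WT/KD midpoint pairs with |wm - km| <= tol
# (exhaustive recursion; instances <= 12)
brute_max_matching <- function(wm, km, tol) {
  rec <- function(i, used) {
    if (i > length(wm)) return(0L)
    best <- rec(i + 1L, used)   # leave wm[i] unmatched
    for (j in seq_along(km)) {
      if (!used[j] && abs(wm[i] - km[j]) <= tol) {
        u <- used; u[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, u))
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(km)))
}

# independent Mann-Whitney: exact U statistic + normal approximation
brute_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  2 * stats::pnorm(-abs(u - mu) / sigma)
}

# anchor labels by all-pairs overlap with the tie rule promoter > enhancer
brute_anchor_type <- function(loop_row, promoters, enhancers) {
  lab <- function(s, e, ch) {
    a <- data.frame(chrom = ch, start = s, end = e)
    if (brute_count_overlapping(a, promoters) > 0) return("promoter")
    if (brute_count_overlapping(a, enhancers) > 0) return("enhancer")
    "other"
  }
  l1 <- lab(loop_row$start1, loop_row$end1, loop_row$chrom1)
  l2 <- lab(loop_row$start2, loop_row$end2, loop_row$chrom2)
  if (l1 == "other" || l2 == "other") return("other")
  if (l1 == "promoter" && l2 == "promoter") return("PP")
  if (l1 == "enhancer" && l2 == "enhancer") return("EE")
  "PE"
}

brute_tad_relation <- function(loop_row, tads) {
  find <- function(ch, pos) {
    for (j in seq_len(nrow(tads))) {
      if (tads$chrom[j] == ch && pos >= tads$start[j] && pos < tads$end[j])
        return(j)
    }
    NA_integer_
  }
  t1 <- find(loop_row$chrom1, (loop_row$start1 + loop_row$end1) / 2)
  t2 <- find(loop_row$chrom2, (loop_row$start2 + loop_row$end2) / 2)
  if (is.na(t1) || is.na(t2)) return("outside")
  if (t1 == t2) "within" else "across"
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 10000, max_len = 500) {
  start <- floor(stats::runif(n, 0, max_pos - max_len))
  len <- ceiling(stats::runif(n, 1, max_len))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}
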