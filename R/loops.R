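.loop_count_cols <- function(df) {
  list(wt = grep("^wt_rep[0-9]+$", names(df), value = TRUE),
       kd = grep("^kd_rep[0-9]+$", names(df), value = TRUE))
}

#' Loop anchor-midpoint separation in bp
#' @param df loop data.frame.
#' @return numeric vector of distances between anchor midpoints.
#' @export
loop_lengths <- function(df) {
  abs((df$start2 + df$end2) / 2 - (df$start1 + df$end1) / 2)
}

#' Filter HiChIP loops
#'
#' Applies the standard pre-test filters: (a) self-ligated loops, i.e.
#' anchors overlapping or separated by a gap smaller than one anchor width;
#' (b) loops whose caller FDR exceeds \code{fdr_max}; (c) loops supported
#' strongly (>= \code{strong_min} reads) in one replicate of a condition
#' but absent (exactly 0 reads) in another replicate of the same condition.
#' Order is preserved; the filter is idempotent.
#'
#' @param df loop data.frame (see [read_loops()]).
#' @param fdr_max caller-FDR ceiling, default 0.01.
#' @param strong_min read count that counts as "strong", default 5.
#' @return list with \code{loops} (survivors) and \code{removed} (data.frame
#'   of dropped rows with the rule that removed each, first rule wins).
#' @export
filter_loops <- function(df, fdr_max = 0.01, strong_min = 5) {
  cc <- .loop_count_cols(df)
  if (length(cc$wt) < 2 || length(cc$kd) < 2)
    warning("fewer than 2 replicates per condition; replicate rule skipped")
  anchor_w <- pmax(df$end1 - df$start1, df$end2 - df$start2)
  gap <- df$start2 - df$end1
  self_lig <- df$chrom1 == df$chrom2 & gap < anchor_w
  bad_fdr <- df$fdr > fdr_max
  strong_vs_zero <- function(cols) {
    if (length(cols) < 2) return(rep(FALSE, nrow(df)))
    m <- as.matrix(df[, cols, drop = FALSE])
    apply(m, 1, function(x) any(x >= strong_min) && any(x == 0))
  }
  rep_rule <- strong_vs_zero(cc$wt) | strong_vs_zero(cc$kd)
  rule <- rep(NA_character_, nrow(df))
  rule[rep_rule] <- "strong_vs_zero_replicate"
  rule[bad_fdr] <- "caller_fdr"
  rule[self_lig] <- "self_ligated"
  keep <- is.na(rule)
  removed <- df[!keep, , drop = FALSE]
  removed$rule <- rule[!keep]
  list(loops = df[keep, , drop = FALSE], removed = removed)
}

# Closed-form per-loop two-group quasi-Poisson GLM with log library-size
# offsets. For count ~ condition with offset log(lib), the MLE fitted rate
# per group is (group total count)/(group total lib), the condition
# coefficient is the log rate ratio, and the Wald variance is
# phi * (1/T_wt + 1/T_kd) with T the group total counts. Matches
# stats::glm(family = quasipoisson) loop by loop, but vectorized. The
# over-dispersion phi is a single Pearson estimate pooled across all loops
# (residual sum over residual df, floored at 1): with two replicates per
# condition, per-loop 2-df dispersion estimates are too unstable to keep
# the FDR under control.
.quasi_poisson_test <- function(W, K, lib_w, lib_k, dispersion_floor = 1) {
  Tw <- rowSums(W); Tk <- rowSums(K)
  Lw <- sum(lib_w); Lk <- sum(lib_k)
  all_zero <- Tw + Tk == 0
  # Haldane-style half-count when one group is empty
  adj <- (Tw == 0 | Tk == 0) & !all_zero
  Tw_a <- Tw + 0.5 * adj
  Tk_a <- Tk + 0.5 * adj
  beta <- log(Tk_a / Lk) - log(Tw_a / Lw)
  mu_w <- (Tw / Lw) %o% lib_w
  mu_k <- (Tk / Lk) %o% lib_k
  pear <- rowSums((W - mu_w)^2 / ifelse(mu_w > 0, mu_w, NA), na.rm = TRUE) +
    rowSums((K - mu_k)^2 / ifelse(mu_k > 0, mu_k, NA), na.rm = TRUE)
  dfree <- (ncol(W) + ncol(K) - 2) * sum(!all_zero)
  phi <- max(sum(pear, na.rm = TRUE) / dfree, dispersion_floor)
  se <- sqrt(phi * (1 / Tw_a + 1 / Tk_a))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[all_zero] <- 1
  beta[all_zero] <- 0
  data.frame(log2fc = beta / log(2), p_value = p, dispersion = phi)
}

#' Differential loop calling between conditions
#'
#' Fits, per loop, supporting-read count ~ condition as an over-dispersed
#' (quasi-)Poisson generalized linear model with a log library-size offset,
#' library size being each replicate's total filtered read support. The
#' Pearson-residual over-dispersion is pooled across loops and floored at 1
#' (never under-dispersed); significance is a Wald test on the condition
#' coefficient, corrected across loops by Benjamini-Hochberg. Loops at
#' FDR < \code{fdr_threshold} are classed \code{enhanced} (stronger in KD)
#' or \code{impaired} (weaker in KD) by the sign of the fold change.
#'
#' @param df loop data.frame with >= 2 replicate count columns per
#'   condition.
#' @param fdr_threshold BH-FDR cutoff for calling a loop differential,
#'   default 0.01.
#' @param lib_sizes optional named numeric vector of library sizes per
#'   count column; defaults to the column totals of \code{df}.
#' @return \code{df} with added columns log2fc, p_value, fdr, klass.
#' @export
differential_loops <- function(df, fdr_threshold = 0.01, lib_sizes = NULL) {
  cc <- .loop_count_cols(df)
  if (length(cc$wt) < 2 || length(cc$kd) < 2)
    stop("need >= 2 replicates per condition")
  W <- as.matrix(df[, cc$wt, drop = FALSE])
  K <- as.matrix(df[, cc$kd, drop = FALSE])
  if (is.null(lib_sizes)) {
    lib_w <- colSums(W); lib_k <- colSums(K)
  } else {
    lib_w <- lib_sizes[cc$wt]; lib_k <- lib_sizes[cc$kd]
  }
  if (any(c(lib_w, lib_k) <= 0)) stop("library sizes must be > 0")
  res <- .quasi_poisson_test(W, K, lib_w, lib_k)
  df$log2fc <- res$log2fc
  df$p_value <- res$p_value
  df$dispersion <- res$dispersion
  df$fdr <- stats::p.adjust(res$p_value, method = "BH")
  df$klass <- ifelse(df$fdr < fdr_threshold & df$log2fc > 0, "enhanced",
                     ifelse(df$fdr < fdr_threshold & df$log2fc < 0,
                            "impaired", "unchanged"))
  df
}

.anchor_label <- function(anch, promoters, enhancers) {
  on_p <- overlaps_any(anch, promoters)
  on_e <- overlaps_any(anch, enhancers)
  ifelse(on_p, "promoter", ifelse(on_e, "enhancer", "other"))
}

#' Classify loops as PP / PE / EE by anchor annotation
#'
#' Each anchor is labeled promoter if it overlaps any promoter (promoter
#' wins when an anchor overlaps both annotations), else enhancer, else
#' other; a loop with any "other" anchor is classed other.
#'
#' @param df loop data.frame.
#' @param promoters,enhancers interval data.frames.
#' @return character vector in \code{PP, PE, EE, other} along rows of
#'   \code{df}.
#' @export
classify_loop_anchors <- function(df, promoters, enhancers) {
  if (nrow(df) == 0) return(character(0))
  a1 <- data.frame(chrom = df$chrom1, start = df$start1, end = df$end1)
  a2 <- data.frame(chrom = df$chrom2, start = df$start2, end = df$end2)
  l1 <- .anchor_label(a1, promoters, enhancers)
  l2 <- .anchor_label(a2, promoters, enhancers)
  ifelse(l1 == "other" | l2 == "other", "other",
         ifelse(l1 == "promoter" & l2 == "promoter", "PP",
                ifelse(l1 == "enhancer" & l2 == "enhancer", "EE", "PE")))
}

#' Classify loops relative to TADs
#'
#' A loop is \code{within} a TAD if both anchor midpoints fall in the same
#' TAD, \code{across} if they fall in different TADs, and \code{outside} if
#' either midpoint is in no TAD.
#'
#' @param df loop data.frame.
#' @param tads TAD interval data.frame.
#' @return character vector in \code{within, across, outside}.
#' @export
loops_vs_tads <- function(df, tads) {
  if (nrow(df) == 0) return(character(0))
  tad_of <- function(chrom, pos) {
    idx <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      t <- which(tads$chrom == ch)
      if (length(t) == 0) next
      hit <- outer(pos[sel], tads$start[t], ">=") &
        outer(pos[sel], tads$end[t], "<")
      w <- apply(hit, 1, function(x) if (any(x)) t[which(x)[1]] else NA)
      idx[sel] <- w
    }
    idx
  }
  m1 <- (df$start1 + df$end1) / 2
  m2 <- (df$start2 + df$end2) / 2
  t1 <- tad_of(df$chrom1, m1)
  t2 <- tad_of(df$chrom2, m2)
  ifelse(is.na(t1) | is.na(t2), "outside",
         ifelse(t1 == t2 & df$chrom1 == df$chrom2, "within", "across"))
}

#' Loop length comparison between enhanced and impaired classes
#'
#' @param enhanced,impaired loop data.frames (non-empty).
#' @return list with medians and the two-sided Mann-Whitney p-value on
#'   anchor-midpoint separations.
#' @export
loop_length_stats <- function(enhanced, impaired) {
  if (nrow(enhanced) == 0 || nrow(impaired) == 0)
    stop("both loop classes must be non-empty")
  le <- loop_lengths(enhanced)
  li <- loop_lengths(impaired)
  list(n_enhanced = length(le), n_impaired = length(li),
       median_enhanced = stats::median(le), median_impaired = stats::median(li),
       p_value = stats::wilcox.test(le, li,
                                    alternative = "two.sided")$p.value)
}
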