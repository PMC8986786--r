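#' Extract merged TAD boundary regions
#'
#' Each TAD contributes two boundary regions, its left and right edge
#' extended by \code{flank} bp in both directions. Overlapping or touching
#' regions (e.g. the shared edge of adjacent TADs) are merged into one big
#' boundary. Regions are clipped to [0, chrom length) when a genome spec is
#' given.
#'
#' @param tads interval data.frame of TAD calls (per chromosome sorted,
#'   non-overlapping).
#' @param flank half-width of a boundary region in bp (> 0), default 10000.
#' @param genome optional [genome_spec()] used for clipping.
#' @return interval data.frame of merged boundary regions.
#' @export
extract_boundaries <- function(tads, flank = 10000, genome = NULL) {
  if (flank <= 0) stop("flank must be > 0")
  validate_intervals(tads)
  edges <- data.frame(chrom = rep(tads$chrom, 2),
                      pos = c(tads$start, tads$end))
  b <- data.frame(chrom = edges$chrom,
                  start = pmax(edges$pos - flank, 0),
                  end = edges$pos + flank,
                  stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    clen <- genome$length[match(b$chrom, genome$chrom)]
    b$end <- pmin(b$end, clen)
    b <- b[b$start < b$end, , drop = FALSE]
  }
  merge_intervals(b)
}

#' Match WT and KD boundaries and classify stable vs variable
#'
#' Boundaries whose midpoints lie within \code{tolerance} bp of a partner in
#' the other condition are stable pairs; unmatched boundaries on either side
#' are variable. Matching is a per-chromosome greedy sweep in genomic order
#' (each WT boundary takes the leftmost unmatched KD midpoint within
#' tolerance), which attains the maximum number of stable pairs for points
#' on a line and is deterministic with leftmost tie-breaks. For variable
#' boundary reporting, the start site refers to WT and the end site to KD.
#'
#' @param wt,kd boundary interval data.frames (from [extract_boundaries()]).
#' @param tolerance midpoint distance in bp for calling a pair stable,
#'   default 10000.
#' @return data.frame with one row per match or unmatched boundary:
#'   condition-wise coordinates (NA when absent), \code{klass}
#'   (stable/variable), \code{side} (both/wt_only/kd_only) and signed
#'   \code{displacement} (KD midpoint - WT midpoint) for stable pairs.
#' @export
classify_boundaries <- function(wt, kd, tolerance = 10000) {
  validate_intervals(wt); validate_intervals(kd)
  res <- list()
  for (ch in sort(unique(c(wt$chrom, kd$chrom)))) {
    w <- wt[wt$chrom == ch, , drop = FALSE]
    k <- kd[kd$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    k <- k[order(k$start), , drop = FALSE]
    wm <- interval_midpoints(w); km <- interval_midpoints(k)
    match_k <- rep(NA_integer_, nrow(w))
    j <- 1L
    for (i in seq_len(nrow(w))) {
      while (j <= length(km) && km[j] < wm[i] - tolerance) j <- j + 1L
      if (j <= length(km) && abs(km[j] - wm[i]) <= tolerance) {
        match_k[i] <- j
        j <- j + 1L
      }
    }
    matched <- !is.na(match_k)
    if (any(matched)) {
      mi <- which(matched)
      res[[length(res) + 1]] <- data.frame(
        chrom = ch,
        wt_start = w$start[mi], wt_end = w$end[mi],
        kd_start = k$start[match_k[mi]], kd_end = k$end[match_k[mi]],
        klass = "stable", side = "both",
        displacement = km[match_k[mi]] - wm[mi],
        stringsAsFactors = FALSE)
    }
    if (any(!matched)) {
      mi <- which(!matched)
      res[[length(res) + 1]] <- data.frame(
        chrom = ch,
        wt_start = w$start[mi], wt_end = w$end[mi],
        kd_start = NA_real_, kd_end = NA_real_,
        klass = "variable", side = "wt_only",
        displacement = NA_real_, stringsAsFactors = FALSE)
    }
    un_k <- setdiff(seq_len(nrow(k)), match_k[matched])
    if (length(un_k) > 0) {
      res[[length(res) + 1]] <- data.frame(
        chrom = ch,
        wt_start = NA_real_, wt_end = NA_real_,
        kd_start = k$start[un_k], kd_end = k$end[un_k],
        klass = "variable", side = "kd_only",
        displacement = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify per-TAD changes between conditions
#'
#' Each KD TAD is matched to WT TADs by overlap. A KD TAD covering >=
#' \code{merge_coverage} of each of two or more WT TADs is a merge of
#' neighboring TADs; otherwise it is paired with the WT TAD of maximal
#' overlap. Pairs with both boundary displacements within \code{tolerance}
#' are stable; a boundary moved outward beyond tolerance makes the TAD
#' expanded, inward shrinked (mixed movements classify by the sign of the
#' size change). Variable changes are subcategorized: \code{merged} as
#' above; \code{new_boundary} when a moved KD boundary region overlaps no
#' WT boundary region; otherwise \code{shifted}.
#'
#' @param wt,kd TAD interval data.frames.
#' @param tolerance boundary-displacement tolerance in bp, default 10000.
#' @param flank boundary-region half-width used for the new/shifted rule,
#'   default 10000.
#' @param merge_coverage minimum fraction of each constituent WT TAD a KD
#'   TAD must cover to be called merged, default 0.8.
#' @return data.frame, one row per KD TAD with a WT counterpart: matched WT
#'   coordinates, \code{klass} (stable/expanded/shrinked), \code{vb_category}
#'   (none/new_boundary/merged/shifted), \code{n_wt_tads},
#'   \code{size_delta} (KD length - matched WT length).
#' @export
classify_tad_changes <- function(wt, kd, tolerance = 10000, flank = 10000,
                                 merge_coverage = 0.8) {
  validate_intervals(wt); validate_intervals(kd)
  wt_bounds <- extract_boundaries(wt, flank)
  rows <- list()
  for (ch in sort(unique(kd$chrom))) {
    w <- wt[wt$chrom == ch, , drop = FALSE]
    k <- kd[kd$chrom == ch, , drop = FALSE]
    if (nrow(w) == 0 || nrow(k) == 0) next
    for (i in seq_len(nrow(k))) {
      ov <- pmin(k$end[i], w$end) - pmax(k$start[i], w$start)
      ov[ov < 0] <- 0
      if (all(ov == 0)) next  # no WT counterpart
      cov_frac <- ov / (w$end - w$start)
      constituents <- which(cov_frac >= merge_coverage)
      is_merge <- length(constituents) >= 2
      j <- which.max(ov)  # max-overlap WT TAD anchors the boundary test
      dl <- k$start[i] - w$start[j]
      dr <- k$end[i] - w$end[j]
      size_delta <- (k$end[i] - k$start[i]) - (w$end[j] - w$start[j])
      outward <- (dl < -tolerance) || (dr > tolerance)
      inward <- (dl > tolerance) || (dr < -tolerance)
      if (!outward && !inward) {
        klass <- "stable"; vb <- "none"
      } else {
        klass <- if (outward && !inward) "expanded"
        else if (inward && !outward) "shrinked"
        else if (size_delta > 0) "expanded" else "shrinked"
        if (is_merge) {
          vb <- "merged"
        } else {
          # regions around the moved KD boundaries vs WT boundary regions
          moved <- numeric(0)
          if (abs(dl) > tolerance) moved <- c(moved, k$start[i])
          if (abs(dr) > tolerance) moved <- c(moved, k$end[i])
          mb <- data.frame(chrom = ch,
                           start = pmax(moved - flank, 0),
                           end = moved + flank)
          vb <- if (count_overlapping(mb, wt_bounds) == 0) "new_boundary"
          else "shifted"
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, kd_start = k$start[i], kd_end = k$end[i],
        wt_start = w$start[j], wt_end = w$end[j],
        n_wt_tads = max(1L, length(constituents)),
        klass = klass, vb_category = vb, size_delta = size_delta,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' TAD size comparison between conditions
#'
#' @param wt,kd TAD interval data.frames (non-empty).
#' @return list with n_wt, n_kd, quantiles (10/25/50/75/90th percentile of
#'   lengths per condition), medians and the two-sided Mann-Whitney
#'   (Wilcoxon rank-sum) p-value.
#' @export
tad_size_stats <- function(wt, kd) {
  if (nrow(wt) == 0 || nrow(kd) == 0) stop("TAD sets must be non-empty")
  lw <- wt$end - wt$start
  lk <- kd$end - kd$start
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  p <- stats::wilcox.test(lw, lk, alternative = "two.sided")$p.value
  list(n_wt = length(lw), n_kd = length(lk),
       quantiles_wt = stats::quantile(lw, qs),
       quantiles_kd = stats::quantile(lk, qs),
       median_wt = stats::median(lw), median_kd = stats::median(lk),
       p_value = p)
}
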