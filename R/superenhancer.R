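#' Stitch H3K27ac peaks into enhancer regions
#'
#' Peaks whose edge-to-edge gap is at most \code{stitch_distance} are
#' transitively grouped; each stitched region spans its constituents and
#' carries their summed signal.
#'
#' @param peaks interval data.frame with non-negative \code{score} signal.
#' @param stitch_distance maximum inter-peak gap in bp, default 12500.
#' @return data.frame of stitched enhancers: chrom, start, end,
#'   n_constituents, total_signal.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500) {
  validate_intervals(peaks)
  if (any(is.na(peaks$score)) || any(peaks$score < 0))
    stop("peaks need non-negative signal scores")
  out <- list()
  for (ch in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    # running max end: overlapping peaks keep the chain open
    reach <- cummax(p$end)
    grp <- cumsum(c(1, (p$start[-1] - reach[-nrow(p)]) > stitch_distance))
    out[[ch]] <- data.frame(
      chrom = ch,
      start = tapply(p$start, grp, min),
      end = tapply(p$end, grp, max),
      n_constituents = as.integer(table(grp)),
      total_signal = tapply(p$score, grp, sum),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call super-enhancers by the rank-signal slope rule
#'
#' Stitched enhancers are sorted by total signal; with both the rank axis
#' and the signal axis min-max rescaled to [0, 1], the cutoff is the
#' tangency point where the discrete slope of the ascending curve passes 1
#' (the point maximizing scaled rank minus scaled signal; ties take the
#' lowest-signal point). Regions with signal strictly above the cutoff are
#' super-enhancers, so non-constant inputs always yield at least one.
#'
#' @param stitched data.frame from [stitch_peaks()].
#' @return same data.frame with added \code{rank} (1 = highest signal) and
#'   logical \code{is_super}.
#' @export
call_superenhancers <- function(stitched) {
  n <- nrow(stitched)
  if (n < 2) stop("need >= 2 stitched enhancers")
  s <- stitched$total_signal
  if (length(unique(s)) == 1)
    stop("all signals identical; slope rule is undefined")
  ord <- order(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s[ord] - min(s)) / (max(s) - min(s))
  cut_idx <- which.max(x - y)          # first index on ties = lowest signal
  cutoff <- s[ord][cut_idx]
  stitched$rank <- as.integer(rank(-s, ties.method = "first"))
  stitched$is_super <- s > cutoff
  stitched
}

#' Compare super-enhancer sets between conditions
#'
#' A KD super-enhancer is \code{maintained} when it reciprocally overlaps a
#' WT super-enhancer by at least \code{min_overlap_fraction} of the shorter
#' region; KD-only regions are \code{gained}, WT-only \code{lost}.
#'
#' @param wt,kd data.frames from [call_superenhancers()].
#' @param min_overlap_fraction overlap fraction of the shorter region,
#'   default 0.5.
#' @return list with counts gained/lost/maintained and the region subsets.
#' @export
compare_superenhancers <- function(wt, kd, min_overlap_fraction = 0.5) {
  ws <- wt[wt$is_super, , drop = FALSE]
  ks <- kd[kd$is_super, , drop = FALSE]
  matched_kd <- rep(FALSE, nrow(ks))
  matched_wt <- rep(FALSE, nrow(ws))
  for (i in seq_len(nrow(ks))) {
    same <- which(ws$chrom == ks$chrom[i])
    if (length(same) == 0) next
    ov <- pmin(ks$end[i], ws$end[same]) - pmax(ks$start[i], ws$start[same])
    shorter <- pmin(ks$end[i] - ks$start[i],
                    ws$end[same] - ws$start[same])
    hit <- ov / shorter >= min_overlap_fraction
    if (any(hit)) {
      matched_kd[i] <- TRUE
      matched_wt[same[hit]] <- TRUE
    }
  }
  list(n_gained = sum(!matched_kd),
       n_lost = sum(!matched_wt),
       n_maintained = sum(matched_kd),
       n_maintained_wt = sum(matched_wt),
       gained = ks[!matched_kd, , drop = FALSE],
       lost = ws[!matched_wt, , drop = FALSE],
       maintained = ks[matched_kd, , drop = FALSE])
}
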