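# Average value of a step-function track over arbitrary query windows.
# Uncovered bases contribute 0. Windows may be fractional (scaled mode).
.track_window_means <- function(track, chrom, starts, ends) {
  out <- numeric(length(starts))
  tdf <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tdf) == 0) return(out)
  qir <- IRanges::IRanges(start = floor(starts) + 1L,
                          end = pmax(ceiling(ends), floor(starts) + 1L))
  tir <- IRanges::IRanges(start = tdf$start + 1L, end = tdf$end)
  ov <- IRanges::findOverlaps(qir, tir)
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    lo <- pmax(starts[qh], tdf$start[sh])
    hi <- pmin(ends[qh], tdf$end[sh])
    w <- pmax(hi - lo, 0)
    sums <- tapply(w * tdf$value[sh], qh, sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out / (ends - starts)
}

#' Signal metaprofile over a set of regions
#'
#' Computes a sites-by-bins matrix of mean track signal, either in fixed
#' windows around site centers (ChIP metaplots at boundaries/anchors) or
#' across length-scaled regions (expression metaplots over scaled TADs).
#'
#' @param sites interval data.frame.
#' @param track bedGraph-style data.frame (chrom, start, end, value);
#'   uncovered bases read as 0.
#' @param mode \code{"fixed_window"} (site center +/- \code{window_bp}) or
#'   \code{"scaled_region"} (region plus \code{flank_bp} on each side split
#'   into \code{n_bins} proportional bins).
#' @param window_bp half-width for fixed_window mode.
#' @param n_bins number of bins per site (>= 1).
#' @param flank_bp flank added on both sides in scaled_region mode.
#' @param genome optional [genome_spec()]; with it, fixed windows running
#'   past a chromosome end are dropped (with a warning), as are windows
#'   running below 0.
#' @return list with \code{profile} (matrix sites x bins, dropped sites
#'   removed), \code{meta} (column means) and \code{kept} (row indices of
#'   sites retained).
#' @export
signal_metaprofile <- function(sites, track,
                               mode = c("fixed_window", "scaled_region"),
                               window_bp = 50000, n_bins = 20,
                               flank_bp = 0, genome = NULL) {
  mode <- match.arg(mode)
  validate_intervals(sites)
  stopifnot(n_bins >= 1)
  n <- nrow(sites)
  if (mode == "fixed_window") {
    center <- interval_midpoints(sites)
    lo <- center - window_bp
    hi <- center + window_bp
  } else {
    lo <- sites$start - flank_bp
    hi <- sites$end + flank_bp
  }
  keep <- lo >= 0
  if (!is.null(genome)) {
    clen <- genome$length[match(sites$chrom, genome$chrom)]
    keep <- keep & hi <= clen
  }
  if (any(!keep))
    warning(sprintf("%d site(s) dropped: window extends past chromosome edge",
                    sum(!keep)))
  idx <- which(keep)
  prof <- matrix(NA_real_, nrow = length(idx), ncol = n_bins)
  for (ch in unique(sites$chrom[idx])) {
    ii <- idx[sites$chrom[idx] == ch]
    pos <- match(ii, idx)
    # bin edges per site: n_bins equal (fixed) or proportional (scaled) bins
    for (b in seq_len(n_bins)) {
      bs <- lo[ii] + (b - 1) / n_bins * (hi[ii] - lo[ii])
      be <- lo[ii] + b / n_bins * (hi[ii] - lo[ii])
      prof[pos, b] <- .track_window_means(track, ch, bs, be)
    }
  }
  list(profile = prof, meta = colMeans(prof), kept = idx)
}
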