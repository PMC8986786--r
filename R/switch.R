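#' Log2 signal change between conditions
#'
#' Delta = log2((kd + eps) / (wt + eps)), the per-site change in normalized
#' ChIP signal upon knockdown. The pseudocount keeps the ratio finite at
#' zero-signal sites and treats both conditions symmetrically, so swapping
#' wt and kd negates delta exactly.
#'
#' @param wt,kd non-negative RPM-normalized signal vectors.
#' @param epsilon pseudocount in RPM (> 0), default 0.5.
#' @return numeric vector of log2 fold changes.
#' @export
compute_delta <- function(wt, kd, epsilon = 0.5) {
  if (any(wt < 0) || any(kd < 0)) stop("signal must be non-negative")
  stopifnot(epsilon > 0)
  log2((kd + epsilon) / (wt + epsilon))
}

#' Classify STAG2-to-STAG1 switch sites by k-means
#'
#' At sites that lose STAG2 binding upon knockdown, sites are partitioned
#' into two groups by 1-D k-means on the STAG1 signal change; the cluster
#' with the higher mean STAG1 gain is the "switch" group. With 10 random
#' restarts on a single feature the clustering is effectively exact and
#' deterministic for a fixed seed.
#'
#' @param delta_stag1 numeric vector of STAG1 log2 changes, one per site.
#' @param seed integer RNG seed for the k-means restarts.
#' @return character vector of labels \code{"switch"} / \code{"non_switch"}.
#' @export
classify_switch_sites <- function(delta_stag1, seed = 1L) {
  if (length(delta_stag1) < 2) stop("need >= 2 sites")
  if (length(unique(delta_stag1)) == 1)
    stop("all STAG1 deltas identical; k-means partition is undefined")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  cluster <- tryCatch({
    km <- stats::kmeans(matrix(delta_stag1, ncol = 1), centers = 2,
                        nstart = 10)
    km$cluster == which.max(km$centers)
  }, error = function(e) {
    # tiny inputs kmeans refuses: exact 1-D split minimizing within-SS
    o <- order(delta_stag1)
    x <- delta_stag1[o]
    n <- length(x)
    ss <- vapply(seq_len(n - 1), function(k) {
      sum((x[1:k] - mean(x[1:k]))^2) +
        sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2)
    }, 1)
    delta_stag1 > x[which.min(ss)]
  })
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ifelse(cluster, "switch", "non_switch")
}

#' Degree of the STAG2-to-STAG1 switch
#'
#' D = delta[STAG1] + delta[STAG2] in log2 units. Positive D means the gain
#' of STAG1 over-compensates the loss of STAG2 at the site; negative D means
#' under-compensation.
#'
#' @param delta_stag1,delta_stag2 log2 signal changes per site.
#' @return numeric vector of degree-of-switch values.
#' @export
degree_of_switch <- function(delta_stag1, delta_stag2) {
  if (length(delta_stag1) != length(delta_stag2))
    stop("delta vectors must have equal length")
  if (anyNA(delta_stag1) || anyNA(delta_stag2))
    stop("missing deltas: both STAG1 and STAG2 are required")
  delta_stag1 + delta_stag2
}

#' Build a site table with per-factor deltas
#'
#' Convenience wrapper combining site intervals with paired WT/KD signals
#' for several factors into one table with delta columns.
#'
#' @param sites interval data.frame.
#' @param signal named list: for each factor a list/data.frame with numeric
#'   vectors \code{wt} and \code{kd}.
#' @param epsilon pseudocount for [compute_delta()].
#' @return data.frame: sites plus \code{<factor>_wt/_kd/_delta} columns.
#' @export
signal_site_table <- function(sites, signal, epsilon = 0.5) {
  validate_intervals(sites)
  out <- sites
  for (f in names(signal)) {
    s <- signal[[f]]
    stopifnot(length(s$wt) == nrow(sites), length(s$kd) == nrow(sites))
    out[[paste0(f, "_wt")]] <- s$wt
    out[[paste0(f, "_kd")]] <- s$kd
    out[[paste0(f, "_delta")]] <- compute_delta(s$wt, s$kd, epsilon)
  }
  out
}
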