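# Bins with an all-zero row are unmappable and excluded from all means.
.valid_bins <- function(m) which(rowSums(m) > 0)

# Mean contact at each separation s = 1..max_s over valid bin pairs.
.raw_decay <- function(m, max_s = nrow(m) - 1) {
  ok <- .valid_bins(m)
  sapply(seq_len(max_s), function(s) {
    i <- seq_len(nrow(m) - s)
    keep <- i %in% ok & (i + s) %in% ok
    if (!any(keep)) return(NA_real_)
    mean(m[cbind(i[keep], i[keep] + s)])
  })
}

#' Contact-probability decay curve
#'
#' Per chromosome, the mean contact count at each genomic separation is
#' divided by that chromosome's mean count in the first off-diagonal, so
#' loci one bin apart have contact probability 1 on average; curves are
#' then averaged across chromosomes with equal weight. This normalization
#' makes curves from libraries of different depth directly comparable.
#'
#' @param maps a [contact_map()] or list of them (one per chromosome).
#' @param max_s maximum separation in bins; default half the smallest map,
#'   where pair counts keep sampling error small.
#' @return data.frame with columns \code{distance} (bins, and
#'   \code{distance_bp}) and \code{probability}.
#' @export
contact_decay <- function(maps, max_s = NULL) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1)
  nb <- vapply(maps, function(m) nrow(m$matrix), 1L)
  if (any(nb < 2)) stop("need >= 2 bins per map")
  if (is.null(max_s)) max_s <- max(1L, floor(min(nb) / 2))
  curves <- lapply(maps, function(m) {
    d <- .raw_decay(m$matrix, min(max_s, nrow(m$matrix) - 1))
    if (is.na(d[1]) || d[1] == 0)
      stop("first off-diagonal mean is zero; cannot normalize")
    c(d / d[1], rep(NA_real_, max_s - length(d)))
  })
  prob <- rowMeans(do.call(cbind, curves), na.rm = TRUE)
  bs <- maps[[1]]$bin_size
  data.frame(distance = seq_len(max_s),
             distance_bp = seq_len(max_s) * bs,
             probability = prob)
}

#' Compartment-stratified contact levels
#'
#' Mean contacts for bin pairs labeled A-A, A-B and B-B, each normalized by
#' the same first-off-diagonal mean used for the decay curve. Classes with
#' no pairs are NA. Only separations >= 1 bin are pooled (cis matrices).
#'
#' @param maps a [contact_map()] or list of them; compartment labels
#'   required.
#' @return named numeric vector with entries \code{AA}, \code{AB},
#'   \code{BB}.
#' @export
compartment_decay <- function(maps) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  sums <- c(AA = 0, AB = 0, BB = 0)
  npair <- c(AA = 0, AB = 0, BB = 0)
  for (m in maps) {
    lab <- m$compartments
    if (is.null(lab)) stop("compartment labels required")
    if (!any(lab %in% c("A", "B")))
      stop("all bins unassigned; compartment analysis undefined")
    mat <- m$matrix
    norm <- .raw_decay(mat, 1)[1]
    if (is.na(norm) || norm == 0) stop("first off-diagonal mean is zero")
    ok <- .valid_bins(mat)
    n <- nrow(mat)
    ij <- which(upper.tri(mat), arr.ind = TRUE)
    keep <- ij[, 1] %in% ok & ij[, 2] %in% ok &
      lab[ij[, 1]] %in% c("A", "B") & lab[ij[, 2]] %in% c("A", "B")
    ij <- ij[keep, , drop = FALSE]
    cls <- paste0(pmin(lab[ij[, 1]], lab[ij[, 2]]),
                  pmax(lab[ij[, 1]], lab[ij[, 2]]))
    v <- mat[ij] / norm
    for (k in c("AA", "AB", "BB")) {
      sel <- cls == k
      sums[k] <- sums[k] + sum(v[sel])
      npair[k] <- npair[k] + sum(sel)
    }
  }
  out <- sums / npair
  out[npair == 0] <- NA_real_
  out
}

#' Insulation-score track
#'
#' Crane-style sliding square: for each bin i with a full window on both
#' sides, the mean contact count in the square of upstream x downstream
#' bins crossing i is taken, and the score is the log2 ratio of that mean
#' to the chromosome-wide mean of all such square means. Local minima mark
#' insulating boundaries; the score is invariant to uniform scaling of the
#' matrix.
#'
#' @param map a [contact_map()].
#' @param window window half-width in bins (>= 1).
#' @return data.frame with \code{bin} (0-based), \code{start}, \code{end}
#'   (bp) and \code{score} (log2 units; NA where the window is incomplete).
#' @export
insulation_track <- function(map, window) {
  stopifnot(window >= 1)
  m <- map$matrix
  n <- nrow(m)
  if (n <= 2 * window) stop("window too large for matrix")
  sq <- rep(NA_real_, n)
  for (i in (window + 1):(n - window + 1)) {
    sq[i] <- mean(m[(i - window):(i - 1), i:(i + window - 1)])
  }
  mu <- mean(sq, na.rm = TRUE)
  score <- log2(sq / mu)
  data.frame(bin = seq_len(n) - 1L,
             start = (seq_len(n) - 1) * map$bin_size,
             end = seq_len(n) * map$bin_size,
             score = score)
}
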