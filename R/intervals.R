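#' Construct a genomic interval table
#'
#' Intervals follow the BED convention throughout the package: 0-based,
#' half-open \code{[start, end)}. A touching pair such as \code{[0,10)} and
#' \code{[10,20)} does not overlap.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, \code{0 <= start < end}.
#' @param name optional labels (default \code{"."}).
#' @param score optional numeric scores (default \code{NA}).
#' @param strand optional strand in \code{+,-,.} (default \code{"."}).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
intervals <- function(chrom, start, end, name = ".", score = NA_real_,
                      strand = ".") {
  n <- max(length(chrom), length(start))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' @keywords internal
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("interval chrom must be non-empty")
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval start must be < end")
  invisible(df)
}

# IRanges uses 1-based closed coordinates; [start,end) maps to [start+1, end].
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Merge overlapping or touching intervals
#'
#' Produces the per-chromosome union of the input: sorted, pairwise disjoint,
#' with touching intervals (one's end equal to the next one's start) merged
#' into a single region, as when adjacent TAD boundary regions coalesce into
#' one big boundary.
#'
#' @param df interval data.frame (see [intervals()]).
#' @return merged interval data.frame, sorted by (chrom, start).
#' @export
merge_intervals <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(.as_iranges(d))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(r) - 1,
               end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Do two intervals overlap?
#'
#' Half-open semantics: \code{[0,10)} and \code{[10,20)} do not overlap.
#'
#' @param a,b single-row interval data.frames (or lists with chrom/start/end).
#' @return logical scalar.
#' @export
interval_overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Count query intervals overlapping any subject interval
#'
#' @param query,subject interval data.frames.
#' @return integer: number of query rows with >= 1 bp overlap with any
#'   subject interval (half-open semantics).
#' @export
count_overlapping <- function(query, subject) {
  sum(overlaps_any(query, subject))
}

#' Per-row overlap indicator
#'
#' @param query,subject interval data.frames.
#' @return logical vector along query rows.
#' @export
overlaps_any <- function(query, subject) {
  validate_intervals(query)
  validate_intervals(subject)
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  hit <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sdf <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sdf) == 0) next
    n <- IRanges::countOverlaps(.as_iranges(query[qi, , drop = FALSE]),
                                .as_iranges(sdf))
    hit[qi] <- n > 0
  }
  hit
}

#' Midpoints of intervals
#' @param df interval data.frame.
#' @return numeric vector of (start+end)/2 midpoints.
#' @export
interval_midpoints <- function(df) (df$start + df$end) / 2

#' Genome specification
#'
#' @param chrom chromosome names (unique).
#' @param length chromosome lengths in bp (> 0).
#' @return data.frame with columns chrom, length.
#' @export
genome_spec <- function(chrom, length) {
  stopifnot(!anyDuplicated(chrom), all(length > 0))
  data.frame(chrom = as.character(chrom), length = as.numeric(length),
             stringsAsFactors = FALSE)
}
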