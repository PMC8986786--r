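#' Read intervals from BED or narrowPeak files
#'
#' BED columns beyond the first three (name, score, strand) are kept when
#' present. For narrowPeak (10 columns) the signalValue column is mapped to
#' \code{score}, as downstream analyses use it as the per-peak signal.
#'
#' @param path path to a tab-separated text file.
#' @param format \code{"bed"} or \code{"narrowPeak"}.
#' @return interval data.frame (see [intervals()]).
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(intervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- if (format == "narrowPeak") 10L else 3L
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < ncol_min)
      stop(sprintf("line %d: expected >= %d columns, got %d",
                   i, ncol_min, length(f)))
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stop(sprintf("line %d: non-integer coordinate", i))
    if (s >= e)
      stop(sprintf("line %d: start >= end", i))
  }
  get <- function(j, default) {
    vapply(fields, function(f) if (length(f) >= j) f[j] else default, "")
  }
  chrom <- get(1, NA_character_)
  start <- as.numeric(get(2, NA_character_))
  end <- as.numeric(get(3, NA_character_))
  name <- get(4, ".")
  strand <- get(6, ".")
  score <- if (format == "narrowPeak") {
    as.numeric(get(7, NA_character_))  # signalValue
  } else {
    suppressWarnings(as.numeric(get(5, NA_character_)))
  }
  intervals(chrom, start, end, name, score, strand)
}

#' Write intervals as BED6
#' @param df interval data.frame.
#' @param path output path.
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df)
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else NA_real_
  strand <- if ("strand" %in% names(df)) df$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   df$chrom, as.integer(df$start), as.integer(df$end),
                   name,
                   ifelse(is.na(score), ".", format(score, trim = TRUE,
                                                    scientific = FALSE)),
                   strand)
  writeLines(lines, path)
}

.count_col_rx <- "^(wt|kd)_rep[0-9]+$"

#' Read HiChIP loops from headered BEDPE
#'
#' Expected dialect: a header line starting with \code{#} naming columns
#' \code{chrom1 start1 end1 chrom2 start2 end2 <wt_rep*> <kd_rep*> fdr};
#' per-replicate supporting-read counts are non-negative integers and
#' \code{fdr} is the upstream loop caller's FDR. Anchors are stored in
#' canonical order (anchor1 <= anchor2 by chrom, start).
#'
#' @param path path to the BEDPE file.
#' @return data.frame with columns chrom1,start1,end1,chrom2,start2,end2,
#'   one column per replicate count, and fdr.
#' @export
read_loops <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || !startsWith(lines[1], "#"))
    stop("loop file must begin with a '#' header line")
  header <- strsplit(sub("^#", "", lines[1]), "[\t ]+")[[1]]
  header <- header[nzchar(header)]
  count_cols <- grep(.count_col_rx, header, value = TRUE)
  if (length(count_cols) == 0) stop("no replicate count columns in header")
  if (!"fdr" %in% header) stop("missing fdr column in header")
  body <- lines[-1]
  if (length(body) == 0) {
    df <- as.data.frame(matrix(numeric(0), ncol = length(header)))
    names(df) <- header
    return(df)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != length(header))
      stop(sprintf("line %d: expected %d columns, got %d",
                   i + 1L, length(header), length(fields[[i]])))
  }
  m <- do.call(rbind, fields)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- header
  num_cols <- setdiff(header, c("chrom1", "chrom2"))
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in count_cols) {
    v <- df[[cc]]
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
      stop(sprintf("column %s: counts must be non-negative integers", cc))
  }
  canonicalize_loops(df)
}

#' Put loop anchors in canonical genomic order
#' @param df loop data.frame.
#' @return same data.frame with anchor1 <= anchor2 by (chrom, start).
#' @export
canonicalize_loops <- function(df) {
  if (nrow(df) == 0) return(df)
  flip <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$start2 < df$start1)
  if (any(flip)) {
    a <- df[flip, c("chrom1", "start1", "end1")]
    df[flip, c("chrom1", "start1", "end1")] <-
      df[flip, c("chrom2", "start2", "end2")]
    df[flip, c("chrom2", "start2", "end2")] <- a
  }
  df
}

#' Write loops as headered BEDPE
#' @param df loop data.frame as returned by [read_loops()].
#' @param path output path.
#' @export
write_loops <- function(df, path) {
  coord <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  count_cols <- grep(.count_col_rx, names(df), value = TRUE)
  cols <- c(coord, count_cols, "fdr")
  header <- paste0("#", paste(cols, collapse = "\t"))
  fmt <- function(x) {
    if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE, digits = 15)
    else as.character(x)
  }
  body <- do.call(paste, c(lapply(df[cols], fmt), sep = "\t"))
  writeLines(c(header, if (nrow(df) > 0) body), path)
}

#' Read a bedGraph signal track
#' @param path bedGraph path (chrom, start, end, value).
#' @return data.frame with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  df
}

#' Write a bedGraph signal track
#' @param df data.frame with chrom, start, end, value.
#' @param path output path.
#' @export
write_bedgraph <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                     as.integer(df$end),
                     format(df$value, trim = TRUE, scientific = FALSE)),
             path)
}

#' Construct a contact map
#'
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param matrix symmetric non-negative square matrix of contact counts.
#' @param compartments optional per-bin labels in \code{A,B,unassigned}.
#' @return object of class \code{contact_map}.
#' @export
contact_map <- function(chrom, bin_size, matrix, compartments = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix), bin_size > 0)
  if (any(matrix < 0)) stop("contact matrix entries must be >= 0")
  if (max(abs(matrix - t(matrix))) > 1e-9)
    stop("contact matrix must be symmetric")
  if (!is.null(compartments))
    stopifnot(length(compartments) == nrow(matrix))
  structure(list(chrom = chrom, bin_size = bin_size, matrix = matrix,
                 compartments = compartments),
            class = "contact_map")
}

#' Write a contact map as dense text plus sidecar header
#'
#' The matrix is written whitespace-separated, one row per line, to
#' \code{path}; a sidecar \code{<path>.hdr} records chrom, bin_size and
#' n_bins (and compartment labels when present).
#'
#' @param map a [contact_map()].
#' @param path output path for the dense matrix.
#' @export
write_contact_map <- function(map, path) {
  rows <- apply(map$matrix, 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
          collapse = " "))
  writeLines(rows, path)
  hdr <- c(paste("chrom", map$chrom),
           paste("bin_size", format(map$bin_size, scientific = FALSE)),
           paste("n_bins", nrow(map$matrix)))
  if (!is.null(map$compartments))
    hdr <- c(hdr, paste("compartments", paste(map$compartments,
                                              collapse = " ")))
  writeLines(hdr, paste0(path, ".hdr"))
}

#' Read a contact map written by [write_contact_map()]
#' @param path path to the dense matrix file.
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path) {
  hdr_lines <- readLines(paste0(path, ".hdr"))
  kv <- strsplit(hdr_lines, " ")
  keys <- vapply(kv, `[`, "", 1)
  val <- function(k) kv[[match(k, keys)]][-1]
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  comp <- if ("compartments" %in% keys) val("compartments") else NULL
  map <- contact_map(val("chrom"), as.numeric(val("bin_size")), m, comp)
  stopifnot(nrow(m) == as.integer(val("n_bins")))
  map
}
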