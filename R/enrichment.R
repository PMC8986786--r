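#' Permutation test for interval-overlap enrichment
#'
#' Tests whether a set of sites (e.g. STAG2-to-STAG1 switch sites) overlaps
#' a feature set (TAD boundaries, domains, enhancers, promoters) more or
#' less often than expected by chance. Each permutation re-places every site
#' uniformly at random on its own chromosome, preserving its length; sites
#' may overlap each other after placement. Empirical p-values use the
#' add-one form p = (1 + #{null >= observed}) / (n_perm + 1), which never
#' reports zero.
#'
#' @param sites,features interval data.frames.
#' @param genome [genome_spec()] covering every site chromosome.
#' @param n_perm number of permutations (>= 1), default 1000.
#' @param seed RNG seed.
#' @return list with observed, null_counts, enrichment_ratio, p_enrich,
#'   p_deplete.
#' @export
permutation_enrichment <- function(sites, features, genome, n_perm = 1000,
                                   seed = 1L) {
  validate_intervals(sites)
  validate_intervals(features)
  stopifnot(n_perm >= 1)
  if (!all(sites$chrom %in% genome$chrom))
    stop("every site chromosome must be present in the genome spec")
  len <- sites$end - sites$start
  chrom_len <- genome$length[match(sites$chrom, genome$chrom)]
  if (any(len > chrom_len)) stop("site longer than its chromosome")

  observed <- count_overlapping(sites, features)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  n <- nrow(sites)
  # all permutations drawn at once; one overlap query per chromosome
  starts <- floor(matrix(stats::runif(n * n_perm), nrow = n) *
                    (chrom_len - len + 1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  hit <- matrix(FALSE, nrow = n, ncol = n_perm)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    fdf <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(fdf) == 0) next
    st <- as.vector(starts[si, , drop = FALSE])
    ir <- IRanges::IRanges(start = st + 1, width = rep(len[si], n_perm))
    cnt <- IRanges::countOverlaps(ir, .as_iranges(fdf))
    hit[si, ] <- matrix(cnt > 0, nrow = length(si))
  }
  null_counts <- colSums(hit)

  list(observed = observed,
       null_counts = as.integer(null_counts),
       enrichment_ratio = observed / mean(null_counts),
       p_enrich = (1 + sum(null_counts >= observed)) / (n_perm + 1),
       p_deplete = (1 + sum(null_counts <= observed)) / (n_perm + 1))
}
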