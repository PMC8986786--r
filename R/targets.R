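#' Nominate direct target genes by three-way evidence integration
#'
#' A gene is a direct target when it (1) is differentially expressed
#' (expression FDR below \code{expr_fdr_max}), (2) has reduced STAG2
#' binding at its promoter (promoter overlaps a lost-STAG2 peak), and
#' (3) is associated with a differential H3K27ac loop (promoter overlaps an
#' anchor of an enhanced or impaired loop). Per-gene criteria are recorded
#' for Venn-style reporting.
#'
#' @param genes data.frame with columns gene_id, chrom, tss (bp),
#'   expr_log2fc, expr_fdr.
#' @param lost_stag2_peaks interval data.frame of peaks losing STAG2.
#' @param diff_loops loop data.frame with a \code{klass} column from
#'   [differential_loops()].
#' @param expr_fdr_max differential-expression FDR cutoff, default 0.05.
#' @param promoter_flank promoter half-width around the TSS in bp,
#'   default 2000.
#' @return data.frame with gene_id, logical criterion columns
#'   (differential_expression, promoter_binding_loss, differential_loop)
#'   and is_direct_target.
#' @export
identify_direct_targets <- function(genes, lost_stag2_peaks, diff_loops,
                                    expr_fdr_max = 0.05,
                                    promoter_flank = 2000) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(genes$tss - promoter_flank, 0),
                     end = genes$tss + promoter_flank)
  c1 <- genes$expr_fdr < expr_fdr_max
  c2 <- overlaps_any(prom, lost_stag2_peaks)
  dl <- diff_loops[diff_loops$klass %in% c("enhanced", "impaired"), ,
                   drop = FALSE]
  anchors <- if (nrow(dl) > 0) {
    rbind(data.frame(chrom = dl$chrom1, start = dl$start1, end = dl$end1),
          data.frame(chrom = dl$chrom2, start = dl$start2, end = dl$end2))
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  c3 <- overlaps_any(prom, anchors)
  data.frame(gene_id = genes$gene_id,
             differential_expression = c1,
             promoter_binding_loss = c2,
             differential_loop = c3,
             is_direct_target = c1 & c2 & c3,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted Spearman correlation
#'
#' Regresses \code{y} on the covariate by ordinary least squares (with
#' intercept), then correlates \code{x} with the residuals by Spearman's
#' rank method. Used to ask whether x predicts y independently of a
#' confounding regulator (e.g. STAG2 vs PD-L1 expression adjusted for
#' STAT1).
#'
#' @param x,y,covariate numeric vectors of equal length >= 4.
#' @return list with rho and the two-sided p-value.
#' @export
adjusted_spearman <- function(x, y, covariate) {
  n <- length(x)
  stopifnot(length(y) == n, length(covariate) == n)
  if (n < 4) stop("need >= 4 observations")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  res <- stats::residuals(stats::lm(y ~ covariate))
  if (stats::sd(res) < 1e-12 * max(stats::sd(y), 1))
    stop("residuals are constant; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, res, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
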