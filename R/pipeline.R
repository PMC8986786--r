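#' Pipeline configuration
#'
#' Bundles the input paths (as emitted by [generate_scenario()] or by
#' upstream callers in the same formats) with every tunable parameter.
#'
#' @param input_dir directory holding the input bundle.
#' @param output_dir directory for stage outputs and summary.json.
#' @param ... parameter overrides (epsilon, flank, tolerance,
#'   stitch_distance, loop_fdr, expr_fdr_max, promoter_flank, n_perm,
#'   insulation_window, seed).
#' @return config list.
#' @export
pipeline_config <- function(input_dir, output_dir, ...) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              epsilon = 0.5, flank = 10000, tolerance = 10000,
              stitch_distance = 12500, loop_fdr = 0.01,
              expr_fdr_max = 0.05, promoter_flank = 2000,
              n_perm = 1000, insulation_window = 4, seed = 1L)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(cfg)))
  cfg[names(ov)] <- ov
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full downstream analysis pipeline
#'
#' Executes, in order: switch classification at lost-STAG2 sites, TAD
#' boundary and size dynamics, contact-decay and insulation metrics,
#' differential-loop calling and classification, super-enhancer calling,
#' and direct-target integration. Writes per-stage tables and a
#' machine-readable summary.json to the output directory.
#'
#' @param cfg a [pipeline_config()].
#' @return the summary list, invisibly written as summary.json.
#' @export
run_pipeline <- function(cfg) {
  ind <- function(f) {
    p <- file.path(cfg$input_dir, f)
    if (!file.exists(p)) stop(sprintf("missing input: %s", p))
    p
  }
  required <- c("sites_signal.tsv", "lost_stag2_peaks.bed", "tads_wt.bed",
                "tads_kd.bed", "matrix_wt.txt", "matrix_kd.txt",
                "loops.bedpe", "genes.tsv", "promoters.bed",
                "enhancers.bed", "expression.tsv")
  for (f in required) ind(f)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  summary <- list(parameters = cfg[setdiff(names(cfg),
                                           c("input_dir", "output_dir"))])

  ## switch analysis
  sites <- .stage("switch", {
    s <- utils::read.table(ind("sites_signal.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
    s$switch_label <- classify_switch_sites(s$STAG1_delta, seed = cfg$seed)
    s$degree_of_switch <- degree_of_switch(s$STAG1_delta, s$STAG2_delta)
    utils::write.table(s, out("sites_classified.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    s
  })
  is_sw <- sites$switch_label == "switch"
  summary$switch <- list(
    n_sites = nrow(sites), n_switch = sum(is_sw),
    n_non_switch = sum(!is_sw),
    mean_h3k27ac_delta_switch = mean(sites$H3K27ac_delta[is_sw]),
    mean_h3k27ac_delta_non_switch = mean(sites$H3K27ac_delta[!is_sw]))

  ## switch-site enrichment in genomic features
  summary$enrichment <- .stage("enrichment", {
    genome <- {
      hdr <- readLines(paste0(ind("matrix_wt.txt"), ".hdr"))
      kv <- strsplit(hdr, " ")
      genome_spec(kv[[1]][2], as.numeric(kv[[2]][2]) *
                    as.numeric(kv[[3]][2]))
    }
    sw <- sites[is_sw, c("chrom", "start", "end")]
    wt_tads_e <- read_intervals(ind("tads_wt.bed"))
    feats <- list(
      tad_boundaries = extract_boundaries(wt_tads_e, cfg$flank, genome),
      tad_domains = wt_tads_e,
      enhancers = read_intervals(ind("enhancers.bed")),
      promoters = read_intervals(ind("promoters.bed")))
    lapply(feats, function(f) {
      e <- permutation_enrichment(sw, f, genome, n_perm = cfg$n_perm,
                                  seed = cfg$seed)
      e[c("observed", "enrichment_ratio", "p_enrich", "p_deplete")]
    })
  })

  ## TAD dynamics
  tads <- .stage("tads", {
    wt <- read_intervals(ind("tads_wt.bed"))
    kd <- read_intervals(ind("tads_kd.bed"))
    bw <- extract_boundaries(wt, cfg$flank)
    bk <- extract_boundaries(kd, cfg$flank)
    bm <- classify_boundaries(bw, bk, cfg$tolerance)
    ch <- classify_tad_changes(wt, kd, cfg$tolerance, cfg$flank)
    utils::write.table(bm, out("boundaries.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ch, out("tad_changes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(wt = wt, kd = kd, bw = bw, bk = bk, bm = bm, ch = ch)
  })
  sz <- tad_size_stats(tads$wt, tads$kd)
  vb <- tads$ch[tads$ch$klass != "stable", , drop = FALSE]
  summary$tads <- list(
    n_wt = nrow(tads$wt), n_kd = nrow(tads$kd),
    n_boundaries_wt = nrow(tads$bw), n_boundaries_kd = nrow(tads$bk),
    n_stable = sum(tads$bm$klass == "stable"),
    n_variable = sum(tads$bm$klass == "variable"),
    n_expanded = sum(tads$ch$klass == "expanded"),
    n_shrinked = sum(tads$ch$klass == "shrinked"),
    vb_pct_new = if (nrow(vb)) 100 * mean(vb$vb_category == "new_boundary"),
    vb_pct_merged = if (nrow(vb)) 100 * mean(vb$vb_category == "merged"),
    vb_pct_shifted = if (nrow(vb)) 100 * mean(vb$vb_category == "shifted"),
    median_size_wt = sz$median_wt, median_size_kd = sz$median_kd,
    size_p_value = sz$p_value)

  ## contact metrics
  contacts <- .stage("contacts", {
    mw <- read_contact_map(ind("matrix_wt.txt"))
    mk <- read_contact_map(ind("matrix_kd.txt"))
    dw <- contact_decay(mw); dk <- contact_decay(mk)
    iw <- insulation_track(mw, cfg$insulation_window)
    ik <- insulation_track(mk, cfg$insulation_window)
    utils::write.table(
      data.frame(distance = dw$distance, distance_bp = dw$distance_bp,
                 wt = dw$probability, kd = dk$probability),
      out("decay_curves.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_bedgraph(data.frame(chrom = mw$chrom, start = iw$start,
                              end = iw$end,
                              value = ifelse(is.na(iw$score), 0, iw$score)),
                   out("insulation_wt.bedgraph"))
    write_bedgraph(data.frame(chrom = mk$chrom, start = ik$start,
                              end = ik$end,
                              value = ifelse(is.na(ik$score), 0, ik$score)),
                   out("insulation_kd.bedgraph"))
    list(mw = mw, mk = mk, dw = dw, dk = dk, iw = iw, ik = ik)
  })
  long <- contacts$dw$distance > 10
  summary$contacts <- list(
    n_bins = nrow(contacts$mw$matrix),
    frac_long_range_kd_above_wt = mean(
      contacts$dk$probability[long] >= contacts$dw$probability[long]))

  ## differential loops
  loops <- .stage("loops", {
    l <- read_loops(ind("loops.bedpe"))
    fl <- filter_loops(l)
    dl <- differential_loops(fl$loops, fdr_threshold = cfg$loop_fdr)
    dl$anchor_type <- classify_loop_anchors(
      dl, read_intervals(ind("promoters.bed")),
      read_intervals(ind("enhancers.bed")))
    dl$tad_relation <- loops_vs_tads(dl, tads$wt)
    utils::write.table(dl, out("diffloops.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(all = l, filtered = fl, dl = dl)
  })
  dl <- loops$dl
  altered <- dl[dl$klass != "unchanged", , drop = FALSE]
  lls <- if (any(dl$klass == "enhanced") && any(dl$klass == "impaired"))
    loop_length_stats(dl[dl$klass == "enhanced", ],
                      dl[dl$klass == "impaired", ])
  summary$loops <- list(
    n_input = nrow(loops$all), n_filtered_out = nrow(loops$filtered$removed),
    n_tested = nrow(dl),
    n_enhanced = sum(dl$klass == "enhanced"),
    n_impaired = sum(dl$klass == "impaired"),
    pct_within_tad = if (nrow(altered))
      100 * mean(altered$tad_relation == "within"),
    anchor_type_counts = as.list(table(dl$anchor_type)),
    median_length_enhanced = if (!is.null(lls)) lls$median_enhanced,
    median_length_impaired = if (!is.null(lls)) lls$median_impaired,
    length_p_value = if (!is.null(lls)) lls$p_value)

  ## degree of switch at loop anchors
  summary$degree_of_switch <- .stage("degree_of_switch", {
    anchor_mean_D <- function(sub) {
      if (nrow(sub) == 0) return(NA_real_)
      anch <- rbind(
        data.frame(chrom = sub$chrom1, start = sub$start1, end = sub$end1),
        data.frame(chrom = sub$chrom2, start = sub$start2, end = sub$end2))
      hit <- overlaps_any(sites[, c("chrom", "start", "end")], anch)
      mean(sites$degree_of_switch[hit])
    }
    list(mean_d_enhanced_anchors = anchor_mean_D(
           dl[dl$klass == "enhanced", ]),
         mean_d_impaired_anchors = anchor_mean_D(
           dl[dl$klass == "impaired", ]))
  })

  ## super-enhancers from H3K27ac site signal
  summary$superenhancers <- .stage("superenhancers", {
    se_call <- function(col) {
      pk <- intervals(sites$chrom, sites$start, sites$end,
                      name = sites$name, score = sites[[col]])
      call_superenhancers(stitch_peaks(pk, cfg$stitch_distance))
    }
    se_wt <- se_call("H3K27ac_wt")
    se_kd <- se_call("H3K27ac_kd")
    cmp <- compare_superenhancers(se_wt, se_kd)
    utils::write.table(se_kd, out("superenhancers_kd.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(n_super_wt = sum(se_wt$is_super), n_super_kd = sum(se_kd$is_super),
         n_gained = cmp$n_gained, n_lost = cmp$n_lost,
         n_maintained = cmp$n_maintained)
  })

  ## direct-target integration
  summary$targets <- .stage("targets", {
    genes <- utils::read.table(ind("genes.tsv"), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    lost <- read_intervals(ind("lost_stag2_peaks.bed"))
    tc <- identify_direct_targets(genes, lost, dl,
                                  expr_fdr_max = cfg$expr_fdr_max,
                                  promoter_flank = cfg$promoter_flank)
    utils::write.table(tc, out("targets.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(n_genes = nrow(tc),
         n_differential_expression = sum(tc$differential_expression),
         n_promoter_binding_loss = sum(tc$promoter_binding_loss),
         n_differential_loop = sum(tc$differential_loop),
         n_direct_targets = sum(tc$is_direct_target),
         direct_targets = sort(tc$gene_id[tc$is_direct_target]))
  })

  ## TCGA-style adjusted correlation
  summary$adjusted_correlation <- .stage("adjusted_correlation", {
    e <- utils::read.table(ind("expression.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
    marg <- suppressWarnings(
      stats::cor.test(e$STAG2, e$CD274, method = "spearman"))
    adj <- adjusted_spearman(e$STAG2, e$CD274, e$STAT1)
    list(marginal_rho = unname(marg$estimate), adjusted_rho = adj$rho,
         adjusted_p = adj$p_value)
  })

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(summary)
}
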