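#' Default synthetic-scenario configuration
#'
#' One 20-Mb chromosome carrying ~100 TADs with planted boundary changes
#' (30 expansions, 20 shrinkages, 10 merges under the default fractions),
#' 1000 lost-STAG2 binding sites of which 40% switch to STAG1 (mean STAG1
#' gain 1.5 log2 units, sd 0.3), paired WT/KD contact matrices with TAD
#' block structure, 1000 replicated HiChIP-style loops with planted
#' enhanced/impaired classes, and 200 genes of which 20 are wired as
#' direct targets (differential expression + promoter STAG2 loss +
#' promoter-anchored differential loop).
#'
#' @param seed mandatory integer seed; all randomness flows from it.
#' @param ... overrides for any default field.
#' @return list of scenario parameters.
#' @export
scenario_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom = "chr1",
    chrom_length = 20e6,
    bin_size = 20000,
    n_tads = 100,
    tad_size_range = c(120e3, 200e3),
    fraction_expanded = 0.30,
    fraction_shrinked = 0.20,
    fraction_merged = 0.20,       # fraction of WT TADs consumed by merges
    boundary_shift_range = c(15e3, 28e3),
    decay_alpha_wt = 1.0,
    decay_alpha_kd = 0.9,         # planted long-range contact gain in KD
    tad_boost = 2.0,
    boundary_leak = 1.0,          # contact gain across weak boundaries
    map_depth = 50,
    n_binding_sites = 1000,
    site_width = 1000,
    fraction_switch = 0.40,
    switch_effect = 1.5,
    switch_sd = 0.3,
    stag2_loss_effect = -2.0,
    h3k27ac_coupling = 0.4,
    epsilon = 0.5,
    n_loops = 1000,
    anchor_width = 5000,
    fraction_enhanced = 0.15,
    fraction_impaired = 0.15,
    loop_fold_change = 3,
    loop_base_mean = 20,
    nb_dispersion = 0.1,
    replicates = 2,
    target_loop_mean = 100,
    target_loop_fold = 8,
    n_genes = 200,
    n_targets = 20,
    n_de_peak_only = 15,
    n_de_only = 15,
    promoter_flank = 2000,
    n_enhancers = 300,
    n_expr_samples = 473
  )
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(cfg)))
  cfg[names(ov)] <- ov
  fr <- cfg$fraction_expanded + cfg$fraction_shrinked + cfg$fraction_merged
  if (fr > 1) stop("TAD change fractions sum to more than 1")
  if (cfg$fraction_enhanced + cfg$fraction_impaired > 1)
    stop("loop class fractions sum to more than 1")
  cfg
}

# Lay out exactly n non-overlapping TADs along one chromosome: sizes drawn
# from size_range, separated by one uniform gap sized to fill the
# chromosome (so planted change counts are exact for a given n).
.layout_tads <- function(L, n, size_range) {
  sizes <- round(stats::runif(n, size_range[1], size_range[2]) /
                   1000) * 1000
  gap <- floor((L - sum(sizes)) / (n + 1) / 1000) * 1000
  if (gap < 24000)
    stop("chromosome too short for the requested TAD layout")
  starts <- gap + cumsum(c(0, sizes[-n] + gap))
  data.frame(start = starts, end = starts + sizes)
}

#' Simulate a binned contact matrix with TAD block structure
#'
#' Expected contacts are \code{depth * |i-j|^(-decay_alpha)} off the
#' diagonal, multiplied by \code{1 + boost} for bin pairs inside the same
#' TAD (boost may be a per-TAD vector, allowing planted weak domains).
#' Counts are Poisson draws around the expectation unless
#' \code{noiseless}.
#'
#' Weak (leaky) boundaries can be planted: bin pairs straddling a listed
#' boundary position within \code{leak_window} bins on each side have
#' their expectation multiplied by \code{1 + leak}, which raises the
#' insulation score (shallower minimum) at that boundary without touching
#' the rest of the matrix.
#'
#' @param tads interval data.frame of TADs on one chromosome.
#' @param chrom,chrom_length,bin_size map geometry.
#' @param decay_alpha distance-decay exponent (> 0).
#' @param tad_boost scalar or per-TAD vector of same-TAD contact boosts.
#' @param depth expected count at one-bin separation outside TADs.
#' @param seed RNG seed (ignored when noiseless).
#' @param noiseless emit the expectation itself instead of Poisson draws.
#' @param leaky_boundaries optional vector of boundary positions (bp) with
#'   planted contact leak across them.
#' @param leak fractional contact gain across leaky boundaries.
#' @param leak_window half-width of the leak zone in bins.
#' @return a [contact_map()].
#' @export
simulate_contact_map <- function(tads, chrom, chrom_length, bin_size,
                                 decay_alpha = 1, tad_boost = 2, depth = 50,
                                 seed = 1L, noiseless = FALSE,
                                 leaky_boundaries = NULL, leak = 1,
                                 leak_window = 4) {
  stopifnot(decay_alpha > 0, all(tad_boost >= 0))
  n <- floor(chrom_length / bin_size)
  centers <- (seq_len(n) - 0.5) * bin_size
  tid <- rep(NA_integer_, n)
  for (t in seq_len(nrow(tads)))
    tid[centers >= tads$start[t] & centers < tads$end[t]] <- t
  boost <- rep_len(tad_boost, nrow(tads))
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- depth * ifelse(s == 0, 0, s^(-decay_alpha))
  same <- !is.na(tid) & outer(tid, tid, "==")
  same[is.na(same)] <- FALSE
  bmat <- matrix(0, n, n)
  bmat[same] <- boost[tid[row(bmat)[same]]]
  lam <- lam * (1 + bmat)
  for (pos in leaky_boundaries) {
    b <- floor(pos / bin_size)        # boundary between bins b and b+1
    lo <- max(b - leak_window + 1, 1)
    hi <- min(b + leak_window, n)
    if (lo > b || b + 1 > hi) next
    lam[lo:b, (b + 1):hi] <- lam[lo:b, (b + 1):hi] * (1 + leak)
    lam[(b + 1):hi, lo:b] <- lam[(b + 1):hi, lo:b] * (1 + leak)
  }
  if (noiseless) {
    m <- lam
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    up <- upper.tri(lam)
    m <- matrix(0, n, n)
    m[up] <- stats::rpois(sum(up), lam[up])
    m <- m + t(m)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  contact_map(chrom, bin_size, m)
}

#' Simulate replicated loop supporting-read counts
#'
#' Negative-binomial counts (variance mu + dispersion * mu^2; Poisson when
#' dispersion is 0) for WT and KD replicates. Enhanced loops have their KD
#' mean multiplied by \code{fold_change}; impaired loops have their WT mean
#' multiplied by it (so both classes change by the same fold and the
#' expected per-replicate totals stay balanced across conditions).
#'
#' @param classes character vector in enhanced/impaired/unchanged.
#' @param base_mean expected WT count per replicate.
#' @param fold_change planted fold change for differential classes.
#' @param nb_dispersion NB dispersion (>= 0).
#' @param replicates replicates per condition.
#' @param seed RNG seed.
#' @return matrix with columns wt_rep1..wt_repR, kd_rep1..kd_repR.
#' @export
simulate_loop_counts <- function(classes, base_mean = 20, fold_change = 3,
                                 nb_dispersion = 0.1, replicates = 2,
                                 seed = 1L) {
  stopifnot(base_mean > 0, nb_dispersion >= 0)
  n <- length(classes)
  mu_wt <- base_mean * ifelse(classes == "impaired", fold_change, 1)
  mu_kd <- base_mean * ifelse(classes == "enhanced", fold_change, 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  draw <- function(mu) {
    if (nb_dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
  }
  m <- cbind(
    matrix(draw(rep(mu_wt, replicates)), n, replicates),
    matrix(draw(rep(mu_kd, replicates)), n, replicates)
  )
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  colnames(m) <- c(paste0("wt_rep", seq_len(replicates)),
                   paste0("kd_rep", seq_len(replicates)))
  m
}

# kd signal realizing a target log2 change given the shared pseudocount
.kd_from_delta <- function(wt, delta, eps) {
  pmax((wt + eps) * 2^delta - eps, 0)
}

#' Generate the full paired WT/KD synthetic bundle with planted truth
#'
#' Emits every input the pipeline consumes (signal site table, lost-STAG2
#' peaks, WT/KD TAD BED, WT/KD contact matrices, boundary signal tracks,
#' replicated loop BEDPE, promoter/enhancer BED, gene table, expression
#' matrix) plus a truth record of all planted labels, to \code{out_dir}.
#' Deterministic and byte-identical for a fixed config seed.
#'
#' @param cfg a [scenario_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with all in-memory objects, the truth record
#'   and the written file paths.
#' @export
generate_scenario <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  ## --- TADs and planted changes -------------------------------------
  set.seed(cfg$seed + 101L)
  td <- .layout_tads(cfg$chrom_length, cfg$n_tads, cfg$tad_size_range)
  n_tad <- nrow(td)
  n_exp <- round(cfg$fraction_expanded * n_tad)
  n_shr <- round(cfg$fraction_shrinked * n_tad)
  n_mrg <- floor(cfg$fraction_merged * n_tad / 2)   # merge events (pairs)
  # merges consume adjacent pairs; changes must not collide
  avail <- seq_len(n_tad)
  merge_first <- integer(0)
  while (length(merge_first) < n_mrg) {
    c1 <- sample(avail[avail < n_tad], 1)
    if ((c1 + 1) %in% avail) {
      merge_first <- c(merge_first, c1)
      avail <- setdiff(avail, c(c1, c1 + 1))
    }
  }
  expanded <- sample(avail, n_exp); avail <- setdiff(avail, expanded)
  shrinked <- sample(avail, n_shr); avail <- setdiff(avail, shrinked)
  tad_class <- rep("stable", n_tad)
  tad_class[expanded] <- "expanded"
  tad_class[shrinked] <- "shrinked"
  tad_class[c(merge_first, merge_first + 1)] <- "merged"

  shift <- round(stats::runif(n_tad, cfg$boundary_shift_range[1],
                              cfg$boundary_shift_range[2]) / 1000) * 1000
  kd_start <- td$start
  kd_end <- td$end
  kd_end[expanded] <- td$end[expanded] + shift[expanded]
  kd_end[shrinked] <- td$end[shrinked] - shift[shrinked]
  kd_keep <- rep(TRUE, n_tad)
  kd_end[merge_first] <- td$end[merge_first + 1]
  kd_keep[merge_first + 1] <- FALSE
  wt_tads <- intervals(cfg$chrom, td$start, td$end,
                       name = sprintf("tad%03d", seq_len(n_tad)))
  kd_tads <- intervals(cfg$chrom, kd_start[kd_keep], kd_end[kd_keep])
  # boundary truth: edges whose position changed between conditions
  variable_edges <- c(td$end[expanded], td$end[shrinked],
                      td$end[merge_first], td$start[merge_first + 1])
  all_edges <- c(td$start, td$end)
  stable_edges <- setdiff(all_edges, variable_edges)

  ## --- contact maps --------------------------------------------------
  # variable boundaries are contact-leaky (weak) in WT; after the change
  # the moved expanded/shrinked boundaries stay leaky in KD
  kd_leaky <- c(kd_end[expanded], kd_end[shrinked])
  map_wt <- simulate_contact_map(wt_tads, cfg$chrom, cfg$chrom_length,
                                 cfg$bin_size, cfg$decay_alpha_wt,
                                 cfg$tad_boost, cfg$map_depth,
                                 seed = cfg$seed + 201L,
                                 leaky_boundaries = variable_edges,
                                 leak = cfg$boundary_leak)
  map_kd <- simulate_contact_map(kd_tads, cfg$chrom, cfg$chrom_length,
                                 cfg$bin_size, cfg$decay_alpha_kd,
                                 cfg$tad_boost, cfg$map_depth,
                                 seed = cfg$seed + 202L,
                                 leaky_boundaries = kd_leaky,
                                 leak = cfg$boundary_leak)

  ## --- loops -----------------------------------------------------------
  set.seed(cfg$seed + 401L)
  n_l <- cfg$n_loops
  n_enh <- round(cfg$fraction_enhanced * n_l)
  n_imp <- round(cfg$fraction_impaired * n_l)
  loop_class <- c(rep("enhanced", n_enh), rep("impaired", n_imp),
                  rep("unchanged", n_l - n_enh - n_imp))
  aw2 <- cfg$anchor_width / 2
  # 80% of loops sit inside a single WT TAD; the rest bridge adjacent
  # TADs near their shared boundary. Enhanced loops are planted longer.
  within <- stats::runif(n_l) < 0.8
  a1 <- a2 <- numeric(n_l)
  tlen <- td$end - td$start
  for (i in seq_len(n_l)) {
    if (within[i]) {
      t <- sample(n_tad, 1)
      dmax <- min(tlen[t] - 15000,
                  if (loop_class[i] == "impaired") 60e3 else 110e3)
      dmin <- if (loop_class[i] == "enhanced") 60e3 else 20e3
      d <- round(stats::runif(1, min(dmin, dmax), dmax))
      a1[i] <- round(stats::runif(1, td$start[t] + 7500,
                                  td$end[t] - d - 7500))
      a2[i] <- a1[i] + d
    } else {
      t <- sample(n_tad - 1, 1)
      a1[i] <- td$end[t] - round(stats::runif(1, 7500, 40e3))
      a2[i] <- td$start[t + 1] + round(stats::runif(1, 7500, 40e3))
    }
  }
  loops <- data.frame(
    chrom1 = cfg$chrom, start1 = a1 - aw2, end1 = a1 + aw2,
    chrom2 = cfg$chrom, start2 = a2 - aw2, end2 = a2 + aw2)
  counts <- simulate_loop_counts(loop_class, cfg$loop_base_mean,
                                 cfg$loop_fold_change, cfg$nb_dispersion,
                                 cfg$replicates, seed = cfg$seed + 402L)
  set.seed(cfg$seed + 403L)
  loops <- cbind(loops, as.data.frame(counts))
  loops$fdr <- stats::runif(n_l, 0, 0.005)

  ## --- binding sites and signals -------------------------------------
  set.seed(cfg$seed + 301L)
  n_s <- cfg$n_binding_sites
  is_switch <- seq_len(n_s) <= round(cfg$fraction_switch * n_s)
  # switch sites sit at enhanced-loop anchors and TAD boundaries more
  # often than non-switch sites, which favor impaired-loop anchors
  # a share of sites sits in tight clusters (regulatory hotspots): switch
  # clusters gain enough H3K27ac in KD to stitch into new super-enhancers
  placement <- character(n_s)
  u <- stats::runif(n_s)
  placement[is_switch] <- ifelse(u[is_switch] < 0.3, "anchor",
                                 ifelse(u[is_switch] < 0.55, "boundary",
                                        ifelse(u[is_switch] < 0.75,
                                               "cluster", "uniform")))
  placement[!is_switch] <- ifelse(u[!is_switch] < 0.3, "anchor",
                                  ifelse(u[!is_switch] < 0.4, "boundary",
                                         ifelse(u[!is_switch] < 0.5,
                                                "cluster", "uniform")))
  cl_sw <- round(stats::runif(20, 2e5, cfg$chrom_length - 2e5))
  # non-switch clusters include a few very strong ones that pin the top
  # of the signal-rank curve identically in both conditions
  cl_ns <- round(stats::runif(12, 2e5, cfg$chrom_length - 2e5))
  anchor_mid <- function(sub) c((sub$start1 + sub$end1) / 2,
                                (sub$start2 + sub$end2) / 2)
  enh_anchors <- anchor_mid(loops[loop_class == "enhanced", ])
  imp_anchors <- anchor_mid(loops[loop_class == "impaired", ])
  pos <- numeric(n_s)
  sel <- placement == "anchor" & is_switch
  pos[sel] <- sample(enh_anchors, sum(sel), replace = TRUE)
  sel <- placement == "anchor" & !is_switch
  pos[sel] <- sample(imp_anchors, sum(sel), replace = TRUE)
  # round-robin allocation keeps cluster sizes even, so no single cluster
  # outgrows the pinning clusters in either condition
  in_sw_cluster <- placement == "cluster" & is_switch
  sw_cl_id <- rep_len(seq_along(cl_sw), sum(in_sw_cluster))
  pos[in_sw_cluster] <- cl_sw[sw_cl_id] +
    round(stats::runif(sum(in_sw_cluster), -5000, 5000))
  in_ns_cluster <- placement == "cluster" & !is_switch
  ns_cl_id <- rep_len(seq_along(cl_ns), sum(in_ns_cluster))
  pos[in_ns_cluster] <- cl_ns[ns_cl_id] +
    round(stats::runif(sum(in_ns_cluster), -5000, 5000))
  is_pin <- rep(FALSE, n_s)
  is_pin[which(in_ns_cluster)[ns_cl_id <= 3]] <- TRUE
  sel <- placement == "boundary"
  pos[sel] <- sample(all_edges, sum(sel), replace = TRUE) +
    round(stats::runif(sum(sel), -8000, 8000))
  sel <- placement == "uniform"
  pos[sel] <- round(stats::runif(sum(sel), 1e5, cfg$chrom_length - 1e5))
  w2 <- cfg$site_width / 2
  sites <- intervals(cfg$chrom, pmax(pos - w2, 0), pos + w2,
                     name = sprintf("site%04d", seq_len(n_s)))
  eps <- cfg$epsilon
  d_stag2 <- stats::rnorm(n_s, cfg$stag2_loss_effect, cfg$switch_sd)
  d_stag1 <- stats::rnorm(n_s, ifelse(is_switch, cfg$switch_effect, 0),
                          cfg$switch_sd)
  d_smc1a <- stats::rnorm(n_s, 0, 0.2)
  d_ctcf <- stats::rnorm(n_s, 0, 0.2)
  d_h3k <- stats::rnorm(n_s, ifelse(is_switch, cfg$h3k27ac_coupling, 0), 0.3)
  # switch hotspots start quiet and activate strongly in KD (new
  # super-enhancers); non-switch clusters are strong in both conditions
  d_h3k[in_sw_cluster] <- stats::rnorm(sum(in_sw_cluster), 2.8, 0.15)
  d_h3k[in_ns_cluster] <- stats::rnorm(sum(in_ns_cluster), 0, 0.1)
  sig <- list(
    STAG2 = list(wt = stats::runif(n_s, 5, 15)),
    STAG1 = list(wt = stats::runif(n_s, 2, 8)),
    SMC1A = list(wt = stats::runif(n_s, 4, 12)),
    CTCF = list(wt = stats::runif(n_s, 4, 12)),
    H3K27ac = list(wt = ifelse(in_sw_cluster, stats::runif(n_s, 1.5, 2.5),
                               ifelse(is_pin, stats::runif(n_s, 22, 28),
                                      ifelse(in_ns_cluster,
                                             stats::runif(n_s, 8, 11),
                                             stats::runif(n_s, 2, 10)))))
  )
  deltas <- list(STAG2 = d_stag2, STAG1 = d_stag1, SMC1A = d_smc1a,
                 CTCF = d_ctcf, H3K27ac = d_h3k)
  for (f in names(sig))
    sig[[f]]$kd <- .kd_from_delta(sig[[f]]$wt, deltas[[f]], eps)
  site_tab <- signal_site_table(sites, sig, eps)

  ## --- boundary ChIP tracks (stable boundaries bind more cohesin) ----
  set.seed(cfg$seed + 351L)
  mk_track <- function(amp_stable, amp_var) {
    bump <- function(edges, amp) {
      if (length(edges) == 0) return(NULL)
      data.frame(chrom = cfg$chrom, start = pmax(edges - 5000, 0),
                 end = edges + 5000,
                 value = amp + stats::rnorm(length(edges), 0, amp * 0.1))
    }
    tr <- rbind(bump(sort(stable_edges), amp_stable),
                bump(sort(variable_edges), amp_var))
    tr <- tr[order(tr$start), , drop = FALSE]
    tr$value <- pmax(tr$value, 0)
    tr
  }
  track_stag2 <- mk_track(8, 3)
  track_ctcf <- mk_track(10, 4)

  ## --- genes, targets, expression ------------------------------------
  set.seed(cfg$seed + 501L)
  n_g <- cfg$n_genes
  gene_kind <- c(rep("target", cfg$n_targets),
                 rep("de_peak", cfg$n_de_peak_only),
                 rep("de_only", cfg$n_de_only),
                 rep("background", n_g - cfg$n_targets -
                       cfg$n_de_peak_only - cfg$n_de_only))
  tss <- round(stats::runif(n_g, 2e5, cfg$chrom_length - 2e5))
  pf <- cfg$promoter_flank
  loop_anchors <- rbind(
    data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1),
    data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2),
    # the promoter-side anchors of the target loops built further down
    data.frame(chrom = cfg$chrom,
               start = tss[gene_kind == "target"] - cfg$anchor_width / 2,
               end = tss[gene_kind == "target"] + cfg$anchor_width / 2))
  clear_of <- function(p, what) {
    prom <- data.frame(chrom = cfg$chrom, start = p - pf, end = p + pf)
    count_overlapping(prom, what) == 0
  }
  for (i in which(gene_kind == "de_peak")) {
    # promoter must never touch a loop anchor, whatever gets called
    while (!clear_of(tss[i], loop_anchors))
      tss[i] <- round(stats::runif(1, 2e5, cfg$chrom_length - 2e5))
  }
  # wire targets and de_peak genes: lost-STAG2 peak inside the promoter
  wire <- which(gene_kind %in% c("target", "de_peak"))
  extra_sites <- intervals(cfg$chrom, tss[wire] - 500, tss[wire] + 500,
                           name = sprintf("sitePr%03d", seq_along(wire)))
  lost_peaks <- rbind(sites, extra_sites)
  for (i in which(gene_kind == "de_only")) {
    # promoter clear of every loop anchor and every lost-STAG2 peak
    while (!clear_of(tss[i], loop_anchors) ||
             !clear_of(tss[i], lost_peaks))
      tss[i] <- round(stats::runif(1, 2e5, cfg$chrom_length - 2e5))
  }
  # wire targets: strong promoter-anchored enhanced loop whose distal
  # anchor stays clear of decoy-gene promoters
  ti <- which(gene_kind == "target")
  decoy_prom <- data.frame(
    chrom = cfg$chrom,
    start = tss[gene_kind %in% c("de_peak", "de_only")] - pf,
    end = tss[gene_kind %in% c("de_peak", "de_only")] + pf)
  tgt_a1 <- tss[ti]
  tgt_a2 <- tgt_a1 + round(stats::runif(length(ti), 50e3, 100e3))
  for (j in seq_along(tgt_a2)) {
    while (count_overlapping(data.frame(chrom = cfg$chrom,
                                        start = tgt_a2[j] - aw2,
                                        end = tgt_a2[j] + aw2),
                             decoy_prom) > 0)
      tgt_a2[j] <- tgt_a1[j] + round(stats::runif(1, 50e3, 100e3))
  }
  tgt_loops <- data.frame(
    chrom1 = cfg$chrom, start1 = tgt_a1 - aw2, end1 = tgt_a1 + aw2,
    chrom2 = cfg$chrom, start2 = tgt_a2 - aw2, end2 = tgt_a2 + aw2)
  # unambiguous positive controls: high depth, Poisson noise, big fold,
  # half enhanced / half impaired so condition totals stay balanced
  tgt_class <- rep(c("enhanced", "impaired"), length.out = length(ti))
  tgt_counts <- simulate_loop_counts(tgt_class,
                                     cfg$target_loop_mean,
                                     cfg$target_loop_fold,
                                     nb_dispersion = 0, cfg$replicates,
                                     seed = cfg$seed + 502L)
  set.seed(cfg$seed + 503L)
  tgt_loops <- cbind(tgt_loops, as.data.frame(tgt_counts))
  tgt_loops$fdr <- stats::runif(length(ti), 0, 0.005)
  all_loops <- canonicalize_loops(rbind(loops, tgt_loops))
  all_loops$name <- sprintf("loop%04d", seq_len(nrow(all_loops)))
  loop_truth <- c(loop_class, tgt_class)
  fold_of <- c(rep(cfg$loop_fold_change, n_l),
               rep(cfg$target_loop_fold, length(ti)))
  true_l2fc <- ifelse(loop_truth == "enhanced", log2(fold_of),
                      ifelse(loop_truth == "impaired", -log2(fold_of), 0))

  de <- gene_kind != "background"
  expr_fdr <- ifelse(de, stats::runif(n_g, 1e-6, 0.01),
                     stats::runif(n_g, 0.2, 0.9))
  expr_l2fc <- ifelse(de, sample(c(-1, 1), n_g, TRUE) *
                        stats::runif(n_g, 1, 3),
                      stats::rnorm(n_g, 0, 0.2))
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_g)),
    chrom = cfg$chrom, tss = tss,
    strand = sample(c("+", "-"), n_g, TRUE),
    expr_log2fc = round(expr_l2fc, 4), expr_fdr = expr_fdr,
    stringsAsFactors = FALSE)
  promoters <- intervals(cfg$chrom, pmax(tss - pf, 0), tss + pf,
                         name = genes$gene_id)
  set.seed(cfg$seed + 551L)
  enh_pos <- round(stats::runif(cfg$n_enhancers, 1e5,
                                cfg$chrom_length - 1e5))
  enhancers <- intervals(cfg$chrom, enh_pos - 500, enh_pos + 500,
                         name = sprintf("enh%03d",
                                        seq_len(cfg$n_enhancers)))

  # expression triplet with a planted sign flip: STAG2 tracks STAT1, and
  # CD274 = 2*STAT1 - STAG2 + noise, so the marginal STAG2~CD274 Spearman
  # is positive but turns negative after adjusting for STAT1
  set.seed(cfg$seed + 601L)
  ns <- cfg$n_expr_samples
  stat1 <- stats::rnorm(ns)
  stag2 <- stat1 + 0.5 * stats::rnorm(ns)
  cd274 <- 2 * stat1 - stag2 + 0.5 * stats::rnorm(ns)
  expr <- data.frame(sample = sprintf("s%03d", seq_len(ns)),
                     STAG2 = round(stag2, 6), STAT1 = round(stat1, 6),
                     CD274 = round(cd274, 6), stringsAsFactors = FALSE)

  ## --- write bundle ---------------------------------------------------
  utils::write.table(site_tab, path("sites_signal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_intervals(lost_peaks, path("lost_stag2_peaks.bed"))
  write_intervals(wt_tads, path("tads_wt.bed"))
  write_intervals(kd_tads, path("tads_kd.bed"))
  write_contact_map(map_wt, path("matrix_wt.txt"))
  write_contact_map(map_kd, path("matrix_kd.txt"))
  write_bedgraph(track_stag2, path("stag2_wt.bedgraph"))
  write_bedgraph(track_ctcf, path("ctcf_wt.bedgraph"))
  write_loops(all_loops[, c("chrom1", "start1", "end1", "chrom2", "start2",
                            "end2", colnames(counts), "fdr")],
              path("loops.bedpe"))
  utils::write.table(genes, path("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_intervals(promoters, path("promoters.bed"))
  write_intervals(enhancers, path("enhancers.bed"))
  utils::write.table(expr, path("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = cfg$seed,
    genome = list(chrom = cfg$chrom, length = cfg$chrom_length),
    site_switch = is_switch,
    tad_class = tad_class,
    n_merge_events = n_mrg,
    stable_edges = sort(stable_edges),
    variable_edges = sort(variable_edges),
    loop_class = loop_truth,
    loop_true_log2fc = true_l2fc,
    target_genes = genes$gene_id[gene_kind == "target"],
    gene_kind = gene_kind,
    effects = list(switch_effect = cfg$switch_effect,
                   loop_fold_change = cfg$loop_fold_change,
                   decay_alpha = c(wt = cfg$decay_alpha_wt,
                                   kd = cfg$decay_alpha_kd))
  )
  jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(
    config = cfg,
    genome = genome_spec(cfg$chrom, cfg$chrom_length),
    sites = site_tab, is_switch = is_switch,
    lost_peaks = lost_peaks,
    wt_tads = wt_tads, kd_tads = kd_tads, tad_class = tad_class,
    map_wt = map_wt, map_kd = map_kd,
    track_stag2 = track_stag2, track_ctcf = track_ctcf,
    stable_edges = stable_edges, variable_edges = variable_edges,
    loops = all_loops, loop_class = loop_truth,
    genes = genes, gene_kind = gene_kind,
    promoters = promoters, enhancers = enhancers,
    expr = expr, truth = truth, dir = out_dir
  ))
}
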