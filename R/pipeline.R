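#' Pipeline configuration
#'
#' Collects every stage threshold (defaults are the study's printed
#' values) plus the synthetic-data configuration and the seed that drives
#' all randomness.
#'
#' @param seed integer seed for the whole run.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param fdr_malignancy SAM FDR cutoff for the malignancy screen (0.05).
#' @param fdr_survival SAM FDR cutoff for the survival screen (0.10).
#' @param fc_min minimal linear fold change (1.5).
#' @param golub_p Golub score p cutoff (0.01).
#' @param rho_cis,rho_trans Spearman cutoffs (0.5 strict / 0.7 inclusive).
#' @param p_corr correlation p cutoff (0.05).
#' @param abundance_frac top-abundance fraction for the trans screen (0.2).
#' @param fet_cut tissue-specificity cutoff on the maximum F.E.T. (0.5).
#' @param max_dist,bin TSS-distance window and histogram bin (10 kb / 1 kb).
#' @param n_controls number of random control sets (10).
#' @param n_perm permutations for SAM and Golub (1000).
#' @param module_alpha Bonferroni-adjusted significance level for the GO
#'   module map (0.05).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            fdr_malignancy = 0.05, fdr_survival = 0.10,
                            fc_min = 1.5, golub_p = 0.01,
                            rho_cis = 0.5, rho_trans = 0.7, p_corr = 0.05,
                            abundance_frac = 0.2, fet_cut = 0.5,
                            max_dist = 10000, bin = 1000,
                            n_controls = 10L, n_perm = 1000L,
                            module_alpha = 0.05) {
  structure(list(seed = as.integer(seed), sim = sim,
                 fdr_malignancy = fdr_malignancy,
                 fdr_survival = fdr_survival, fc_min = fc_min,
                 golub_p = golub_p, rho_cis = rho_cis,
                 rho_trans = rho_trans, p_corr = p_corr,
                 abundance_frac = abundance_frac, fet_cut = fet_cut,
                 max_dist = max_dist, bin = bin,
                 n_controls = as.integer(n_controls),
                 n_perm = as.integer(n_perm),
                 module_alpha = module_alpha),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate, preprocess, signatures, co-expression, genomic
#' context, specificity/conservation and concordance bookkeeping in
#' sequence, returning every stage result plus a machine-readable summary.
#' With `out_dir` set, the summary is written as JSON alongside the main
#' result tables as TSV.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return an object of class `rcc_pipeline`: a list of stage results and
#'   a `summary` list with every headline statistic.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  ## ---- simulate -------------------------------------------------------
  ds <- simulate_rcc_dataset(config$sim)
  study <- ds$study; truth <- ds$truth
  probes <- study$probes
  neg_ids <- probes$probe_id[probes$class == "negative_control"]
  lnc_classes <- c("intronic_antisense", "lincRNA")
  lnc_ids <- probes$probe_id[probes$class %in% lnc_classes]

  ## ---- preprocess: paired design -------------------------------------
  det <- detect_expressed(study$intensities, neg_ids,
                          detection_rule(k_sd = 3, scope = "per_array"))
  retained <- filter_by_prevalence(det, study$samples$status, 0.9)
  retained <- setdiff(retained, neg_ids)
  norm <- quantile_normalize(study$intensities)
  pairing <- data.frame(tumor = sprintf("T%02d", seq_len(config$sim$n_pairs)),
                        nontumor = sprintf("N%02d", seq_len(config$sim$n_pairs)))
  ratios <- log2_ratio(norm[retained, , drop = FALSE], pairing)

  ## ---- malignancy signature ------------------------------------------
  set.seed(sub_seed(config$seed, 11L))
  lnc_rows <- intersect(rownames(ratios), lnc_ids)
  malignancy <- leave_one_out_signature(ratios[lnc_rows, , drop = FALSE],
                                        fdr_cut = config$fdr_malignancy,
                                        fc_min = config$fc_min,
                                        n_perm = config$n_perm)
  sig_ids <- malignancy$probes$probe_id[malignancy$probes$final]
  de_truth <- names(truth$de_probes)
  de_eval <- list(
    sensitivity = if (length(de_truth))
      mean(de_truth %in% sig_ids) else NA_real_,
    fdp = if (length(sig_ids))
      mean(!sig_ids %in% de_truth) else 0)

  ## ---- survival signature --------------------------------------------
  set.seed(sub_seed(config$seed, 12L))
  surv_norm <- quantile_normalize(study$survival_intensities)
  surv_det <- detect_expressed(study$survival_intensities, neg_ids,
                               detection_rule(k_sd = 3, scope = "per_array"))
  surv_keep <- filter_by_prevalence(surv_det, study$survival_samples$outcome,
                                    0.9)
  surv_keep <- intersect(surv_keep,
                         probes$probe_id[probes$class == "intronic_antisense"])
  survival <- survival_signature(log2(surv_norm[surv_keep, , drop = FALSE]),
                                 study$survival_samples$outcome,
                                 sam_fdr = config$fdr_survival,
                                 golub_p = config$golub_p,
                                 n_perm = config$n_perm)
  surv_truth <- names(truth$survival_probes)
  surv_sens <- if (length(surv_truth)) mean(surv_truth %in% survival$genes)
    else NA_real_

  ## ---- pooled design + co-expression ---------------------------------
  pool_det <- detect_expressed(study$pools, neg_ids,
                               detection_rule(k_sd = 2, min_arrays = 3,
                                              scope = "per_group"),
                               groups = study$pool_groups)
  as_ids <- probes$probe_id[probes$class == "intronic_antisense"]
  expressed_lnc <- intersect(names(which(pool_det$expressed)), as_ids)
  pool_norm <- quantile_normalize(study$pools)
  tissue <- ds$tissue
  cis <- cis_correlation(tissue$lnc_expr, tissue$mrna_expr,
                         tissue$locus_map, rho_cut = config$rho_cis,
                         p_cut = config$p_corr)
  cis_truth <- truth$cis_pairs$lnc
  cis_sens <- if (length(cis_truth)) mean(cis_truth %in% cis$records$lnc_id)
    else NA_real_
  tumor_cols <- grep("^tumor", colnames(pool_norm))
  top_ids <- select_top_abundant(
    pool_norm[intersect(expressed_lnc, rownames(tissue$lnc_expr)),
              tumor_cols, drop = FALSE],
    frac = config$abundance_frac)
  trans <- trans_correlation(tissue$lnc_expr[top_ids, , drop = FALSE],
                             tissue$mrna_expr, tissue$locus_map,
                             rho_cut = config$rho_trans,
                             p_cut = config$p_corr)
  modmap <- go_module_map(trans, tissue$go_annotation,
                          background = rownames(tissue$mrna_expr),
                          alpha = config$module_alpha)

  ## ---- genomic context ------------------------------------------------
  context <- ds$context
  lnc_gr <- context$lnc
  queries <- tss_granges(lnc_gr)
  controls <- make_random_controls(GenomicRanges::width(lnc_gr),
                                   context$seqlengths,
                                   exclusions = context$exclusions,
                                   n_sets = config$n_controls,
                                   seed = sub_seed(config$seed, 13L))
  control_pts <- lapply(controls, function(g)
    GenomicRanges::resize(g, 1L, fix = "start", ignore.strand = TRUE))
  tracks <- context$tracks
  tracks$cage <- filter_track_by_score(tracks$cage, "rpkm", 1)
  ks <- lapply(tracks[setdiff(names(tracks), "h3k36me3")], function(tr) {
    qd <- distance_distribution(queries, tr, config$max_dist, config$bin)
    cd <- lapply(control_pts, distance_distribution, track = tr,
                 max_dist = config$max_dist, bin = config$bin)
    list(query = qd, ks = ks_enrichment_test(qd, cd))
  })
  k36 <- overlap_count(lnc_gr, tracks$h3k36me3)

  ## ---- specificity & conservation ------------------------------------
  fet_lnc <- fraction_expression(tissue$lnc_fpkm, config$fet_cut)
  fet_mrna <- fraction_expression(tissue$mrna_fpkm, config$fet_cut)
  spec_fish <- specificity_fisher(fet_lnc$specific, fet_mrna$specific)
  cons <- conservation_enrichment(lnc_gr, tissue$conserved_elements, controls)
  expr_cons <- expression_conservation(lnc_gr, tissue$species_tracks)
  syn <- syntenic_overlap(lnc_gr, tissue$synteny$mapped_foreign,
                          tissue$synteny$null_queries)

  ## ---- concordance bookkeeping on the packaged tables ----------------
  t1 <- rcc_table1()
  reg <- classify_regulation(t1$lnc_fc)
  intronic <- t1[t1$type == "Intronic", ]
  host <- host_gene_concordance(intronic$lnc_fc, intronic$host_fc,
                                fc_min = config$fc_min)
  t2 <- rcc_table2()
  t2_pct <- vapply(seq_len(nrow(t2)), function(i)
    concordance_report(t2$n_common[i], t2$n_concordant[i])$pct_concordance,
    numeric(1))

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_probes = nrow(probes),
    n_retained_paired = length(retained),
    malignancy_signature_size = malignancy$n_final,
    malignancy_sensitivity = de_eval$sensitivity,
    malignancy_fdp = de_eval$fdp,
    survival_signature_size = length(survival$genes),
    survival_sensitivity = surv_sens,
    n_expressed_lnc_pooled = length(expressed_lnc),
    cis_n_passing = cis$summary$n_passing,
    cis_pct_of_full = cis$summary$pct_of_full,
    cis_sensitivity = cis_sens,
    n_top_abundant = length(top_ids),
    trans_n_lnc = trans$summary$n_lnc,
    trans_mean_partners = trans$summary$mean_partners,
    module_map_enriched_cells = sum(modmap$sign != 0),
    ks_max_p = vapply(ks, function(k) k$ks$max_p, numeric(1)),
    h3k36me3_total_overlaps = sum(k36),
    specificity_fisher_p = spec_fish$p,
    conservation_max_fisher_p = cons$max_p,
    conservation_pct = report_fraction(cons$n_overlapping, cons$n_total, 0),
    expression_conservation_pct = expr_cons$pct,
    synteny_fisher_p = syn$fisher_p,
    table1_n_up = reg$n_up, table1_n_down = reg$n_down,
    host_n_altered = host$n_altered, host_n_concordant = host$n_concordant,
    host_n_inverse = host$n_inverse,
    table2_pct = stats::setNames(t2_pct, t2$study)
  )

  res <- structure(list(
    config = config, truth = truth,
    preprocess = list(detection = det, retained = retained),
    malignancy = malignancy, survival = survival,
    cis = cis, trans = trans, module_map = modmap,
    ks = ks, h3k36me3 = k36,
    fet = list(lnc = fet_lnc, mrna = fet_mrna, fisher = spec_fish),
    conservation = cons, expression_conservation = expr_cons,
    synteny = syn, table1 = t1, table2 = t2,
    summary = summary
  ), class = "rcc_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(res$malignancy$probes,
                     file.path(out_dir, "malignancy_signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$cis$records, file.path(out_dir, "cis_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$trans$records,
                     file.path(out_dir, "trans_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$module_map),
                     file.path(out_dir, "module_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.rcc_pipeline <- function(x, ...) {
  s <- x$summary
  cat("RCC intronic lncRNA pipeline run\n")
  cat(sprintf("  malignancy signature: %d probes (sensitivity %.2f, FDP %.2f)\n",
              s$malignancy_signature_size, s$malignancy_sensitivity,
              s$malignancy_fdp))
  cat(sprintf("  survival signature: %d genes (sensitivity %.2f)\n",
              s$survival_signature_size, s$survival_sensitivity))
  cat(sprintf("  cis-correlated: %d lncRNAs (%g%% of set, sensitivity %.2f)\n",
              s$cis_n_passing, s$cis_pct_of_full, s$cis_sensitivity))
  cat(sprintf("  trans: %d lncRNAs, mean %.1f partners | module map: %d enriched cells\n",
              s$trans_n_lnc, s$trans_mean_partners,
              s$module_map_enriched_cells))
  cat(sprintf("  KS max p across tracks: %.3g | conservation max Fisher p: %.3g\n",
              max(s$ks_max_p), s$conservation_max_fisher_p))
  invisible(x)
}
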