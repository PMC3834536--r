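#' Simulate the paired and pooled microarray study with planted ground truth
#'
#' Generates log-normal probe intensities for (i) the paired tumor/nontumor
#' cDNA-array design, (ii) the survival cohort of tumor arrays, and (iii) the
#' pooled strand-specific oligoarray design (four tumor and four nontumor
#' pools), together with a `planted_truth` object naming every planted
#' differential-expression, survival, co-expression, genomic-mark and
#' conservation feature. Negative-control probes are drawn from the
#' background-noise distribution only, which is what makes the
#' "mean + k SD of negative controls" detection rule meaningful.
#'
#' Log2 intensities follow probe baseline + array effect + Gaussian noise;
#' planted differentially expressed probes are shifted by
#' `planted_log2fc` (with a random sign per probe) in tumor samples, and
#' planted survival probes are shifted between the outcome groups.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `study` (class `expression_study`) and
#'   `truth` (class `planted_truth`). The study holds linear-scale intensity
#'   matrices (`intensities`, `survival_intensities`, `pools`), sample tables
#'   and the probe annotation; the truth holds the planted id sets.
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))

  npc <- config$n_probes_by_class
  probe_ids <- list(
    intronic_antisense = sprintf("aslnc%04d", seq_len(npc[["intronic_antisense"]])),
    protein_coding     = sprintf("pc%04d",   seq_len(npc[["protein_coding"]])),
    lincRNA            = sprintf("linc%04d", seq_len(npc[["lincRNA"]])),
    negative_control   = sprintf("neg%04d",  seq_len(npc[["negative_control"]]))
  )
  gene_ids <- sprintf("gene%04d", seq_len(npc[["protein_coding"]]))
  as_ids   <- probe_ids$intronic_antisense
  lnc_ids  <- c(as_ids, probe_ids$lincRNA)

  host <- sample(gene_ids, length(as_ids), replace = TRUE)
  probes <- data.frame(
    probe_id = unlist(probe_ids, use.names = FALSE),
    class = rep(names(probe_ids), times = lengths(probe_ids)),
    host_gene = NA_character_,
    gene_id = NA_character_,
    stringsAsFactors = FALSE
  )
  probes$host_gene[match(as_ids, probes$probe_id)] <- host
  probes$gene_id[match(probe_ids$protein_coding, probes$probe_id)] <- gene_ids

  ## ---- planted truth --------------------------------------------------
  pick <- function(ids, frac) sort(sample(ids, round(frac * length(ids))))
  de_ids <- pick(lnc_ids, config$frac_de)
  de_sign <- stats::setNames(sample(c(-1, 1), length(de_ids), replace = TRUE),
                             de_ids)
  surv_ids <- pick(as_ids, config$frac_survival)
  surv_sign <- stats::setNames(sample(c(-1, 1), length(surv_ids), replace = TRUE),
                               surv_ids)
  ## cis pairs need distinct hosts (one shared latent per host gene)
  cis_cand <- as_ids[!duplicated(host)]
  n_cis <- min(round(config$frac_cis * length(as_ids)), length(cis_cand))
  cis_ids <- sort(sample(cis_cand, n_cis))
  cis_sign <- stats::setNames(sample(c(-1, 1), length(cis_ids), replace = TRUE),
                              cis_ids)
  cis_hosts <- probes$host_gene[match(cis_ids, probes$probe_id)]
  ## trans modules live on lncRNAs and mRNAs untouched by the cis planting;
  ## modules are pairwise disjoint so each mRNA tracks one latent profile
  trans_cand <- setdiff(as_ids, cis_ids)
  trans_pool <- sample(setdiff(gene_ids, cis_hosts))
  n_trans <- min(round(config$frac_trans * length(trans_cand)),
                 floor(length(trans_pool) / config$trans_module_size))
  trans_ids <- sort(sample(trans_cand, n_trans))
  trans_modules <- list()
  spare_at <- n_trans * config$trans_module_size  # unused tail of the pool
  for (i in seq_along(trans_ids)) {
    id <- trans_ids[i]
    chunk <- trans_pool[seq.int((i - 1) * config$trans_module_size + 1,
                                i * config$trans_module_size)]
    own <- probes$host_gene[probes$probe_id == id]
    if (own %in% chunk) {   # never correlate a lncRNA with its own host here
      if (spare_at < length(trans_pool)) {
        spare_at <- spare_at + 1L
        chunk[chunk == own] <- trans_pool[spare_at]
      } else {
        chunk <- setdiff(chunk, own)
      }
    }
    trans_modules[[id]] <- sort(chunk)
  }
  truth <- structure(list(
    de_probes = de_sign,
    survival_probes = surv_sign,
    cis_pairs = data.frame(lnc = cis_ids,
                           host = probes$host_gene[match(cis_ids, probes$probe_id)],
                           sign = unname(cis_sign), stringsAsFactors = FALSE),
    trans_modules = trans_modules,
    marked_tss = pick(as_ids, config$frac_marked),
    conserved_lnc = pick(as_ids, config$frac_conserved),
    tissue_specific_lnc = pick(as_ids, config$frac_tissue_specific_lnc)
  ), class = "planted_truth")

  ## ---- intensity model (log2 scale) -----------------------------------
  mu_class <- c(intronic_antisense = 8.5, protein_coding = 10,
                lincRNA = 8.5, negative_control = 6)
  n_probes <- nrow(probes)
  baseline <- mu_class[probes$class] +
    ifelse(probes$class == "negative_control", 0, stats::rnorm(n_probes, 0, 0.8))

  de_shift <- numeric(n_probes)
  de_shift[match(de_ids, probes$probe_id)] <- de_sign * config$planted_log2fc

  draw <- function(n_arrays, tumor_cols, shift) {
    arr <- stats::rnorm(n_arrays, 0, 0.15)
    m <- matrix(baseline, n_probes, n_arrays) +
      matrix(arr, n_probes, n_arrays, byrow = TRUE) +
      matrix(stats::rnorm(n_probes * n_arrays, 0, config$noise_sd),
             n_probes, n_arrays)
    if (length(tumor_cols)) m[, tumor_cols] <- m[, tumor_cols] + shift
    m
  }

  np <- config$n_pairs
  tumor_cols <- seq_len(np)
  log2_paired <- draw(2L * np, tumor_cols, de_shift)
  samples <- data.frame(
    sample_id = c(sprintf("T%02d", seq_len(np)), sprintf("N%02d", seq_len(np))),
    patient = rep(sprintf("P%02d", seq_len(np)), 2),
    status = rep(c("tumor", "nontumor"), each = np),
    pair = rep(seq_len(np), 2),
    stringsAsFactors = FALSE
  )
  colnames(log2_paired) <- samples$sample_id
  rownames(log2_paired) <- probes$probe_id

  ## survival cohort: tumor arrays only, planted probes shifted in the dead group
  ns <- config$n_survival
  dead_cols <- seq_len(ns / 2)
  surv_shift <- numeric(n_probes)
  surv_shift[match(surv_ids, probes$probe_id)] <- surv_sign * config$planted_log2fc
  log2_surv <- draw(ns, dead_cols, surv_shift)
  survival_samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(ns)),
    outcome = rep(c("dead", "alive"), each = ns / 2),
    stringsAsFactors = FALSE
  )
  colnames(log2_surv) <- survival_samples$sample_id
  rownames(log2_surv) <- probes$probe_id

  ## pooled 44k-style design: 4 tumor + 4 nontumor pools
  log2_pools <- draw(8L, 1:4, de_shift)
  pool_groups <- rep(c("tumor", "nontumor"), each = 4)
  colnames(log2_pools) <- sprintf("%s_pool%d", pool_groups, rep(1:4, 2))
  rownames(log2_pools) <- probes$probe_id

  study <- structure(list(
    intensities = 2^log2_paired,
    samples = samples,
    survival_intensities = 2^log2_surv,
    survival_samples = survival_samples,
    pools = 2^log2_pools,
    pool_groups = pool_groups,
    probes = probes
  ), class = "expression_study")

  list(study = study, truth = truth)
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Synthetic expression study\n")
  cat(sprintf("  %d probes (%s)\n", nrow(x$probes),
              paste(sprintf("%s %d", names(table(x$probes$class)),
                            as.integer(table(x$probes$class))), collapse = ", ")))
  cat(sprintf("  paired design: %d arrays | survival cohort: %d | pools: %d\n",
              ncol(x$intensities), ncol(x$survival_intensities), ncol(x$pools)))
  invisible(x)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted ground truth\n")
  cat(sprintf("  DE probes %d | survival %d | cis pairs %d | trans modules %d\n",
              length(x$de_probes), length(x$survival_probes),
              nrow(x$cis_pairs), length(x$trans_modules)))
  cat(sprintf("  marked TSS %d | conserved %d | tissue-specific %d\n",
              length(x$marked_tss), length(x$conserved_lnc),
              length(x$tissue_specific_lnc)))
  invisible(x)
}
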