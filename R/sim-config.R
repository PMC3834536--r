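#' Configuration for the synthetic RCC lncRNA dataset
#'
#' Bundles every tunable of the synthetic-data generator: the paired
#' tumor/nontumor array design, the pooled strand-specific design, the planted
#' differential-expression / survival / co-expression / genomic-mark /
#' conservation ground truth, and the toy genome. Defaults mirror the study
#' design the pipeline targets: 11 tumor/nontumor pairs, a 16-patient
#' survival cohort split 8/8, four expression pools per group, planted fold
#' changes of at least 1.5, and nine tissues for the fraction-of-expression
#' statistic.
#'
#' @param seed integer global seed; ordered sub-seeds are derived from it so
#'   each generator stage is independently reproducible.
#' @param n_pairs number of tumor/nontumor sample pairs (>= 3).
#' @param n_probes_by_class named integer vector of probe counts per class;
#'   names must include `intronic_antisense`, `protein_coding`, `lincRNA`
#'   and `negative_control`.
#' @param frac_de fraction of lncRNA probes (intronic antisense + lincRNA)
#'   with planted tumor/nontumor differential expression.
#' @param planted_log2fc planted effect size in log2 units (>= log2(1.5)).
#' @param frac_survival fraction of intronic antisense probes with a planted
#'   survival-outcome association.
#' @param n_survival size of the survival cohort (tumor arrays, split evenly
#'   into dead / alive groups).
#' @param n_tissues number of tissues in the cross-tissue correlation design
#'   the pipeline accepts (the study design uses 4).
#' @param n_corr_tissues number of pseudo-tissue columns the generator emits
#'   for correlation tables (>= 8; rank correlations on 4 points have
#'   degenerate p-values, so power experiments need more columns).
#' @param n_fet_tissues number of tissues in the FPKM table (9 in the design
#'   emulated).
#' @param frac_cis fraction of lncRNA/host pairs with planted cross-tissue
#'   correlation.
#' @param frac_trans fraction of lncRNAs carrying a planted trans module.
#' @param trans_module_size number of mRNA partners per planted trans module.
#' @param frac_marked fraction of lncRNA TSSs with planted proximal genomic
#'   marks.
#' @param mark_decay_bp exponential scale (bp) of planted mark-to-TSS
#'   distances.
#' @param frac_conserved fraction of lncRNAs overlapping planted conserved
#'   elements (and carrying cross-species expression hits).
#' @param conserved_background background probability that a random interval
#'   overlaps a conserved element.
#' @param frac_tissue_specific_lnc,frac_tissue_specific_mrna fractions of
#'   rows planted tissue-specific (one tissue carrying >= 50\% of FPKM).
#' @param n_species number of cross-species cDNA tracks.
#' @param genome_length_bp total toy-genome length in bp.
#' @param n_chroms number of chromosomes.
#' @param noise_sd intensity noise SD on the log2 scale.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_pairs = 5,
#'                   n_probes_by_class = c(intronic_antisense = 60,
#'                                         protein_coding = 40,
#'                                         lincRNA = 10,
#'                                         negative_control = 20))
sim_config <- function(seed = 1L,
                       n_pairs = 11L,
                       n_probes_by_class = c(intronic_antisense = 600L,
                                             protein_coding = 250L,
                                             lincRNA = 50L,
                                             negative_control = 100L),
                       frac_de = 0.1,
                       planted_log2fc = 1.0,
                       frac_survival = 0.05,
                       n_survival = 16L,
                       n_tissues = 4L,
                       n_corr_tissues = 12L,
                       n_fet_tissues = 9L,
                       frac_cis = 0.3,
                       frac_trans = 0.05,
                       trans_module_size = 8L,
                       frac_marked = 0.5,
                       mark_decay_bp = 500,
                       frac_conserved = 0.6,
                       conserved_background = 0.05,
                       frac_tissue_specific_lnc = 0.3,
                       frac_tissue_specific_mrna = 0.1,
                       n_species = 15L,
                       genome_length_bp = 6e7,
                       n_chroms = 4L,
                       noise_sd = 0.3) {
  fracs <- c(frac_de = frac_de, frac_survival = frac_survival,
             frac_cis = frac_cis, frac_trans = frac_trans,
             frac_marked = frac_marked, frac_conserved = frac_conserved,
             conserved_background = conserved_background,
             frac_tissue_specific_lnc = frac_tissue_specific_lnc,
             frac_tissue_specific_mrna = frac_tissue_specific_mrna)
  if (any(fracs < 0 | fracs > 1))
    stopf("all fractions must lie in [0, 1]; offending: %s",
          paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (planted_log2fc < log2(1.5))
    stopf("planted_log2fc must be >= log2(1.5) = %.4f", log2(1.5))
  if (n_pairs < 3) stopf("n_pairs must be >= 3 (got %d)", n_pairs)
  req <- c("intronic_antisense", "protein_coding", "lincRNA",
           "negative_control")
  if (!all(req %in% names(n_probes_by_class)))
    stopf("n_probes_by_class must name classes: %s",
          paste(req, collapse = ", "))
  if (n_probes_by_class[["negative_control"]] < 2)
    stopf("need >= 2 negative-control probes to estimate a detection SD")
  if (n_survival < 4 || n_survival %% 2 != 0)
    stopf("n_survival must be an even number >= 4")
  if (n_corr_tissues < 8)
    stopf("n_corr_tissues must be >= 8 for usable rank-correlation p-values")
  if (noise_sd <= 0) stopf("noise_sd must be positive")

  cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
              n_probes_by_class = vapply(n_probes_by_class, as.integer, 1L),
              frac_de = frac_de, planted_log2fc = planted_log2fc,
              frac_survival = frac_survival,
              n_survival = as.integer(n_survival),
              n_tissues = as.integer(n_tissues),
              n_corr_tissues = as.integer(n_corr_tissues),
              n_fet_tissues = as.integer(n_fet_tissues),
              frac_cis = frac_cis, frac_trans = frac_trans,
              trans_module_size = as.integer(trans_module_size),
              frac_marked = frac_marked, mark_decay_bp = mark_decay_bp,
              frac_conserved = frac_conserved,
              conserved_background = conserved_background,
              frac_tissue_specific_lnc = frac_tissue_specific_lnc,
              frac_tissue_specific_mrna = frac_tissue_specific_mrna,
              n_species = as.integer(n_species),
              genome_length_bp = genome_length_bp,
              n_chroms = as.integer(n_chroms),
              noise_sd = noise_sd)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic RCC lncRNA dataset configuration\n")
  cat(sprintf("  seed %d | %d tumor/nontumor pairs | survival cohort %d\n",
              x$seed, x$n_pairs, x$n_survival))
  cat(sprintf("  probes: %s\n",
              paste(sprintf("%s=%d", names(x$n_probes_by_class),
                            x$n_probes_by_class), collapse = ", ")))
  cat(sprintf("  planted: DE %.0f%% @ %.2f log2 | survival %.0f%% | cis %.0f%% | marked %.0f%% | conserved %.0f%%\n",
              100 * x$frac_de, x$planted_log2fc, 100 * x$frac_survival,
              100 * x$frac_cis, 100 * x$frac_marked, 100 * x$frac_conserved))
  cat(sprintf("  genome: %.0f bp over %d chromosomes | noise SD %.2f (log2)\n",
              x$genome_length_bp, x$n_chroms, x$noise_sd))
  invisible(x)
}
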