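#' Simulate cross-tissue expression, FPKM, conservation and GO inputs
#'
#' Produces (i) lncRNA and mRNA expression tables across pseudo-tissue
#' columns with planted cis pairs (lncRNA correlated with its own host's
#' mRNA through a shared latent profile) and planted trans modules (a
#' lncRNA correlated with a set of mRNAs from other loci); (ii) per-tissue
#' FPKM tables with planted tissue-specific rows (one tissue carrying at
#' least half the total FPKM); (iii) a conserved-element track overlapping
#' the planted conserved lncRNAs, with non-conserved lncRNAs overlapping
#' only at the configured background rate; (iv) per-species cDNA tracks
#' hitting the conserved lncRNAs; (v) a synthetic mouse-synteny input pair
#' (lifted foreign intervals plus a non-expressed null query set); and
#' (vi) a flat gene-to-term GO-style annotation in which each planted trans
#' module seeds one term.
#'
#' @param config a [sim_config()] object.
#' @param truth the `planted_truth` from [simulate_expression_study()].
#' @param study the matching `expression_study`.
#' @param context the matching `genomic_context`.
#' @return an object of class `tissue_profiles`: a list with `lnc_expr`,
#'   `mrna_expr`, `locus_map`, `lnc_fpkm`, `mrna_fpkm`,
#'   `conserved_elements`, `species_tracks`, `synteny` (list with
#'   `mapped_foreign` and `null_queries`) and `go_annotation`.
#' @export
simulate_tissue_profiles <- function(config, truth, study, context) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "planted_truth"),
            inherits(study, "expression_study"),
            inherits(context, "genomic_context"))
  set.seed(sub_seed(config$seed, 3L))

  probes <- study$probes
  as_ids <- probes$probe_id[probes$class == "intronic_antisense"]
  gene_ids <- probes$gene_id[probes$class == "protein_coding"]
  nt <- config$n_corr_tissues
  tissues <- sprintf("tissue%02d", seq_len(nt))

  ## ---- correlation tables --------------------------------------------
  noise <- 0.35
  lnc_expr <- matrix(stats::rnorm(length(as_ids) * nt, 8, 1),
                     length(as_ids), nt,
                     dimnames = list(as_ids, tissues))
  mrna_expr <- matrix(stats::rnorm(length(gene_ids) * nt, 10, 1),
                      length(gene_ids), nt,
                      dimnames = list(gene_ids, tissues))
  for (i in seq_len(nrow(truth$cis_pairs))) {
    z <- stats::rnorm(nt)
    p <- truth$cis_pairs[i, ]
    lnc_expr[p$lnc, ] <- 8 + p$sign * z + stats::rnorm(nt, 0, noise)
    mrna_expr[p$host, ] <- 10 + z + stats::rnorm(nt, 0, noise)
  }
  for (id in names(truth$trans_modules)) {
    z <- stats::rnorm(nt)
    lnc_expr[id, ] <- 8 + z + stats::rnorm(nt, 0, noise)
    for (g in truth$trans_modules[[id]]) {
      sgn <- sample(c(-1, 1), 1)
      mrna_expr[g, ] <- 10 + sgn * z + stats::rnorm(nt, 0, noise)
    }
  }
  locus_map <- data.frame(lnc = as_ids,
                          gene = probes$host_gene[match(as_ids, probes$probe_id)],
                          stringsAsFactors = FALSE)

  ## ---- FPKM tables ----------------------------------------------------
  fet_tissues <- sprintf("fet_tissue%d", seq_len(config$n_fet_tissues))
  make_fpkm <- function(ids, specific_ids) {
    m <- matrix(stats::rexp(length(ids) * length(fet_tissues), 1 / 3),
                length(ids), length(fet_tissues),
                dimnames = list(ids, fet_tissues))
    for (id in specific_ids) {
      row <- stats::rexp(length(fet_tissues), 1)
      row[sample(length(fet_tissues), 1)] <- stats::runif(1, 20, 40)
      m[id, ] <- row
    }
    m
  }
  n_sp_mrna <- round(config$frac_tissue_specific_mrna * length(gene_ids))
  lnc_fpkm <- make_fpkm(as_ids, truth$tissue_specific_lnc)
  mrna_fpkm <- make_fpkm(gene_ids, sample(gene_ids, n_sp_mrna))

  ## ---- conserved elements --------------------------------------------
  lnc <- context$lnc
  seqlens <- context$seqlengths
  conserved <- names(lnc) %in% truth$conserved_lnc
  bg_hit <- !conserved &
    stats::runif(length(lnc)) < config$conserved_background
  overlap_element <- function(sel) {
    w <- pmin(sample(30:300, sum(sel), replace = TRUE),
              GenomicRanges::width(lnc)[sel])
    off <- floor(stats::runif(sum(sel)) *
                   (GenomicRanges::width(lnc)[sel] - w + 1L))
    st <- GenomicRanges::start(lnc)[sel] + off
    GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(lnc))[sel],
                           IRanges::IRanges(st, st + w - 1L),
                           seqlengths = seqlens)
  }
  conserved_elements <- c(overlap_element(conserved), overlap_element(bg_hit),
                          random_intervals(sample(30:300, 50, replace = TRUE),
                                           seqlens))

  ## ---- cross-species cDNA tracks -------------------------------------
  species <- sprintf("species%02d", seq_len(config$n_species))
  n_hits <- 1L + stats::rbinom(sum(conserved), config$n_species - 1L, 0.25)
  hit_species <- lapply(n_hits, function(k) sample(species, k))
  species_tracks <- lapply(stats::setNames(species, species), function(sp) {
    sel <- which(conserved)[vapply(hit_species, function(h) sp %in% h, TRUE)]
    take <- rep(FALSE, length(lnc)); take[sel] <- TRUE
    c(overlap_element(take),
      random_intervals(sample(200:800, 20, replace = TRUE), seqlens))
  })

  ## ---- mouse-synteny inputs ------------------------------------------
  n_syn <- max(1L, round(53 / 4303 * length(lnc)))
  syn_sel <- rep(FALSE, length(lnc))
  syn_sel[sample(length(lnc), n_syn)] <- TRUE
  null_queries <- random_intervals(
    GenomicRanges::width(lnc)[sample(length(lnc), length(lnc), replace = FALSE)],
    seqlens)
  names(null_queries) <- sprintf("null%04d", seq_along(null_queries))
  n_null_hit <- max(1L, round(23 / 4303 * length(null_queries)))
  null_hit <- null_queries[sample(length(null_queries), n_null_hit)]
  mapped_foreign <- c(overlap_element(syn_sel),
                      GenomicRanges::resize(null_hit, pmax(
                        30L, GenomicRanges::width(null_hit) %/% 2L),
                        fix = "center", ignore.strand = TRUE),
                      random_intervals(sample(200:1200, 30, replace = TRUE),
                                       seqlens))
  GenomicRanges::strand(mapped_foreign) <- "*"
  names(mapped_foreign) <- NULL

  ## ---- GO-style annotation -------------------------------------------
  go <- list()
  for (id in names(truth$trans_modules)) {
    term <- sprintf("GO:MOD_%s", id)
    members <- unique(c(truth$trans_modules[[id]], sample(gene_ids, 5)))
    go[[term]] <- members
  }
  for (k in seq_len(30)) {
    go[[sprintf("GO:RND_%02d", k)]] <- sample(gene_ids, sample(10:40, 1))
  }
  go_annotation <- data.frame(
    gene = unlist(go, use.names = FALSE),
    term = rep(names(go), times = lengths(go)),
    stringsAsFactors = FALSE)

  structure(list(lnc_expr = lnc_expr, mrna_expr = mrna_expr,
                 locus_map = locus_map, lnc_fpkm = lnc_fpkm,
                 mrna_fpkm = mrna_fpkm,
                 conserved_elements = conserved_elements,
                 species_tracks = species_tracks,
                 synteny = list(mapped_foreign = mapped_foreign,
                                null_queries = null_queries),
                 go_annotation = go_annotation),
            class = "tissue_profiles")
}

#' Simulate the full synthetic dataset in one call
#'
#' Convenience wrapper running [simulate_expression_study()],
#' [simulate_genomic_context()] and [simulate_tissue_profiles()] off one
#' configuration.
#'
#' @param config a [sim_config()] object.
#' @return a list with `config`, `study`, `truth`, `context`, `tissue`.
#' @export
simulate_rcc_dataset <- function(config = sim_config()) {
  es <- simulate_expression_study(config)
  context <- simulate_genomic_context(config, es$truth, es$study)
  tissue <- simulate_tissue_profiles(config, es$truth, es$study, context)
  list(config = config, study = es$study, truth = es$truth,
       context = context, tissue = tissue)
}
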