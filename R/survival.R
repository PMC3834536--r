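#' Golub signal-to-noise discrimination score
#'
#' Computes the per-gene score \eqn{P(g) = (\mu_1 - \mu_2)/(\sigma_1 +
#' \sigma_2)} between two sample classes and a permutation p-value: the
#' smoothed fraction \eqn{(b + 1)/(m + 1)} of label shuffles whose absolute
#' score is at least the observed one. Genes with \eqn{\sigma_1 + \sigma_2
#' = 0} have an undefined score; they are flagged (`NA`) and excluded from
#' selection with a message.
#'
#' @param X numeric gene-by-sample expression matrix.
#' @param labels vector with two levels, one per column; the score numerator
#'   is mean(first level) - mean(second level).
#' @param n_perm number of label permutations.
#' @param p_cut selection threshold on the permutation p-value (strict `<`).
#' @return an object of class `golub_result`: data frame `genes`
#'   (`gene_id`, `score`, `p`, `selected`), plus `n_selected`.
#' @export
golub_select <- function(X, labels, n_perm = 1000L, p_cut = 0.01) {
  stopifnot(is.matrix(X), length(labels) == ncol(X))
  lev <- unique(labels)
  if (length(lev) != 2) stopf("labels must have exactly two levels")
  a <- labels == lev[1]
  na <- sum(a); nb <- sum(!a)
  if (na < 2 || nb < 2) stopf("each class needs >= 2 samples")
  n <- ncol(X)

  score_for <- function(amask) {
    m1 <- rowMeans(X[, amask, drop = FALSE])
    m2 <- rowMeans(X[, !amask, drop = FALSE])
    s1 <- sqrt(pmax(0, (rowSums(X[, amask, drop = FALSE]^2) - na * m1^2) / (na - 1)))
    s2 <- sqrt(pmax(0, (rowSums(X[, !amask, drop = FALSE]^2) - nb * m2^2) / (nb - 1)))
    denom <- s1 + s2
    ifelse(denom == 0, NA_real_, (m1 - m2) / denom)
  }
  obs <- score_for(a)
  if (anyNA(obs))
    message(sprintf("%d gene(s) with zero within-class variation: score undefined, excluded",
                    sum(is.na(obs))))

  exceed <- integer(nrow(X))
  for (b in seq_len(n_perm)) {
    amask <- logical(n); amask[sample(n, na)] <- TRUE
    pd <- score_for(amask)
    exceed <- exceed + as.integer(!is.na(pd) & !is.na(obs) & abs(pd) >= abs(obs))
  }
  pval <- ifelse(is.na(obs), NA_real_, (exceed + 1) / (n_perm + 1))
  selected <- !is.na(pval) & pval < p_cut
  ids <- rownames(X) %||% sprintf("gene%05d", seq_len(nrow(X)))
  structure(list(
    genes = data.frame(gene_id = ids, score = obs, p = pval,
                       selected = selected, row.names = NULL,
                       stringsAsFactors = FALSE),
    n_selected = sum(selected), n_perm = n_perm
  ), class = "golub_result")
}

#' @export
print.golub_result <- function(x, ...) {
  cat(sprintf("Golub discrimination screen: %d / %d genes selected (%d permutations)\n",
              x$n_selected, nrow(x$genes), x$n_perm))
  invisible(x)
}

#' Survival signature: two-class SAM intersected with the Golub screen
#'
#' Identifies genes correlated with the survival outcome as the
#' intersection of a two-class unpaired SAM selection (default FDR < 10\%)
#' and the Golub discrimination screen (default p < 0.01), then orders the
#' samples by the Pearson correlation of their signature-gene profile with
#' the mean profile of the dead group.
#'
#' @param X gene-by-sample expression matrix of the survival cohort
#'   (log2 scale).
#' @param outcome vector per column with levels `"dead"` and `"alive"`.
#' @param sam_fdr FDR cutoff for the SAM screen.
#' @param golub_p p-value cutoff for the Golub screen.
#' @param n_perm permutations for both screens.
#' @return an object of class `survival_signature`: `genes` (character,
#'   the intersection), `sam` and `golub` component results,
#'   `sample_order` (sample ids, most dead-like first) and `correlations`.
#' @export
survival_signature <- function(X, outcome, sam_fdr = 0.10, golub_p = 0.01,
                               n_perm = 1000L) {
  stopifnot(is.matrix(X), length(outcome) == ncol(X))
  if (!all(c("dead", "alive") %in% outcome))
    stopf("outcome must contain both 'dead' and 'alive'")
  labels <- factor(outcome, levels = c("dead", "alive"))
  sam <- sam_select(X, "two_class", labels = as.character(labels),
                    n_perm = n_perm, fdr_cut = sam_fdr)
  golub <- golub_select(X, as.character(labels), n_perm = n_perm,
                        p_cut = golub_p)
  genes <- intersect(sam$probes$probe_id[sam$probes$selected],
                     golub$genes$gene_id[golub$genes$selected])
  if (!length(genes)) {
    warning("empty survival signature: SAM and Golub selections do not intersect")
    ord <- colnames(X); cors <- rep(NA_real_, ncol(X))
  } else {
    sig <- X[genes, , drop = FALSE]
    dead_mean <- rowMeans(sig[, outcome == "dead", drop = FALSE])
    cors <- apply(sig, 2, stats::cor, y = dead_mean)
    ord <- colnames(X)[order(cors, decreasing = TRUE)]
  }
  structure(list(genes = genes, sam = sam, golub = golub,
                 sample_order = ord,
                 correlations = stats::setNames(cors, colnames(X))),
            class = "survival_signature")
}

#' @export
print.survival_signature <- function(x, ...) {
  cat(sprintf("Survival signature: %d genes (SAM %d, Golub %d)\n",
              length(x$genes), x$sam$n_selected, x$golub$n_selected))
  if (length(x$sample_order))
    cat(sprintf("  sample order (most dead-like first): %s ...\n",
                paste(utils::head(x$sample_order, 5), collapse = ", ")))
  invisible(x)
}
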