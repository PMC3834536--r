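#' Spearman rank correlation with a t-approximation p-value
#'
#' Tie-aware Spearman correlation: the Pearson correlation of
#' average-ranked values, with a two-sided p-value from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return list with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stopf("Spearman correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  list(rho = rho, p = p, n = n)
}

# two-sided p from the t approximation; |rho| = 1 gives p = 0
spearman_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1)
  tt <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  pmin(p, 1)
}

# rank rows of a matrix (average ranks, tie-aware)
row_ranks <- function(m) t(apply(m, 1, rank))

#' Cis correlation between lncRNAs and their host-locus mRNAs
#'
#' For every lncRNA with a mapped host locus, computes the cross-tissue
#' Spearman correlation with the host mRNA and records pairs passing the
#' strict cutoff `|rho| > rho_cut` at `p < p_cut`. Only pairs with both
#' transcripts detected in all tissues (no missing values) are tested;
#' lncRNAs missing from the locus map, or with a constant expression
#' vector, are skipped with a log message.
#'
#' @param lnc_expr lncRNA-by-tissue expression matrix (row names = lncRNA
#'   ids); rows with missing values are treated as not detected in all
#'   tissues.
#' @param mrna_expr mRNA-by-tissue matrix (row names = gene ids).
#' @param locus_map data frame with columns `lnc` and `gene` linking each
#'   lncRNA to its host locus.
#' @param rho_cut correlation cutoff, strict (default 0.5).
#' @param p_cut p-value cutoff (default 0.05).
#' @param n_full size of the full lncRNA set used for the reported
#'   fraction (defaults to `nrow(lnc_expr)`).
#' @return list of class `cis_result`: `records` (data frame with
#'   `lnc_id`, `partner_id`, `rho`, `p`, `mode`, `direction`) and
#'   `summary` (`n_tested`, `n_passing`, `pct_of_full`).
#' @export
cis_correlation <- function(lnc_expr, mrna_expr, locus_map, rho_cut = 0.5,
                            p_cut = 0.05, n_full = nrow(lnc_expr)) {
  stopifnot(is.matrix(lnc_expr), is.matrix(mrna_expr))
  lnc_ids <- rownames(lnc_expr)
  unmapped <- setdiff(lnc_ids, locus_map$lnc)
  if (length(unmapped))
    message(sprintf("%d lncRNA(s) missing from the locus map: skipped",
                    length(unmapped)))
  rec <- list(); n_tested <- 0L
  for (id in intersect(lnc_ids, locus_map$lnc)) {
    gene <- locus_map$gene[match(id, locus_map$lnc)]
    if (!gene %in% rownames(mrna_expr)) next
    x <- lnc_expr[id, ]; y <- mrna_expr[gene, ]
    if (anyNA(x) || anyNA(y)) next  # not detected in all tissues
    if (length(unique(x)) == 1 || length(unique(y)) == 1) {
      message(sprintf("constant expression for pair (%s, %s): skipped", id, gene))
      next
    }
    n_tested <- n_tested + 1L
    sc <- spearman_cor(x, y)
    # strict cutoff with a numeric guard against floating-point ties at the
    # boundary (rank-based rho values are rationals)
    if (abs(sc$rho) > rho_cut + 1e-12 && sc$p < p_cut)
      rec[[length(rec) + 1L]] <- data.frame(
        lnc_id = id, partner_id = gene, rho = sc$rho, p = sc$p,
        mode = "cis", direction = ifelse(sc$rho > 0, "direct", "inverse"),
        stringsAsFactors = FALSE)
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(lnc_id = character(), partner_id = character(),
               rho = numeric(), p = numeric(), mode = character(),
               direction = character(), stringsAsFactors = FALSE)
  structure(list(records = records,
                 summary = list(n_tested = n_tested,
                                n_passing = nrow(records),
                                pct_of_full = report_fraction(
                                  nrow(records), n_full, 0))),
            class = "cis_result")
}

#' Select the most abundant lncRNAs
#'
#' Returns the `floor(frac * N)` lncRNAs with the highest mean expression
#' across arrays. Ties at the boundary are broken by id order (and noted).
#'
#' @param expr lncRNA-by-array matrix, or a named numeric vector of
#'   abundances.
#' @param frac fraction to keep, in (0, 1].
#' @return character vector of selected lncRNA ids.
#' @export
select_top_abundant <- function(expr, frac = 0.2) {
  if (frac <= 0 || frac > 1) stopf("frac must lie in (0, 1]")
  abund <- if (is.matrix(expr)) rowMeans(expr) else expr
  ids <- names(abund)
  if (is.null(ids)) stopf("expression input must carry lncRNA ids as names")
  k <- floor(frac * length(abund))
  ord <- order(-abund, ids)
  if (k > 0 && k < length(abund) && abund[ord[k]] == abund[ord[k + 1]])
    message("abundance tie at the selection boundary broken by id order")
  ids[ord][seq_len(k)]
}

#' Trans correlation between abundant lncRNAs and mRNAs of other loci
#'
#' Computes the full Spearman correlation matrix between the supplied
#' lncRNAs and mRNAs across tissues (pairs sharing a locus are excluded)
#' and records pairs with `|rho| >= rho_cut` (inclusive) at `p < p_cut`.
#'
#' @inheritParams cis_correlation
#' @param rho_cut correlation cutoff, inclusive (default 0.7).
#' @return list of class `trans_result`: `records` as in
#'   [cis_correlation()] (`mode = "trans"`), `partner_counts` (named
#'   integer per lncRNA) and `summary` (`n_lnc` with at least one partner,
#'   `n_partner_mrna` distinct partners, `mean_partners` = distinct
#'   partners per correlated lncRNA, one decimal).
#' @export
trans_correlation <- function(lnc_expr, mrna_expr, locus_map, rho_cut = 0.7,
                              p_cut = 0.05) {
  stopifnot(is.matrix(lnc_expr), is.matrix(mrna_expr))
  keep_l <- !apply(lnc_expr, 1, function(v) anyNA(v) || length(unique(v)) == 1)
  keep_m <- !apply(mrna_expr, 1, function(v) anyNA(v) || length(unique(v)) == 1)
  lnc_expr <- lnc_expr[keep_l, , drop = FALSE]
  mrna_expr <- mrna_expr[keep_m, , drop = FALSE]
  n <- ncol(lnc_expr)
  rho <- stats::cor(t(row_ranks(lnc_expr)), t(row_ranks(mrna_expr)))
  pmat <- matrix(spearman_p(as.vector(rho), n), nrow(rho), ncol(rho))
  same_locus <- outer(rownames(lnc_expr), colnames(rho), FUN = function(l, g) {
    locus_map$gene[match(l, locus_map$lnc)] == g
  })
  same_locus[is.na(same_locus)] <- FALSE
  ## inclusive cutoff, with a numeric guard: rank-based rho values such as
  ## 0.7 are rationals that floating arithmetic can undershoot
  hit <- abs(rho) >= rho_cut - 1e-12 & pmat < p_cut & !same_locus
  idx <- which(hit, arr.ind = TRUE)
  records <- if (nrow(idx)) data.frame(
    lnc_id = rownames(lnc_expr)[idx[, 1]],
    partner_id = rownames(mrna_expr)[idx[, 2]],
    rho = rho[idx], p = pmat[idx], mode = "trans",
    direction = ifelse(rho[idx] > 0, "direct", "inverse"),
    stringsAsFactors = FALSE) else data.frame(
    lnc_id = character(), partner_id = character(), rho = numeric(),
    p = numeric(), mode = character(), direction = character(),
    stringsAsFactors = FALSE)
  records <- records[order(records$lnc_id, records$partner_id), ]
  rownames(records) <- NULL
  counts <- table(records$lnc_id)
  n_lnc <- length(counts)
  n_mrna <- length(unique(records$partner_id))
  structure(list(records = records,
                 partner_counts = stats::setNames(as.integer(counts),
                                                  names(counts)),
                 summary = list(n_lnc = n_lnc, n_partner_mrna = n_mrna,
                                mean_partners = trans_partner_mean(n_lnc,
                                                                   n_mrna))),
            class = "trans_result")
}

#' Mean distinct trans partners per correlated lncRNA
#'
#' @param n_lnc number of lncRNAs with at least one trans partner.
#' @param n_partner_mrna number of distinct partner mRNAs.
#' @param decimals decimal places for the rounded mean.
#' @return the rounded mean partner count (e.g. 5293 partners over 693
#'   lncRNAs gives 7.6).
#' @export
trans_partner_mean <- function(n_lnc, n_partner_mrna, decimals = 1) {
  if (n_lnc <= 0) return(NA_real_)
  round_half_away(n_partner_mrna / n_lnc, decimals)
}

#' GO module map with Bonferroni-corrected hypergeometric enrichment
#'
#' For every (lncRNA, GO term) pair, tests whether the lncRNA's correlated
#' mRNAs are over-represented in the term's gene set within the background
#' universe (hypergeometric upper tail), applying a Bonferroni correction
#' over the terms tested per lncRNA. Enriched cells carry the sign of the
#' majority correlation direction among the overlapping mRNAs (+1 direct,
#' -1 inverse); direction ties fall to the sign with the larger mean
#' absolute correlation.
#'
#' @param records correlation records (as from [trans_correlation()] or
#'   [cis_correlation()]).
#' @param annotation data frame with columns `gene` and `term` (flat
#'   gene-to-term map, no ontology propagation).
#' @param background character vector: the gene universe (must contain
#'   every annotated gene appearing in the records).
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @return data frame of class `module_map`: `lnc_id`, `term`, `overlap`,
#'   `p_raw`, `p_adj`, `sign` (0 when not enriched).
#' @export
go_module_map <- function(records, annotation, background, alpha = 0.05) {
  if (inherits(records, c("cis_result", "trans_result")))
    records <- records$records
  if (!nrow(annotation)) stopf("empty GO annotation")
  annotation <- annotation[annotation$gene %in% background, , drop = FALSE]
  term_genes <- split(annotation$gene, annotation$term)
  N <- length(unique(background))
  out <- list()
  for (id in unique(records$lnc_id)) {
    rr <- records[records$lnc_id == id, ]
    genes <- unique(rr$partner_id[rr$partner_id %in% background])
    if (!length(genes)) next
    n_tests <- length(term_genes)
    for (term in names(term_genes)) {
      tg <- unique(term_genes[[term]])
      ov <- intersect(genes, tg)
      if (!length(ov)) next
      p_raw <- stats::phyper(length(ov) - 1, length(tg), N - length(tg),
                             length(genes), lower.tail = FALSE)
      p_adj <- min(1, p_raw * n_tests)
      sgn <- 0L
      if (p_adj < alpha) {
        dir_rho <- rr$rho[rr$partner_id %in% ov]
        n_pos <- sum(dir_rho > 0); n_neg <- sum(dir_rho < 0)
        if (n_pos > n_neg) sgn <- 1L
        else if (n_neg > n_pos) sgn <- -1L
        else {
          mp <- mean(abs(dir_rho[dir_rho > 0]))
          mn <- mean(abs(dir_rho[dir_rho < 0]))
          sgn <- if (mp >= mn) 1L else -1L
          message(sprintf("direction tie for (%s, %s): resolved by mean |rho|",
                          id, term))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        lnc_id = id, term = term, overlap = length(ov),
        p_raw = p_raw, p_adj = p_adj, sign = sgn,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(lnc_id = character(), term = character(),
               overlap = integer(), p_raw = numeric(), p_adj = numeric(),
               sign = integer(), stringsAsFactors = FALSE)
  class(res) <- c("module_map", class(res))
  res
}
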