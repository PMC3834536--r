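#' Fraction of expression in each tissue (F.E.T.)
#'
#' For every transcript, divides its FPKM in each tissue by the summed
#' FPKM over all tissues. A transcript is called tissue-specific when its
#' maximum fraction is at least 0.5. All-zero rows are undefined and
#' flagged not-expressed.
#'
#' @param fpkm numeric transcript-by-tissue matrix (non-negative) or a
#'   single row as a numeric vector.
#' @param specific_cut specificity threshold on the maximum fraction
#'   (inclusive, default 0.5).
#' @return data frame of class `fet_table`: `id`, `max_fet`, `specific`,
#'   `expressed`, plus one `fet_*` column per tissue.
#' @export
fraction_expression <- function(fpkm, specific_cut = 0.5) {
  if (!is.matrix(fpkm)) fpkm <- matrix(fpkm, 1,
                                       dimnames = list("row1", names(fpkm)))
  if (any(fpkm < 0)) stopf("negative FPKM value")
  tot <- rowSums(fpkm)
  fet <- fpkm / ifelse(tot > 0, tot, NA_real_)
  max_fet <- suppressWarnings(apply(fet, 1, max))
  res <- data.frame(id = rownames(fpkm) %||% sprintf("row%d", seq_len(nrow(fpkm))),
                    max_fet = unname(max_fet),
                    specific = !is.na(max_fet) & max_fet >= specific_cut,
                    expressed = tot > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  fet_df <- as.data.frame(fet)
  names(fet_df) <- paste0("fet_", colnames(fpkm) %||% seq_len(ncol(fpkm)))
  res <- cbind(res, fet_df)
  class(res) <- c("fet_table", class(res))
  res
}

#' Fisher test comparing tissue-specificity rates
#'
#' Two-sided Fisher exact test on the 2x2 table of specific vs
#' non-specific counts between the lncRNA and mRNA sets.
#'
#' @param lnc_specific,mrna_specific logical vectors of per-transcript
#'   specificity calls.
#' @return list with `odds_ratio`, `p` and the `table`.
#' @export
specificity_fisher <- function(lnc_specific, mrna_specific) {
  if (!length(lnc_specific) || !length(mrna_specific))
    stopf("both specificity vectors must be non-empty")
  tab <- matrix(c(sum(lnc_specific), sum(!lnc_specific),
                  sum(mrna_specific), sum(!mrna_specific)), 2,
                dimnames = list(c("specific", "not"), c("lncRNA", "mRNA")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Conserved-element overlap enrichment against random control sets
#'
#' Counts queries overlapping at least one conserved element, does the
#' same for each length-matched random control set, and tests each
#' query-vs-control comparison with a two-sided Fisher exact test on the
#' overlapping / non-overlapping counts.
#'
#' @param queries `GRanges` of query intervals (e.g. lncRNAs).
#' @param element_track `GRanges` of conserved elements.
#' @param random_sets list of control `GRanges` (e.g. from
#'   [make_random_controls()]).
#' @return list of class `conservation_summary`: `n_overlapping`,
#'   `n_total`, `per_control` data frame (`control`, `n_overlapping`,
#'   `fisher_p`), `max_p`, and per-query `overlap_bp`.
#' @export
conservation_enrichment <- function(queries, element_track, random_sets) {
  n_total <- length(queries)
  if (!length(element_track)) {
    return(structure(list(n_overlapping = 0L, n_total = n_total,
                          per_control = data.frame(
                            control = seq_along(random_sets),
                            n_overlapping = 0L, fisher_p = 1),
                          max_p = 1,
                          overlap_bp = stats::setNames(rep(0L, n_total),
                                                       names(queries))),
                     class = "conservation_summary"))
  }
  hit <- overlap_count(queries, element_track) > 0
  ov <- IRanges::pintersect(
    IRanges::findOverlapPairs(queries, element_track,
                                    ignore.strand = TRUE),
    ignore.strand = TRUE)
  bp <- stats::setNames(rep(0L, n_total), names(queries))
  if (length(ov)) {
    w <- tapply(GenomicRanges::width(ov),
                names(ov) %||% as.character(seq_along(ov)), max)
    bp[names(w)] <- as.integer(w)
  }
  per <- do.call(rbind, lapply(seq_along(random_sets), function(i) {
    rhit <- overlap_count(random_sets[[i]], element_track) > 0
    tab <- matrix(c(sum(hit), sum(!hit), sum(rhit), sum(!rhit)), 2)
    data.frame(control = i, n_overlapping = sum(rhit),
               fisher_p = stats::fisher.test(tab)$p.value)
  }))
  structure(list(n_overlapping = sum(hit), n_total = n_total,
                 per_control = per,
                 max_p = if (is.null(per)) NA_real_ else max(per$fisher_p),
                 overlap_bp = bp),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("Conservation overlap: %d / %d queries (%s%%)\n",
              x$n_overlapping, x$n_total,
              format(report_fraction(x$n_overlapping, x$n_total, 0))))
  if (!is.null(x$per_control))
    cat(sprintf("  vs %d control set(s): max Fisher p = %.3g\n",
                nrow(x$per_control), x$max_p))
  invisible(x)
}

#' Cross-species expression conservation
#'
#' Records, per query and species, whether the query intersects at least
#' one interval of the species' expressed-cDNA track (>= 1 bp), and the
#' fraction of queries hit in at least one species.
#'
#' @param queries `GRanges` of query intervals.
#' @param species_tracks named list of `GRanges`, one per species.
#' @return list of class `expression_conservation`: `hits` (logical
#'   query-by-species matrix), `n_hit`, `fraction` and `pct` (rounded
#'   percentage of queries with at least one species hit).
#' @export
expression_conservation <- function(queries, species_tracks) {
  if (!length(species_tracks)) stopf("need at least one species track")
  hits <- vapply(species_tracks, function(tr)
    overlap_count(queries, tr) > 0, logical(length(queries)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = length(queries))
  rownames(hits) <- names(queries)
  any_hit <- rowSums(hits) > 0
  structure(list(hits = hits, n_hit = sum(any_hit),
                 fraction = mean(any_hit),
                 pct = report_fraction(sum(any_hit), length(queries), 0)),
            class = "expression_conservation")
}

#' Syntenic overlap with lifted foreign intervals
#'
#' Intersects the queries with foreign (e.g. mouse) intervals already
#' lifted onto the query assembly, records overlap lengths, and compares
#' the query hit count with that of a null query set (non-expressed
#' intervals) by a two-sided Fisher exact test.
#'
#' @param queries `GRanges` of expressed query intervals.
#' @param mapped_foreign `GRanges` of lifted foreign intervals.
#' @param null_queries `GRanges` of control (non-expressed) intervals.
#' @return list of class `syntenic_overlap`: `overlapping` (query names
#'   with a hit), `overlap_bp` (per overlapping query), `n_query_hit`,
#'   `n_null_hit`, `fisher_p`, `table`.
#' @export
syntenic_overlap <- function(queries, mapped_foreign, null_queries) {
  qhit <- overlap_count(queries, mapped_foreign) > 0
  nhit <- overlap_count(null_queries, mapped_foreign) > 0
  pairs <- IRanges::findOverlapPairs(queries, mapped_foreign,
                                           ignore.strand = TRUE)
  ov <- IRanges::pintersect(pairs, ignore.strand = TRUE)
  bp <- integer(0)
  if (length(ov)) {
    w <- tapply(GenomicRanges::width(ov),
                names(ov) %||% as.character(seq_along(ov)), max)
    bp <- stats::setNames(as.integer(w), names(w))
  }
  tab <- matrix(c(sum(qhit), sum(!qhit), sum(nhit), sum(!nhit)), 2,
                dimnames = list(c("overlap", "no_overlap"),
                                c("expressed", "null")))
  structure(list(overlapping = names(queries)[qhit], overlap_bp = bp,
                 n_query_hit = sum(qhit), n_null_hit = sum(nhit),
                 fisher_p = stats::fisher.test(tab)$p.value, table = tab),
            class = "syntenic_overlap")
}
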