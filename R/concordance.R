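#' Packaged worked-example tables
#'
#' `rcc_table1()` returns the transcribed 40-lncRNA malignancy signature
#' table (29 intronic lncRNAs + 11 lincRNAs) with the signed linear fold
#' change of each lncRNA and, where available, the average fold change of
#' its host gene from the meta-analysis. The raw host-gene annotation
#' string (including the "(x/y)" studies-altered/studies-detected suffix
#' and emphasis markup) is kept as metadata; only the leading signed
#' number enters the concordance rule. `rcc_table2()` returns the
#' per-study meta-analysis concordance counts.
#'
#' @return data frames.
#' @export
rcc_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "rcclnc",
                      mustWork = TRUE)
  t1 <- utils::read.delim(path, stringsAsFactors = FALSE)
  raw <- t1$host_fc_raw
  num <- sub("^\\*{0,2}(-?[0-9]+\\.?[0-9]*).*$", "\\1", raw)
  t1$host_fc <- suppressWarnings(as.numeric(ifelse(raw %in% c("-", "n.d."),
                                                   NA, num)))
  t1$host_detail <- ifelse(grepl("\\(", raw),
                           sub("^.*(\\([0-9]+/[0-9]+\\)).*$", "\\1", raw), NA)
  t1
}

#' @rdname rcc_table1
#' @export
rcc_table2 <- function() {
  path <- system.file("extdata", "table2.tsv", package = "rcclnc",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Count up- and down-regulated genes
#'
#' Signed linear fold changes: positive means up in tumor, negative down.
#'
#' @param fold_changes numeric vector of signed linear fold changes
#'   (no zeros).
#' @return list with `n_up` and `n_down`.
#' @export
classify_regulation <- function(fold_changes) {
  if (!length(fold_changes)) stopf("empty fold-change list")
  if (any(fold_changes == 0, na.rm = TRUE))
    stopf("zero fold change has no direction")
  list(n_up = sum(fold_changes > 0, na.rm = TRUE),
       n_down = sum(fold_changes < 0, na.rm = TRUE))
}

#' Host-gene concordance classification
#'
#' A host gene counts as altered when the magnitude of its average fold
#' change is strictly greater than `fc_min`; among altered hosts,
#' concordant means the same direction as the lncRNA, inverse the
#' opposite. Pairs with a missing host fold change are skipped.
#'
#' @param lnc_fc,host_fc aligned numeric vectors of signed linear fold
#'   changes (`host_fc` may contain `NA`).
#' @param fc_min alteration threshold (> 1), strict.
#' @return list with `n_altered`, `n_concordant`, `n_inverse`.
#' @export
host_gene_concordance <- function(lnc_fc, host_fc, fc_min = 1.5) {
  if (fc_min <= 1) stopf("fc_min must exceed 1")
  if (length(lnc_fc) != length(host_fc))
    stopf("lnc and host fold-change vectors must align")
  keep <- !is.na(host_fc)
  lnc_fc <- lnc_fc[keep]; host_fc <- host_fc[keep]
  altered <- abs(host_fc) > fc_min
  conc <- altered & sign(lnc_fc) == sign(host_fc)
  list(n_altered = sum(altered), n_concordant = sum(conc),
       n_inverse = sum(altered) - sum(conc))
}

#' Signature-vs-study sign concordance
#'
#' Compares two signed gene lists: the number of shared gene ids, the
#' number whose fold-change direction agrees, and the percentage of
#' concordance to one decimal.
#'
#' @param signature,study data frames with columns `gene_id` and
#'   `fold_change` (signed linear values).
#' @return list of class `concordance_report`: `n_common`,
#'   `n_concordant`, `pct_concordance`.
#' @export
study_concordance <- function(signature, study) {
  common <- intersect(signature$gene_id, study$gene_id)
  s1 <- sign(signature$fold_change[match(common, signature$gene_id)])
  s2 <- sign(study$fold_change[match(common, study$gene_id)])
  concordance_report(length(common), sum(s1 == s2))
}

#' @rdname study_concordance
#' @param n_common,n_concordant concordance counts (e.g. Table-style
#'   printed count pairs).
#' @export
concordance_report <- function(n_common, n_concordant) {
  if (n_concordant > n_common) stopf("n_concordant cannot exceed n_common")
  pct <- if (n_common > 0) report_fraction(n_concordant, n_common, 1) else
    NA_real_
  structure(list(n_common = n_common, n_concordant = n_concordant,
                 pct_concordance = pct), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d / %d genes (%s%%)\n", x$n_concordant,
              x$n_common, format(x$pct_concordance)))
  invisible(x)
}

#' Rounded percentage reporting
#'
#' Computes `100 * numerator / denominator` rounded half-away-from-zero to
#' `decimals` places; `mode = "trunc"` truncates instead (some legacy
#' figures are truncations: 142/170 prints as 83\%).
#'
#' @param numerator,denominator counts, `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @param decimals decimal places.
#' @param mode `"half_away"` (default) or `"trunc"`.
#' @return the rounded percentage.
#' @export
report_fraction <- function(numerator, denominator, decimals = 0,
                            mode = c("half_away", "trunc")) {
  mode <- match.arg(mode)
  if (denominator <= 0) stopf("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stopf("numerator must lie in [0, denominator]")
  pct <- 100 * numerator / denominator
  if (mode == "trunc") trunc(pct * 10^decimals) / 10^decimals
  else round_half_away(pct, decimals)
}
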