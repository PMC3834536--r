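#' Detection rule based on negative-control probes
#'
#' Encodes the platform detection rules: on the paired cDNA-array design a
#' probe is detected per array when its intensity exceeds the mean plus
#' `k_sd = 3` standard deviations of the negative-control probes on that
#' array; on the pooled oligoarray design (`scope = "per_group"`,
#' `k_sd = 2`) a probe counts as expressed when detected in at least
#' `min_arrays` (3) of the arrays of one of the two groups.
#'
#' @param k_sd multiplier on the negative-control standard deviation.
#' @param min_arrays minimum detected arrays for the per-group rule.
#' @param scope `"per_array"` or `"per_group"`.
#' @return an object of class `detection_rule`.
#' @export
detection_rule <- function(k_sd = 3, min_arrays = 1L,
                           scope = c("per_array", "per_group")) {
  scope <- match.arg(scope)
  if (k_sd <= 0) stopf("k_sd must be positive")
  if (min_arrays < 1) stopf("min_arrays must be >= 1")
  structure(list(k_sd = k_sd, min_arrays = as.integer(min_arrays),
                 scope = scope), class = "detection_rule")
}

#' Detect expressed probes against negative-control thresholds
#'
#' Per array, the detection threshold is the mean plus `k_sd` sample
#' standard deviations of the negative-control intensities on that array; a
#' probe is detected where its intensity is strictly above the threshold.
#' Under `scope = "per_group"` the per-probe expression call additionally
#' requires detection in at least `min_arrays` arrays of one group.
#'
#' @param intensities numeric probe-by-array matrix with probe row names.
#' @param negcontrol_ids character ids of the negative-control probes
#'   (must be rows of `intensities`; at least two).
#' @param rule a [detection_rule()].
#' @param groups for `scope = "per_group"`, a vector assigning each array
#'   to one of two groups.
#' @return a list of class `detection_result` with `mask` (logical
#'   probe-by-array matrix), `thresholds` (per array) and, for the
#'   per-group rule, `expressed` (named logical per probe).
#' @export
detect_expressed <- function(intensities, negcontrol_ids, rule = detection_rule(),
                             groups = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)))
  miss <- setdiff(negcontrol_ids, rownames(intensities))
  if (length(miss)) stopf("negative controls absent from matrix: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  if (length(negcontrol_ids) < 2)
    stopf("need >= 2 negative-control probes to estimate a standard deviation")
  nc <- intensities[negcontrol_ids, , drop = FALSE]
  thresholds <- colMeans(nc) + rule$k_sd * apply(nc, 2, stats::sd)
  mask <- sweep(intensities, 2, thresholds, `>`)
  out <- list(mask = mask, thresholds = thresholds, rule = rule)
  if (rule$scope == "per_group") {
    if (is.null(groups) || length(groups) != ncol(intensities))
      stopf("per-group detection needs a `groups` vector, one entry per array")
    gl <- unique(groups)
    if (length(gl) != 2) stopf("expected exactly two groups, got %d", length(gl))
    counts <- vapply(gl, function(g)
      rowSums(mask[, groups == g, drop = FALSE]), numeric(nrow(mask)))
    out$expressed <- apply(counts >= rule$min_arrays, 1, any)
  }
  structure(out, class = "detection_result")
}

#' Prevalence filter across two sample groups
#'
#' A probe is retained only if its detection fraction is at least
#' `min_frac` in *both* groups; falling below the cut in either group
#' excludes it (the 90\% prevalence rule).
#'
#' @param mask logical probe-by-array detection matrix (or a
#'   `detection_result`).
#' @param groups vector assigning each array to one of two groups.
#' @param min_frac minimum detection fraction per group (default 0.9).
#' @return character vector of retained probe ids.
#' @export
filter_by_prevalence <- function(mask, groups, min_frac = 0.9) {
  if (inherits(mask, "detection_result")) mask <- mask$mask
  if (min_frac <= 0 || min_frac > 1) stopf("min_frac must lie in (0, 1]")
  if (length(groups) != ncol(mask))
    stopf("`groups` must assign every array to a group")
  gl <- unique(groups)
  if (length(gl) != 2) stopf("expected exactly two groups, got %d", length(gl))
  if (any(table(factor(groups, levels = gl)) == 0)) stopf("empty group")
  frac <- vapply(gl, function(g)
    rowMeans(mask[, groups == g, drop = FALSE]), numeric(nrow(mask)))
  rownames(mask)[frac[, 1] >= min_frac & frac[, 2] >= min_frac]
}

#' Quantile normalization
#'
#' Forces every array to the same intensity distribution (the row-wise mean
#' of the sorted columns) while preserving within-array rank order. A
#' single-column matrix is returned unchanged. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param mat numeric probe-by-array matrix without missing values.
#' @return the normalized matrix with the input dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat)) stopf("missing values are not supported before normalization")
  if (ncol(mat) == 1) return(mat)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-pair tumor/nontumor log2 ratios
#'
#' @param intensities numeric probe-by-array matrix (positive values).
#' @param pairing data frame with columns `tumor` and `nontumor` holding
#'   the paired column names of `intensities`.
#' @return probe-by-pair matrix of `log2(T) - log2(N)`.
#' @export
log2_ratio <- function(intensities, pairing) {
  stopifnot(is.matrix(intensities),
            all(c("tumor", "nontumor") %in% names(pairing)))
  cols <- c(pairing$tumor, pairing$nontumor)
  miss <- setdiff(cols, colnames(intensities))
  if (length(miss)) stopf("pairing names absent from matrix: %s",
                          paste(miss, collapse = ", "))
  bad <- which(intensities[, cols, drop = FALSE] <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("nonpositive intensity for probe %s in sample %s",
          rownames(intensities)[bad[1, 1]], cols[bad[1, 2]])
  r <- log2(intensities[, pairing$tumor, drop = FALSE]) -
    log2(intensities[, pairing$nontumor, drop = FALSE])
  colnames(r) <- sprintf("pair%02d", seq_len(nrow(pairing)))
  r
}
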