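#' SAM d-statistic
#'
#' Computes the moderated t-like SAM score \eqn{d_i = r_i / (s_i + s_0)}.
#' For the one-class (paired log-ratio) design, \eqn{r_i} is the mean
#' per-pair log ratio and \eqn{s_i = SD_i/\sqrt{n}}; for the two-class
#' unpaired design, \eqn{r_i} is the difference of group means and
#' \eqn{s_i} the pooled standard error
#' \eqn{\sqrt{(1/n_A + 1/n_B)\,\Sigma (x-\bar x)^2 / (n_A + n_B - 2)}}.
#'
#' @param X numeric probe-by-sample matrix: per-pair log ratios
#'   (one-class) or expression values (two-class).
#' @param design `"one_class"` or `"two_class"`.
#' @param labels for the two-class design, a vector with two levels
#'   partitioning the columns; `r` is mean(first level) - mean(second).
#' @param s0 the fudge factor (a single non-negative scalar).
#' @return list with per-probe `d`, `r` and `s` (and the `s0` used).
#' @export
sam_d_statistic <- function(X, design = c("one_class", "two_class"),
                            labels = NULL, s0 = 0) {
  design <- match.arg(design)
  stopifnot(is.matrix(X), s0 >= 0)
  if (design == "one_class") {
    n <- ncol(X)
    if (n < 2) stopf("one-class design needs >= 2 pairs")
    r <- rowMeans(X)
    s <- sqrt(pmax(0, (rowSums(X^2) - n * r^2) / (n - 1))) / sqrt(n)
  } else {
    if (is.null(labels) || length(labels) != ncol(X))
      stopf("two-class design needs one label per column")
    lev <- unique(labels)
    if (length(lev) != 2) stopf("labels must have exactly two levels")
    a <- labels == lev[1]
    na <- sum(a); nb <- sum(!a)
    if (na < 2 || nb < 2) stopf("each group needs >= 2 samples")
    ma <- rowMeans(X[, a, drop = FALSE])
    mb <- rowMeans(X[, !a, drop = FALSE])
    ssw <- rowSums(X^2) - na * ma^2 - nb * mb^2
    r <- ma - mb
    s <- sqrt(pmax(0, (1 / na + 1 / nb) * ssw / (na + nb - 2)))
  }
  list(d = r / (s + s0), r = r, s = s, s0 = s0)
}

#' Choose the SAM fudge factor s0
#'
#' Searches the candidate set \{0th, 5th, ..., 100th\} percentiles of the
#' per-probe standard-error distribution and returns the candidate
#' minimising the coefficient of variation of the d-statistic's spread
#' across the standard-error range (the published SAM recipe: the CV of the
#' windowed median absolute deviations of d over equal-count windows of
#' `s`).
#'
#' @inheritParams sam_d_statistic
#' @return the chosen `s0` (a non-negative scalar).
#' @export
choose_s0 <- function(X, design = c("one_class", "two_class"), labels = NULL) {
  design <- match.arg(design)
  st <- sam_d_statistic(X, design, labels, s0 = 0)
  s <- st$s; r <- st$r
  if (all(s == 0)) {
    message("all per-probe standard errors are zero; using a small positive s0 floor")
    return(sqrt(.Machine$double.eps))
  }
  if (max(s) - min(s) < 1e-12) {
    message("all per-probe standard errors equal; any s0 percentile is equivalent, returning the 0th")
    return(stats::quantile(s, 0, names = FALSE))
  }
  cand <- stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE)
  ngroups <- max(2L, min(100L, floor(length(s) / 10)))
  grp <- cut(rank(s, ties.method = "first"),
             breaks = ngroups, labels = FALSE)
  cv <- vapply(cand, function(s0c) {
    d <- r / (s + s0c)
    mads <- tapply(d, grp, stats::mad)
    m <- mean(mads)
    if (m == 0) Inf else stats::sd(mads) / m
  }, numeric(1))
  cand[which.min(cv)]
}

#' Permutation-based SAM selection with FDR control
#'
#' Builds the permutation null (random sign flips of each pair's log ratio
#' for the one-class design -- all \eqn{2^n} designs when there are at most
#' `n_perm`, otherwise `n_perm` sampled with replacement -- or label
#' shuffles for the two-class design), then searches asymmetric thresholds:
#' for a cut \eqn{\Delta}, the upper (lower) cut is the smallest (largest)
#' observed order statistic deviating from its permutation-expected value
#' by at least \eqn{\Delta}. The estimated FDR at a cut is the median
#' across permutations of the null count beyond the cuts divided by the
#' observed count (the null proportion \eqn{\pi_0} is set to 1). The
#' selection uses the smallest \eqn{\Delta} whose estimated FDR is at or
#' below `fdr_cut`; when no threshold qualifies the selection is empty.
#'
#' Randomness is drawn from the current RNG stream; seed it with
#' `set.seed()` for reproducible selections.
#'
#' @inheritParams sam_d_statistic
#' @param n_perm number of permutations (>= 100).
#' @param fdr_cut FDR cutoff as a fraction (0.05 for the malignancy
#'   signature, 0.10 for the survival screen).
#' @param s0 optional fudge factor; chosen by [choose_s0()] when `NULL`.
#' @param n_delta size of the threshold grid searched.
#' @return an object of class `sam_result`: data frame `probes` (columns
#'   `probe_id`, `d`, `r`, `s`, `q`, `selected`) plus `s0`, `delta`, `fdr`,
#'   `cutlow`, `cutup`, `n_selected`.
#' @export
sam_select <- function(X, design = c("one_class", "two_class"), labels = NULL,
                       n_perm = 1000L, fdr_cut = 0.05, s0 = NULL,
                       n_delta = 20L) {
  design <- match.arg(design)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (is.null(s0)) s0 <- choose_s0(X, design, labels)
  obs <- sam_d_statistic(X, design, labels, s0)
  d <- obs$d
  p <- length(d)
  n <- ncol(X)

  ## permutation d-statistics, fully vectorised through matrix products
  rs2 <- rowSums(X^2)
  if (design == "one_class") {
    if (2^n <= n_perm) {
      S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      S <- t(S)
    } else {
      S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    }
    M <- (X %*% S) / n
    Sd <- sqrt(pmax(0, (rs2 - n * M^2) / (n - 1))) / sqrt(n)
    Dp <- M / (Sd + s0)
  } else {
    lev <- unique(labels)
    a <- labels == lev[1]
    na <- sum(a); nb <- sum(!a)
    Z <- vapply(seq_len(n_perm), function(b) {
      z <- numeric(n); z[sample(n, na)] <- 1; z
    }, numeric(n))
    SA <- X %*% Z
    MA <- SA / na
    MB <- (rowSums(X) - SA) / nb
    SSW <- pmax(0, rs2 - na * MA^2 - nb * MB^2)
    Sd <- sqrt((1 / na + 1 / nb) * SSW / (na + nb - 2))
    Dp <- (MA - MB) / (Sd + s0)
  }

  d_ord <- sort(d)
  dbar <- rowMeans(apply(Dp, 2, sort))
  diffs <- d_ord - dbar

  ## threshold grid over the observed deviations from the expected order stats
  pos <- abs(diffs)
  if (any(pos > 0)) {
    ## quantiles of the deviations plus a uniform component, so the search
    ## does not skip the sparse region between null and signal deviations
    cand <- sort(unique(c(
      stats::quantile(pos[pos > 0], probs = seq(0, 1, length.out = n_delta),
                      names = FALSE),
      seq(min(pos[pos > 0]), max(pos), length.out = n_delta))))
  } else {
    cand <- 0
  }

  eval_delta <- function(delta) {
    iu <- which(diffs >= delta & d_ord > 0)
    il <- which(-diffs >= delta & d_ord < 0)
    cutup <- if (length(iu)) d_ord[min(iu)] else Inf
    cutlow <- if (length(il)) d_ord[max(il)] else -Inf
    n_obs <- sum(d >= cutup) + sum(d <= cutlow)
    if (n_obs == 0) return(list(fdr = 0, cutup = cutup, cutlow = cutlow,
                                n_obs = 0L))
    null_counts <- colSums(Dp >= cutup) + colSums(Dp <= cutlow)
    list(fdr = min(1, stats::median(null_counts) / n_obs),
         cutup = cutup, cutlow = cutlow, n_obs = n_obs)
  }

  evals <- lapply(cand, eval_delta)
  fdrs <- vapply(evals, `[[`, numeric(1), "fdr")
  nsel <- vapply(evals, function(e) as.integer(e$n_obs), integer(1))
  ok <- which(fdrs <= fdr_cut & nsel > 0)

  if (length(ok)) {
    k <- ok[1]
    chosen <- evals[[k]]
    delta <- cand[k]
    selected <- d >= chosen$cutup | d <= chosen$cutlow
    fdr <- chosen$fdr
    cutup <- chosen$cutup; cutlow <- chosen$cutlow
  } else {
    delta <- Inf; selected <- rep(FALSE, p); fdr <- NA_real_
    cutup <- Inf; cutlow <- -Inf
  }

  ## per-probe q: smallest estimated FDR over the grid at which the probe
  ## falls beyond the cuts
  q <- rep(NA_real_, p)
  for (k in seq_along(cand)) {
    e <- evals[[k]]
    sel_k <- d >= e$cutup | d <= e$cutlow
    q[sel_k] <- pmin(q[sel_k], e$fdr, na.rm = TRUE)
  }

  ids <- rownames(X) %||% sprintf("probe%05d", seq_len(p))
  structure(list(
    probes = data.frame(probe_id = ids, d = d, r = obs$r, s = obs$s,
                        q = q, selected = selected,
                        row.names = NULL, stringsAsFactors = FALSE),
    s0 = s0, delta = delta, fdr = fdr, cutlow = cutlow, cutup = cutup,
    n_selected = sum(selected), design = design, n_perm = ncol(Dp)
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("SAM %s selection: %d / %d probes selected\n",
              x$design, x$n_selected, nrow(x$probes)))
  cat(sprintf("  s0 = %.4g | delta = %.4g | estimated FDR = %s | cuts (%.3g, %.3g)\n",
              x$s0, x$delta,
              ifelse(is.na(x$fdr), "NA", sprintf("%.3f", x$fdr)),
              x$cutlow, x$cutup))
  invisible(x)
}

#' Leave-one-out consensus malignancy signature
#'
#' Runs [sam_select()] on the full probe-by-pair log-ratio matrix and on
#' each leave-one-pair-out matrix. The consensus signature keeps probes
#' selected in 100\% of the leave-one-out datasets whose mean linear fold
#' change (geometric mean of the per-pair tumor/nontumor ratios, signed by
#' direction) is at least `fc_min` in magnitude.
#'
#' @param pair_ratios probe-by-pair matrix of log2(T/N) ratios (>= 3 pairs).
#' @param fdr_cut FDR cutoff used in every SAM run.
#' @param fc_min minimal linear fold change for the final call.
#' @param n_perm permutations per SAM run.
#' @param s0 optional fudge factor forwarded to every run.
#' @return an object of class `loo_consensus`: data frame `probes`
#'   (`probe_id`, `presence_frac`, `mean_fc`, `final`), the full-data
#'   `sam_result` in `full`, and per-leave-one-out selection sizes.
#' @export
leave_one_out_signature <- function(pair_ratios, fdr_cut = 0.05, fc_min = 1.5,
                                    n_perm = 1000L, s0 = NULL) {
  stopifnot(is.matrix(pair_ratios))
  n <- ncol(pair_ratios)
  if (n < 3) stopf("leave-one-out consensus needs >= 3 pairs")
  full <- sam_select(pair_ratios, "one_class", n_perm = n_perm,
                     fdr_cut = fdr_cut, s0 = s0)
  sel <- vapply(seq_len(n), function(j) {
    sam_select(pair_ratios[, -j, drop = FALSE], "one_class",
               n_perm = n_perm, fdr_cut = fdr_cut, s0 = s0)$probes$selected
  }, logical(nrow(pair_ratios)))
  presence <- rowMeans(sel)
  m <- rowMeans(pair_ratios)
  mean_fc <- ifelse(m >= 0, 2^m, -(2^(-m)))
  final <- presence == 1 & abs(mean_fc) >= fc_min
  ids <- rownames(pair_ratios) %||% sprintf("probe%05d", seq_len(nrow(pair_ratios)))
  structure(list(
    probes = data.frame(probe_id = ids, presence_frac = presence,
                        mean_fc = mean_fc, final = final,
                        row.names = NULL, stringsAsFactors = FALSE),
    full = full, loo_sizes = colSums(sel), n_final = sum(final)
  ), class = "loo_consensus")
}

#' @export
print.loo_consensus <- function(x, ...) {
  cat(sprintf("Leave-one-out consensus signature: %d probes final (of %d)\n",
              x$n_final, nrow(x$probes)))
  cat(sprintf("  per-LOO selection sizes: %s\n",
              paste(x$loo_sizes, collapse = ", ")))
  invisible(x)
}
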