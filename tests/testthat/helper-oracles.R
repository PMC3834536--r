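# Independent brute-force oracles used to check the analytical code paths.

# SAM d by the direct formula, computed loop-wise and independently of the
# package's vectorised implementation
oracle_d_one_class <- function(X, s0) {
  vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    r <- mean(x)
    s <- stats::sd(x) / sqrt(length(x))
    r / (s + s0)
  }, numeric(1))
}

oracle_d_two_class <- function(X, labels, s0) {
  lev <- unique(labels)
  vapply(seq_len(nrow(X)), function(i) {
    xa <- X[i, labels == lev[1]]
    xb <- X[i, labels == lev[2]]
    r <- mean(xa) - mean(xb)
    sp2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) /
      (length(xa) + length(xb) - 2)
    s <- sqrt((1 / length(xa) + 1 / length(xb)) * sp2)
    r / (s + s0)
  }, numeric(1))
}

# Spearman rho from explicitly computed average ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i)
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# hypergeometric upper-tail P(X >= k) by exhaustive summation
oracle_hyper_tail <- function(k, n_white, n_black, n_draw) {
  sum(vapply(k:min(n_white, n_draw), function(j)
    choose(n_white, j) * choose(n_black, n_draw - j), numeric(1))) /
    choose(n_white + n_black, n_draw)
}

# two-sided Fisher p by enumerating all tables with the same margins and
# summing probabilities not exceeding the observed one
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  probs <- vapply(max(0, r1 + c1 - n):min(r1, c1), function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), numeric(1))
  p_obs <- choose(c1, tab[1, 1]) * choose(n - c1, tab[1, 2]) / choose(n, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sample KS D as the explicit sup over the pooled points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

# small simulated dataset shared by several tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_probes_by_class = c(intronic_antisense = 120,
                                   protein_coding = 60,
                                   lincRNA = 15,
                                   negative_control = 25),
             genome_length_bp = 2e7, ...)
}

paired_ratios <- function(study, n_pairs) {
  pairing <- data.frame(tumor = sprintf("T%02d", seq_len(n_pairs)),
                        nontumor = sprintf("N%02d", seq_len(n_pairs)))
  log2_ratio(study$intensities, pairing)
}
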