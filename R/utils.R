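# Internal helpers shared across modules.

# Ordered sub-seeds derived from one global seed, so each generator stage is
# reproducible on its own. Kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  (as.integer(seed %% 1000003L) * 1009L + as.integer(k)) %% 2147483647L
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
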