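test_that("F.E.T. fractions follow the defining arithmetic", {
  one <- fraction_expression(c(t1 = 0, t2 = 7, t3 = 0))
  expect_equal(one$max_fet, 1)
  expect_true(one$specific)
  unif <- fraction_expression(setNames(rep(2, 9), paste0("t", 1:9)))
  expect_equal(unif$max_fet, 1 / 9)
  expect_false(unif$specific)
  half <- fraction_expression(c(10, 10, 0, 0))
  expect_equal(unname(unlist(half[, paste0("fet_", 1:4)])),
               c(0.5, 0.5, 0, 0))
  expect_true(half$specific)  # boundary >= 0.5
  # scale invariance and degenerate rows
  m <- matrix(c(1, 2, 3, 0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "zero"), paste0("t", 1:3)))
  f1 <- fraction_expression(m)
  f2 <- fraction_expression(m * 17)
  expect_equal(f1$max_fet, f2$max_fet)
  expect_false(f1$expressed[f1$id == "zero"])
  expect_false(f1$specific[f1$id == "zero"])
  expect_error(fraction_expression(c(-1, 2)), "negative")
})

test_that("specificity Fisher test matches exact enumeration", {
  # equal rates on a balanced table: no association
  eq <- specificity_fisher(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(eq$p, 1)
  # [[8,2],[2,8]] against the exhaustive hypergeometric oracle
  ft <- specificity_fisher(rep(c(TRUE, FALSE), c(8, 2)),
                           rep(c(TRUE, FALSE), c(2, 8)))
  expect_equal(ft$p, oracle_fisher_two_sided(matrix(c(8, 2, 2, 8), 2)),
               tolerance = 1e-9)
  # planted 3x specificity rate at n = 500 per group is decisive
  set.seed(21)
  hits <- sapply(1:5, function(k) {
    lnc <- runif(500) < 0.3; mrna <- runif(500) < 0.1
    specificity_fisher(lnc, mrna)$p < 0.001
  })
  expect_true(all(hits))
  expect_error(specificity_fisher(logical(0), TRUE), "non-empty")
})

test_that("conservation enrichment counts overlaps and saturates correctly", {
  seqlens <- c(chr1 = 100000)
  qs <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(1000, 28000, by = 3000),
                                                width = 500),
                               seqlengths = seqlens)
  names(qs) <- sprintf("q%02d", seq_along(qs))
  ctrl <- make_random_controls(GenomicRanges::width(qs), seqlens,
                               n_sets = 2, seed = 3)
  # whole-genome element track: everything overlaps, p = 1
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000),
                                  seqlengths = seqlens)
  sat <- conservation_enrichment(qs, whole, ctrl)
  expect_equal(sat$n_overlapping, length(qs))
  expect_equal(max(sat$per_control$fisher_p), 1)
  # empty track: zero overlap everywhere
  none <- conservation_enrichment(qs, whole[0], ctrl)
  expect_equal(none$n_overlapping, 0L)
  # monotonicity: adding elements never decreases the overlap count
  el1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1100, 7100),
                                                         width = 100),
                                seqlengths = seqlens)
  el2 <- c(el1, GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(13100, width = 100),
                                       seqlengths = seqlens))
  expect_lte(conservation_enrichment(qs, el1, ctrl)$n_overlapping,
             conservation_enrichment(qs, el2, ctrl)$n_overlapping)
  # Fisher p equals enumeration on a small instance
  ce <- conservation_enrichment(qs, el2, ctrl)
  i <- 1
  tab <- matrix(c(ce$n_overlapping, ce$n_total - ce$n_overlapping,
                  ce$per_control$n_overlapping[i],
                  ce$n_total - ce$per_control$n_overlapping[i]), 2)
  expect_equal(ce$per_control$fisher_p[i], oracle_fisher_two_sided(tab),
               tolerance = 1e-9)
})

test_that("expression conservation records species hits and fractions", {
  seqlens <- c(chr1 = 50000)
  qs <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1000, 5000, 9000),
                                                width = 400),
                               seqlengths = seqlens)
  names(qs) <- c("a", "b", "a_dup")
  sp <- list(mouse = GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(1100, 1200)),
             rat = GenomicRanges::GRanges("chr1",
                                          IRanges::IRanges(40000, 40100)))
  ec <- expression_conservation(qs, sp)
  expect_equal(dim(ec$hits), c(3L, 2L))
  expect_true(ec$hits["a", "mouse"])
  expect_false(ec$hits["b", "mouse"])
  expect_equal(ec$n_hit, 1L)
  # empty tracks give fraction zero
  empty <- lapply(sp, function(x) x[0])
  expect_equal(expression_conservation(qs, empty)$fraction, 0)
  # duplicated query rows behave identically
  qs2 <- qs; GenomicRanges::ranges(qs2)[3] <- GenomicRanges::ranges(qs)[1]
  ec2 <- expression_conservation(qs2, sp)
  expect_equal(unname(ec2$hits["a", ]), unname(ec2$hits["a_dup", ]))
})

test_that("syntenic overlap lengths are bounded by both intervals", {
  seqlens <- c(chr1 = 50000)
  qs <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1000, 5000), width = 400),
                               seqlengths = seqlens)
  names(qs) <- c("a", "b")
  null_q <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(20000, 30000),
                                                    width = 400),
                                   seqlengths = seqlens)
  names(null_q) <- c("n1", "n2")
  # foreign interval identical to query a: overlap length = full width
  foreign <- qs["a"]
  names(foreign) <- NULL
  syn <- syntenic_overlap(qs, foreign, null_q)
  expect_equal(syn$overlapping, "a")
  expect_equal(unname(syn$overlap_bp["a"]), 400L)
  expect_true(all(syn$overlap_bp >= 1))
  expect_true(all(syn$overlap_bp <= 400))
  expect_equal(syn$n_null_hit, 0L)
})
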