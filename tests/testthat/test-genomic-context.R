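gr <- function(chrom, start, end, strand = "*", seqlens = NULL) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                         seqlengths = seqlens)
}

test_that("TSS follows strand and rejects unstranded intervals", {
  # BED-style (0-based half-open) interval chr1:100-200 is GRanges 101-200
  plus <- gr("chr1", 101, 200, "+")
  minus <- gr("chr1", 101, 200, "-")
  expect_equal(unname(tss_of(plus)), 101)   # 0-based position 100
  expect_equal(unname(tss_of(minus)), 200)  # 0-based position 199
  expect_error(tss_of(gr("chr1", 101, 200, "*")), "unstranded")
  tg <- tss_granges(minus)
  expect_equal(GenomicRanges::start(tg), 200)
  expect_equal(GenomicRanges::width(tg), 1)
})

test_that("random controls match query lengths, avoid exclusions, reproduce", {
  seqlens <- c(chr1 = 100000, chr2 = 50000)
  lens <- c(500L, 1000L, 200L, 700L)
  exc <- gr("chr1", 1, 60000, seqlens = seqlens)
  sets <- make_random_controls(lens, seqlens, exclusions = exc,
                               n_sets = 5, seed = 9)
  for (s in sets) {
    expect_equal(sort(GenomicRanges::width(s)), sort(lens))
    expect_equal(sum(GenomicRanges::countOverlaps(s, exc)), 0)
  }
  sets2 <- make_random_controls(lens, seqlens, exclusions = exc,
                                n_sets = 5, seed = 9)
  expect_identical(lapply(sets, as.data.frame), lapply(sets2, as.data.frame))
  # forced placement: only one window exactly fits a full-length interval
  seq1 <- c(chr1 = 10000)
  exc1 <- c(gr("chr1", 1, 4999, seqlens = seq1),
            gr("chr1", 5300, 10000, seqlens = seq1))
  one <- make_random_controls(300L, seq1, exclusions = exc1, n_sets = 2,
                              seed = 1)
  for (s in one) {
    expect_equal(GenomicRanges::start(s), 5000)
    expect_equal(GenomicRanges::end(s), 5299)
  }
  expect_error(make_random_controls(600L, seq1, exclusions = exc1,
                                    n_sets = 1),
               "placement failure")
})

test_that("nearest-mark distances follow the edge-distance convention", {
  seqlens <- c(chr1 = 1e6, chr2 = 1e6)
  # point marks at 3200 and 7100; TSS at 5000 -> distance 1800, bin 1
  q <- gr("chr1", 5000, 5000, seqlens = seqlens)
  tr <- gr("chr1", c(3200, 7100), c(3200, 7100), seqlens = seqlens)
  dd <- distance_distribution(q, tr, max_dist = 10000, bin = 1000)
  expect_equal(unname(dd$distances), 1800)
  expect_equal(unname(dd$bin_index), 1)
  expect_equal(unname(dd$histogram[2]), 1L)
  # overlap gives zero
  tr2 <- gr("chr1", 4900, 5100)
  expect_equal(unname(distance_distribution(q, tr2)$distances), 0)
  # queries on a mark-free chromosome are excluded and tallied
  q2 <- c(q, gr("chr2", 100, 100, seqlens = seqlens))
  dd2 <- distance_distribution(q2, tr)
  expect_equal(length(dd2$distances), 1)
  expect_equal(dd2$n_no_mark, 1)
  # translation invariance
  sh <- 12345
  dd3 <- distance_distribution(gr("chr1", 5000 + sh, 5000 + sh, seqlens = seqlens),
                               GenomicRanges::shift(tr, sh))
  expect_equal(unname(dd3$distances), unname(dd$distances))
  expect_error(distance_distribution(q, tr[0]), "empty")
})

test_that("score filtering keeps CAGE-like marks at RPKM >= 1", {
  tr <- gr("chr1", c(10, 20, 30), c(15, 25, 35))
  S4Vectors::mcols(tr)$rpkm <- c(0.5, 1, 3)
  kept <- filter_track_by_score(tr, "rpkm", 1)
  expect_equal(GenomicRanges::start(kept), c(20, 30))
  expect_error(filter_track_by_score(tr, "nope"), "score column")
})

test_that("KS statistic matches the brute-force ECDF supremum", {
  set.seed(11)
  x <- rexp(80, 1 / 500); y <- runif(120, 0, 5000)
  ks <- ks_enrichment_test(x, list(y))
  expect_equal(ks$per_control$D, oracle_ks_D(x, y), tolerance = 1e-12)
  # identical distributions: D = 0, p = 1
  same <- ks_enrichment_test(x, list(x))
  expect_equal(same$per_control$D, 0)
  expect_equal(same$per_control$p, 1)
  # exponential query vs uniform control at n = 200: decisive rejection
  rejected <- sapply(1:5, function(k) {
    set.seed(100 + k)
    q <- rexp(200, 1 / 500); ctrl <- runif(200, 0, 10000)
    ks_enrichment_test(q, list(ctrl))$per_control$p < 0.001
  })
  expect_true(all(rejected))
  expect_error(ks_enrichment_test(numeric(0), list(y)), "empty")
})

test_that("overlap counting uses half-open BED semantics", {
  # BED query (100,200) vs marks (150,160), (199,300), (200,210)
  q <- gr("chr1", 101, 200)
  marks <- gr("chr1", c(151, 200, 201), c(160, 300, 210))
  expect_equal(unname(overlap_count(q, marks)), 2)
  expect_equal(unname(suppressWarnings(overlap_count(q, gr("chr2", 1, 10)))),
               0)
  # nested mark counts once
  expect_equal(unname(overlap_count(q, gr("chr1", 120, 130))), 1)
})

test_that("BED round trip preserves interval semantics", {
  skip_if_not_installed("rtracklayer")
  tmp <- tempfile(fileext = ".bed")
  g <- gr("chr1", c(101, 500), c(200, 650), c("+", "-"))
  write_bed(g, tmp)
  txt <- read.table(tmp, sep = "\t")
  expect_equal(txt$V2, c(100, 499))  # 0-based starts on disk
  expect_equal(txt$V3, c(200, 650))
  back <- read_bed(tmp)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(g))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(g))
})
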