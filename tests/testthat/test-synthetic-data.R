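test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(frac_de = 1.2), "fractions")
  expect_error(sim_config(planted_log2fc = 0.3), "log2")
  expect_error(sim_config(n_pairs = 2), "n_pairs")
  expect_error(sim_config(n_probes_by_class = c(intronic_antisense = 10)),
               "classes")
})

test_that("identical seeds give byte-identical outputs and counts match", {
  cfg <- small_config(seed = 42)
  a <- simulate_rcc_dataset(cfg)
  b <- simulate_rcc_dataset(cfg)
  expect_identical(a$study$intensities, b$study$intensities)
  expect_identical(a$study$pools, b$study$pools)
  expect_identical(as.data.frame(a$context$lnc), as.data.frame(b$context$lnc))
  expect_identical(a$tissue$lnc_fpkm, b$tissue$lnc_fpkm)
  counts <- table(a$study$probes$class)
  expect_equal(as.integer(counts[names(cfg$n_probes_by_class)]),
               unname(cfg$n_probes_by_class))
})

test_that("every planted id resolves to a generated entity", {
  ds <- simulate_rcc_dataset(small_config(seed = 3))
  ids <- ds$study$probes$probe_id
  tr <- ds$truth
  expect_true(all(names(tr$de_probes) %in% ids))
  expect_true(all(names(tr$survival_probes) %in% ids))
  expect_true(all(tr$cis_pairs$lnc %in% ids))
  expect_true(all(tr$cis_pairs$host %in% ds$study$probes$gene_id))
  expect_true(all(names(tr$trans_modules) %in% ids))
  expect_true(all(tr$marked_tss %in% names(ds$context$lnc)))
  expect_true(all(tr$conserved_lnc %in% rownames(ds$tissue$lnc_fpkm)))
})

test_that("planted differential expression has the configured effect size", {
  cfg <- sim_config(seed = 11, frac_de = 0.1, planted_log2fc = 1.0,
                    n_pairs = 11,
                    n_probes_by_class = c(intronic_antisense = 300,
                                          protein_coding = 100,
                                          lincRNA = 30,
                                          negative_control = 30),
                    genome_length_bp = 3e7)
  es <- simulate_expression_study(cfg)
  ratios <- paired_ratios(es$study, cfg$n_pairs)
  m <- rowMeans(ratios)
  tr <- es$truth$de_probes
  # planted probes: per-probe mean ratio within 3 SE of the signed effect
  se <- sqrt(2) * cfg$noise_sd / sqrt(cfg$n_pairs)
  expect_true(all(abs(m[names(tr)] - tr) < 3 * se + 0.1))
  # null configuration: no systematic shift after normalization removes
  # the per-array effects
  es0 <- simulate_expression_study(sim_config(seed = 12, frac_de = 0,
    n_probes_by_class = cfg$n_probes_by_class, genome_length_bp = 3e7))
  es0$study$intensities <- quantile_normalize(es0$study$intensities)
  m0 <- rowMeans(paired_ratios(es0$study, 11))
  expect_lt(abs(mean(m0)), 3 * sd(m0) / sqrt(length(m0)) + 0.02)
})

test_that("negative controls carry background noise only", {
  es <- simulate_expression_study(small_config(seed = 5))
  neg <- es$study$probes$probe_id[es$study$probes$class == "negative_control"]
  lv <- log2(es$study$intensities[neg, ])
  # no probe-level effects: between-probe SD of means close to noise_sd/sqrt(n)
  probe_means <- rowMeans(lv)
  expect_lt(sd(probe_means), 3 * 0.3 / sqrt(ncol(lv)))
})

test_that("lncRNA intervals lie wholly inside their host introns, antisense", {
  ds <- simulate_rcc_dataset(small_config(seed = 7))
  lnc <- ds$context$lnc
  introns <- ds$context$introns[S4Vectors::mcols(lnc)$host_gene]
  expect_true(all(GenomicRanges::start(lnc) >= GenomicRanges::start(introns)))
  expect_true(all(GenomicRanges::end(lnc) <= GenomicRanges::end(introns)))
  expect_true(all(as.character(GenomicRanges::strand(lnc)) !=
                    as.character(GenomicRanges::strand(introns))))
})

test_that("planted marks fall near their TSS at the configured scale", {
  cfg <- small_config(seed = 9, frac_marked = 0.5, mark_decay_bp = 500)
  ds <- simulate_rcc_dataset(cfg)
  tss <- tss_of(ds$context$lnc[ds$truth$marked_tss])
  cage <- ds$context$tracks$cage
  planted <- cage[S4Vectors::mcols(cage)$planted]
  centre <- (GenomicRanges::start(planted) + GenomicRanges::end(planted)) / 2
  d <- abs(centre - tss)
  # exponential CDF at 2 kb with scale 500 is ~0.98; demand at least 90%
  expect_gte(mean(d <= 2000), 0.9)
})

test_that("null mark configuration shows no TSS proximity signal", {
  cfg <- small_config(seed = 10, frac_marked = 0)
  ds <- simulate_rcc_dataset(cfg)
  q <- tss_granges(ds$context$lnc)
  qd <- distance_distribution(q, ds$context$tracks$cpg_island)
  ctrl <- make_random_controls(GenomicRanges::width(ds$context$lnc),
                               ds$context$seqlengths, n_sets = 3, seed = 4)
  cd <- lapply(ctrl, function(g)
    distance_distribution(GenomicRanges::resize(g, 1, fix = "start"),
                          ds$context$tracks$cpg_island))
  ks <- ks_enrichment_test(qd, cd)
  expect_gt(min(ks$per_control$p), 0.001)
})

test_that("tissue-specific rows and conservation overlap follow the planting", {
  cfg <- small_config(seed = 13, frac_conserved = 0.6,
                      conserved_background = 0.05)
  ds <- simulate_rcc_dataset(cfg)
  fet <- fraction_expression(ds$tissue$lnc_fpkm)
  planted <- fet$specific[fet$id %in% ds$truth$tissue_specific_lnc]
  expect_true(all(planted))
  # binomial-mixture oracle: overlap rate ~ 0.6 + 0.4 * 0.05
  hit <- overlap_count(ds$context$lnc, ds$tissue$conserved_elements) > 0
  p_mix <- 0.6 + 0.4 * 0.05
  n <- length(hit)
  bounds <- qbinom(c(0.005, 0.995), n, p_mix) / n
  expect_gte(mean(hit), bounds[1] - 0.02)
  expect_lte(mean(hit), bounds[2] + 0.02)
})
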