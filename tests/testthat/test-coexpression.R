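test_that("Spearman correlation handles monotone maps and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # tie-aware oracle from explicit average ranks
  xt <- c(1, 2, 2, 4); yt <- c(1, 3, 2, 4)
  sc <- spearman_cor(xt, yt)
  expect_equal(sc$rho, oracle_spearman(xt, yt), tolerance = 1e-12)
  # symmetry, and agreement with the stats t-approximation
  sc2 <- spearman_cor(yt, xt)
  expect_identical(sc$rho, sc2$rho)
  ct <- suppressWarnings(cor.test(xt, yt, method = "spearman", exact = FALSE))
  expect_equal(sc$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sc$p, ct$p.value, tolerance = 1e-9)
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("cis cutoff is strict and trans cutoff inclusive", {
  # ranks (3,2,1,5,4) vs 1:5 give rho exactly 0.5
  lnc <- matrix(c(1:5), 1, 5, dimnames = list("l1", NULL))
  mr05 <- matrix(c(3, 2, 1, 5, 4), 1, 5, dimnames = list("g1", NULL))
  map <- data.frame(lnc = "l1", gene = "g1")
  cis <- cis_correlation(lnc, mr05, map, rho_cut = 0.5, p_cut = 1)
  expect_equal(spearman_cor(lnc[1, ], mr05[1, ])$rho, 0.5)
  expect_equal(nrow(cis$records), 0)           # rho == cutoff excluded
  expect_equal(cis$summary$n_tested, 1)
  # ranks (1,2,5,3,4) give rho exactly 0.7: inclusive for trans
  mr07 <- matrix(c(1, 2, 5, 3, 4), 1, 5, dimnames = list("g2", NULL))
  tr <- trans_correlation(lnc, mr07, data.frame(lnc = "l1", gene = "other"),
                          rho_cut = 0.7, p_cut = 1)
  expect_equal(nrow(tr$records), 1)
  expect_equal(tr$records$rho, 0.7)
  # a pair sharing a locus never enters the trans records
  tr2 <- trans_correlation(lnc, mr07, data.frame(lnc = "l1", gene = "g2"),
                           rho_cut = 0.7, p_cut = 1)
  expect_equal(nrow(tr2$records), 0)
})

test_that("top-abundance selection floors the count and is tie-stable", {
  expect_error(select_top_abundant(setNames(1:4, letters[1:4]), frac = 0),
               "frac")
  a <- setNames(rep(1, 10), sprintf("l%02d", 10:1))
  expect_message(top <- select_top_abundant(a, 0.2), "tie")
  expect_equal(top, c("l01", "l02"))           # id order under total ties
  expect_identical(top, suppressMessages(select_top_abundant(a, 0.2)))
  b <- setNames(seq_len(10), sprintf("l%02d", 1:10))
  expect_equal(select_top_abundant(b, 0.2), c("l10", "l09"))
})

test_that("planted cis pairs are recovered and record sets stay disjoint", {
  ds <- simulate_rcc_dataset(small_config(seed = 61, frac_cis = 0.3))
  cis <- cis_correlation(ds$tissue$lnc_expr, ds$tissue$mrna_expr,
                         ds$tissue$locus_map)
  expect_gte(mean(ds$truth$cis_pairs$lnc %in% cis$records$lnc_id), 0.8)
  # planted sign agrees with the recovered direction
  hit <- merge(cis$records, ds$truth$cis_pairs,
               by.x = "lnc_id", by.y = "lnc")
  expect_true(all(sign(hit$rho) == hit$sign))
  tr <- trans_correlation(ds$tissue$lnc_expr, ds$tissue$mrna_expr,
                          ds$tissue$locus_map)
  cis_keys <- paste(cis$records$lnc_id, cis$records$partner_id)
  trans_keys <- paste(tr$records$lnc_id, tr$records$partner_id)
  expect_length(intersect(cis_keys, trans_keys), 0)
})

test_that("trans records are rare on null data at the stated cuts", {
  # at |rho| >= 0.7 with p < 0.05 over 12 pseudo-tissues, a null pair passes
  # with probability ~0.01; the observed rate should stay near that level
  rates <- sapply(1:5, function(k) {
    ds <- simulate_rcc_dataset(small_config(seed = 70 + k, frac_cis = 0,
                                            frac_trans = 0))
    n_rec <- nrow(trans_correlation(ds$tissue$lnc_expr[1:40, ],
                                    ds$tissue$mrna_expr[1:40, ],
                                    ds$tissue$locus_map)$records)
    n_rec / (40 * nrow(ds$tissue$mrna_expr))
  })
  expect_true(all(rates < 0.03))
})

test_that("module map enrichment matches an enumeration oracle and recovers planted modules", {
  # 20-gene toy universe
  bg <- sprintf("g%02d", 1:20)
  term_genes <- bg[1:8]
  ann <- data.frame(gene = c(term_genes, bg[9:14]),
                    term = c(rep("GO:A", 8), rep("GO:B", 6)))
  rec <- data.frame(lnc_id = "lnc1", partner_id = bg[c(1:5, 15)],
                    rho = c(.9, .8, .85, .95, .9, -.8), p = 0.01,
                    mode = "trans",
                    direction = c(rep("direct", 5), "inverse"))
  mm <- go_module_map(rec, ann, bg, alpha = 0.05)
  rowA <- mm[mm$term == "GO:A", ]
  p_oracle <- oracle_hyper_tail(5, 8, 12, 6)
  expect_equal(rowA$p_raw, p_oracle, tolerance = 1e-12)
  expect_equal(rowA$p_adj, min(1, p_oracle * 2))
  expect_equal(rowA$sign, 1L)
  expect_true(all(mm$p_adj >= mm$p_raw - 1e-15))
  # degenerate universe: correlated set = term = background is uninformative
  rec2 <- data.frame(lnc_id = "lnc1", partner_id = bg, rho = 0.9, p = 0.01,
                     mode = "trans", direction = "direct")
  ann2 <- data.frame(gene = bg, term = "GO:ALL")
  mm2 <- go_module_map(rec2, ann2, bg)
  expect_equal(mm2$p_raw, 1)
  expect_equal(mm2$sign, 0L)
  # planted module recovery through the simulated annotation
  ds <- simulate_rcc_dataset(small_config(seed = 81, frac_trans = 0.1))
  tr <- trans_correlation(ds$tissue$lnc_expr, ds$tissue$mrna_expr,
                          ds$tissue$locus_map)
  mm3 <- go_module_map(tr, ds$tissue$go_annotation,
                       rownames(ds$tissue$mrna_expr))
  planted_terms <- sprintf("GO:MOD_%s", names(ds$truth$trans_modules))
  found <- mm3[mm3$term %in% planted_terms &
                 mm3$lnc_id == sub("GO:MOD_", "", mm3$term), ]
  expect_gte(mean(found$sign != 0), 0.8)
  expect_error(go_module_map(rec, ann[0, ], bg), "empty")
})
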