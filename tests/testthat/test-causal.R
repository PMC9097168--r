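# Mendelian randomization (instrument selection, harmonization, Wald
# ratio) and ABF colocalization.

test_that("instrument selection keeps the top hit per gene x tissue under the threshold", {
  cl <- classify_variants(rbind(
    make_record(rsid = "rs1"),
    transform(make_record(rsid = "rs2"), pos = 200L, vid = "v2"),
    transform(make_record(rsid = "rs3"), pos = 300L, vid = "v3")))
  eq <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs1"),
    gene_id = c("g1", "g1", "g2", "g3"),
    tissue = "T1",
    slope = c(0.5, 0.4, 0.3, 0.2), slope_se = 0.1,
    pval_nominal = c(1e-5, 1e-6, 1e-3, 1e-5))
  ins <- select_instruments(eq, cl, p_threshold = 5e-4)
  expect_equal(sort(ins$gene_id), c("g1", "g3"))       # g2 fails the threshold
  expect_equal(ins$variant_id[ins$gene_id == "g1"], "rs2")
  # ties in p break deterministically by position
  eq_tie <- data.frame(variant_id = c("rs3", "rs2"), gene_id = "g9",
                       tissue = "T1", slope = 1, slope_se = 0.1,
                       pval_nominal = 1e-5)
  ins_tie <- select_instruments(eq_tie, cl)
  expect_equal(ins_tie$variant_id, "rs2")              # smaller position
  # variants outside the derived catalog are never selected
  eq_out <- data.frame(variant_id = "rs99", gene_id = "g1", tissue = "T1",
                       slope = 1, slope_se = 0.1, pval_nominal = 1e-9)
  expect_equal(nrow(select_instruments(eq_out, cl)), 0)
})

test_that("harmonization aligns, flips and drops as specified", {
  ins <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                    gene_id = "g", tissue = "T1",
                    slope = 0.5, slope_se = 0.05,
                    effect_allele = c("G", "G", "A", "G"),
                    other_allele = c("A", "A", "T", "A"))
  gwas <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4"),
                     beta = c(0.3, 0.3, 0.3, 0.3), se = 0.1,
                     effect_allele = c("G", "A", "A", "C"),
                     other_allele = c("A", "G", "T", "T"),
                     eaf = c(0.8, 0.8, 0.50, 0.8))
  h <- suppressMessages(harmonize_effects(ins, gwas))
  # same allele: identity; swapped: sign flip; palindromic A/T at EAF 0.5
  # and incompatible alleles: dropped
  expect_equal(h$variant_id, c("rs1", "rs2"))
  expect_equal(h$beta_outcome, c(0.3, -0.3))
  # palindromic variant with unambiguous frequency is kept
  gwas$eaf[3] <- 0.9
  h2 <- suppressMessages(harmonize_effects(ins, gwas))
  expect_true("rs3" %in% h2$variant_id)
})

test_that("Wald ratio formula, scale invariance and degenerate input", {
  w <- wald_ratio(0.5, 0.1, 0.2, 0.05)
  expect_equal(w$beta_iv, 0.4)
  expect_equal(w$se_iv, 0.1)
  expect_equal(wald_ratio(1, 0.1, 0, 0.05)$beta_iv, 0)
  expect_gt(wald_ratio(1, 0.1, 0, 0.05)$p, 0.99)
  # scaling the exposure by c rescales the ratio by 1/c exactly
  c_ <- 3.7
  w2 <- wald_ratio(0.5 * c_, 0.1 * c_, 0.2, 0.05)
  expect_equal(w2$beta_iv, w$beta_iv / c_)
  expect_equal(w2$se_iv, w$se_iv / c_)
  expect_error(wald_ratio(0, 0.1, 0.2, 0.05), "zero exposure")
})

test_that("Wald intervals cover a simulated causal ratio at the nominal rate", {
  set.seed(12)
  rho <- 0.4
  cover <- replicate(500, {
    be <- runif(1, 0.4, 0.8); se_e <- 0.02; se_o <- 0.05
    be_h <- be + rnorm(1, 0, se_e)
    bo_h <- rho * be + rnorm(1, 0, se_o)
    w <- wald_ratio(be_h, se_e, bo_h, se_o)
    abs(w$beta_iv - rho) <= qnorm(0.975) * w$se_iv
  })
  expect_gte(mean(cover), 0.93)
})

test_that("random allele flips in the GWAS emission do not change the Wald ratio", {
  fx <- fixture_sim()
  causal <- attr(fx$eqtls, "causal")
  gw <- gen_gwas_summary(fx$cfg, fx$catalog, fx$truth, fx$panel,
                         eqtl_causal = causal, trait = "flip_check")
  cl <- classify_variants(fx$catalog)
  ins <- select_instruments(fx$eqtls, cl, p_threshold = 5e-4)
  h1 <- suppressMessages(harmonize_effects(ins, gw))
  # flip every GWAS record's allele orientation; harmonization must undo it
  gw2 <- gw
  gw2$beta <- -gw$beta
  gw2$effect_allele <- gw$other_allele
  gw2$other_allele <- gw$effect_allele
  gw2$eaf <- 1 - gw$eaf
  h2 <- suppressMessages(harmonize_effects(ins, gw2))
  shared <- intersect(h1$variant_id, h2$variant_id)
  m1 <- h1[match(shared, h1$variant_id), ]
  m2 <- h2[match(shared, h2$variant_id), ]
  w1 <- wald_ratio(m1$beta_exposure, m1$se_exposure, m1$beta_outcome,
                   m1$se_outcome)
  w2 <- wald_ratio(m2$beta_exposure, m2$se_exposure, m2$beta_outcome,
                   m2$se_outcome)
  expect_equal(w1$beta_iv, w2$beta_iv)
})

test_that("colocalization posteriors are normalized, null-dominated under H0 and monotone in p12", {
  set.seed(5)
  n <- 50
  null1 <- data.frame(snp = paste0("s", 1:n), beta = rep(0, n), se = 0.05)
  r0 <- coloc_abf(null1, null1)
  expect_equal(sum(r0$summary[-1]), 1, tolerance = 1e-9)
  expect_equal(names(which.max(r0$summary[-1])), "PP0")

  reg <- gen_coloc_region("H4", seed = 33)
  r4 <- coloc_abf(reg$trait1, reg$trait2)
  expect_equal(sum(r4$summary[-1]), 1, tolerance = 1e-9)

  pp4 <- vapply(c(1e-7, 1e-6, 1e-5, 1e-4),
                function(p12) coloc_abf(reg$trait1, reg$trait2,
                                        p12 = p12)$summary[["PP4"]],
                numeric(1))
  expect_true(all(diff(pp4) >= 0))

  expect_warning(coloc_abf(data.frame(snp = "a", beta = 1, se = 0.1),
                           data.frame(snp = "a", beta = 1, se = 0.1)),
                 "single-variant")
  expect_error(coloc_abf(null1, data.frame(snp = "zz", beta = 0, se = 1)),
               "shared")
})

test_that("colocalization discriminates shared from distinct causal variants", {
  pp4_h4 <- vapply(1:15, function(i) {
    r <- gen_coloc_region("H4", seed = 300 + i)
    coloc_abf(r$trait1, r$trait2)$summary[["PP4"]]
  }, numeric(1))
  expect_gt(mean(pp4_h4), 0.8)
  h3 <- vapply(1:15, function(i) {
    r <- gen_coloc_region("H3", seed = 400 + i)
    s <- coloc_abf(r$trait1, r$trait2)$summary
    s[["PP3"]] - s[["PP4"]]
  }, numeric(1))
  expect_gt(mean(h3), 0)
})

test_that("mr_wald applies Bonferroni over the whole gene x trait family", {
  fx <- fixture_sim()
  cl <- classify_variants(fx$catalog)
  ins <- select_instruments(fx$eqtls, cl)
  causal <- attr(fx$eqtls, "causal")
  gl <- list(
    t1 = gen_gwas_summary(fx$cfg, fx$catalog, fx$truth, fx$panel,
                          eqtl_causal = causal, trait = "t1"),
    t2 = gen_gwas_summary(fx$cfg, fx$catalog, fx$truth, fx$panel,
                          eqtl_causal = causal, trait = "t2"))
  mr <- suppressMessages(mr_wald(ins, gl))
  expect_true(all(mr$p_bonferroni >= mr$p - 1e-15))
  expect_equal(mr$p_bonferroni, pmin(1, mr$p * nrow(mr)))
  expect_error(mr_wald(ins, list()), "no GWAS")
})
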