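# Synthetic-data generator: determinism, frequency consistency,
# ground-truth/classifier consistency and the LD copying model.

test_that("configuration is validated", {
  expect_error(sim_config(n_variants = 0), "positive")
  expect_error(sim_config(hf_fraction = 1.2), "0, 1")
  expect_error(sim_config(sweep_enrichment_factor = 0.5), ">= 1")
  expect_error(sim_config(tissue_enrichment = c(NotATissue = 2)), "tissues")
})

test_that("identical config and seed give identical outputs", {
  fx <- fixture_sim()
  panel2 <- gen_haplotypes(fx$cfg)
  expect_identical(fx$panel$H, panel2$H)
  vc2 <- gen_variant_catalog(fx$cfg, panel2)
  expect_identical(fx$catalog, vc2$catalog)
  eq2 <- gen_eqtl_tables(fx$cfg, vc2$catalog, vc2$truth, panel2)
  expect_identical(fx$eqtls$slope, eq2$slope)
  w1 <- gen_sweep_windows(fx$cfg, fx$catalog, fx$truth)
  w2 <- gen_sweep_windows(fx$cfg, fx$catalog, fx$truth)
  expect_identical(w1, w2)
})

test_that("catalog global frequency equals the panel column frequency", {
  fx <- fixture_sim()
  expect_equal(fx$catalog$af_global, unname(colMeans(fx$panel$H)),
               tolerance = 1e-12)
})

test_that("ground-truth labels agree with the classifier, and every non-HF variant fails its designated rule", {
  fx <- fixture_sim()
  cl <- classify_variants(fx$catalog)
  expect_identical(cl$is_derived_hf, fx$truth$is_derived_hf)
  # each failure mode takes down the matching flag
  fm <- fx$truth$failure_mode
  expect_true(all(cl$af_derived[fm == "freq_lo"] < 0.9 |
                    !cl$derived_major[fm == "freq_lo"]))
  expect_true(all(!cl$hf_all_metapops[fm == "metapop"]))
  expect_true(all(cl$hf_global[fm == "metapop"]))
  expect_true(all(!cl$archaic_ok[fm == "archaic"]))
  expect_true(all(!cl$ancestral_resolved[fm == "ancestral"]))
  expect_true(all(!cl$passes_coverage[fm == "coverage"]))
})

test_that("hf_fraction = 0 yields no classified variant", {
  cfg <- sim_config(n_variants = 300, n_haplotypes = 40, hf_fraction = 0,
                    seed = 9)
  vc <- gen_variant_catalog(cfg, gen_haplotypes(cfg))
  cl <- classify_variants(vc$catalog)
  expect_equal(sum(cl$is_derived_hf), 0)
})

test_that("zero switch probability reproduces templates exactly", {
  cfg <- sim_config(n_variants = 60, n_haplotypes = 30, n_templates = 4,
                    switch_prob = 0, enforce_freq = FALSE, seed = 3,
                    chrom_lengths = c(c1 = 1e6))
  panel <- gen_haplotypes(cfg)
  distinct <- unique(apply(panel$H, 1, paste, collapse = ""))
  expect_lte(length(distinct), 4)
  # within a template class, r2 between polymorphic sites is exactly 1
  cls <- apply(panel$H, 1, paste, collapse = "")
  big <- names(sort(table(cls), decreasing = TRUE))[1]
  rows <- which(cls == big)
  expect_true(all(panel$H[rows[1], ] == panel$H[rows[length(rows)], ]))
})

test_that("distant sites decorrelate under per-site switching", {
  r2_means <- vapply(1:10, function(s) {
    cfg <- sim_config(n_variants = 40, n_haplotypes = 10000, hf_fraction = 0,
                      switch_prob = 0.5, seed = 100 + s,
                      chrom_lengths = c(c1 = 1e7))
    panel <- gen_haplotypes(cfg)
    af <- colMeans(panel$H)
    poly <- which(af > 0 & af < 1)
    far <- cbind(head(poly, 10), tail(poly, 10))  # first vs last sites
    mean(apply(far, 1, function(ij) ld_r2(panel, ij[1], ij[2])))
  }, numeric(1))
  expect_lt(mean(r2_means), 0.02)
})

test_that("a Denisovan-ancestral / Neanderthal-derived variant at 0.95 everywhere is derived-HF", {
  rec <- make_record(af_derived = 0.95, gt_vindija = "A/G",
                     gt_altai = "./.")
  cl <- classify_variants(rec)
  expect_true(cl$is_derived_hf)
})

test_that("null eQTL generator produces only FDR-level false positives", {
  frac <- vapply(1:10, function(s) {
    cfg <- sim_config(n_variants = 400, n_haplotypes = 40,
                      eqtl_effect_prob = 0, seed = 500 + s)
    panel <- gen_haplotypes(cfg)
    vc <- gen_variant_catalog(cfg, panel)
    eq <- gen_eqtl_tables(cfg, vc$catalog, vc$truth, panel)
    mean(eq$qval_pass)
  }, numeric(1))
  expect_lt(mean(frac), 0.005)
})

test_that("eQTL slopes preserve the sign of strong true effects and duplicates are correlated", {
  fx <- fixture_sim()
  causal <- attr(fx$eqtls, "causal")
  strong <- causal[abs(causal$beta_true) > 0.8, ]
  m <- merge(strong, fx$eqtls,
             by.x = c("variant_id", "tissue"), by.y = c("variant_id", "tissue"))
  expect_gt(mean(sign(m$beta_true) == sign(m$slope)), 0.95)
  # duplicate tissue pair shares correlated effects
  cer <- causal[causal$tissue == "Cerebellum", c("vid", "beta_true")]
  hem <- causal[causal$tissue == "Cerebellar_Hemisphere", c("vid", "beta_true")]
  both <- merge(cer, hem, by = "vid")
  expect_gt(nrow(both), 5)
  expect_gt(cor(both$beta_true.x, both$beta_true.y), 0.8)
})

test_that("whole-genome sweep windows give overlap for every variant and p = 1", {
  fx <- fixture_sim()
  w <- data.frame(chrom = names(fx$cfg$chrom_lengths), start = 0,
                  end = as.numeric(fx$cfg$chrom_lengths), source = "all")
  pos <- data.frame(chrom = fx$truth$chrom, pos = fx$truth$pos)
  expect_equal(count_window_overlaps(pos, w), nrow(pos))
  pt <- sweep_permutation_test(pos, w, fx$cfg$chrom_lengths, n_perm = 50,
                               seed = 1)
  expect_equal(pt$p.value, 1)
})

test_that("GWAS allele orientation can be harmonized back to the simulated effect", {
  fx <- fixture_sim()
  causal <- attr(fx$eqtls, "causal")
  gw <- gen_gwas_summary(fx$cfg, fx$catalog, fx$truth, fx$panel,
                         eqtl_causal = causal, trait = "t1")
  m <- match(gw$SNP, fx$catalog$rsid)
  # re-orient betas onto the ALT allele; flipping must be an involution
  alt_beta <- ifelse(gw$effect_allele == fx$catalog$alt[m], gw$beta, -gw$beta)
  flipped <- gw
  flipped$beta <- -flipped$beta
  flipped$effect_allele <- gw$other_allele
  flipped$other_allele <- gw$effect_allele
  flipped$eaf <- 1 - gw$eaf
  alt_beta2 <- ifelse(flipped$effect_allele == fx$catalog$alt[m],
                      flipped$beta, -flipped$beta)
  expect_equal(alt_beta, alt_beta2)
})
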