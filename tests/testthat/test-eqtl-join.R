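# eQTL intersection and composition machinery: closed-form chi-square
# checks, residual properties, correlation and the sampling test.

test_that("intersection splits significant eQTLs into focal and background", {
  fx <- fixture_sim()
  cl <- classify_variants(fx$catalog)
  inter <- eqtl_intersect(cl, fx$eqtls)
  sig <- fx$eqtls[fx$eqtls$qval_pass, ]
  hf <- cl$rsid[cl$is_derived_hf & !is.na(cl$rsid)]
  expect_equal(nrow(inter$focal) + nrow(inter$background), nrow(sig))
  expect_true(all(inter$focal$variant_id %in% hf))
  expect_false(any(inter$background$variant_id %in% hf))
  # empty classified set -> empty focal with a warning
  cl0 <- cl; cl0$is_derived_hf <- FALSE
  expect_warning(i0 <- eqtl_intersect(cl0, fx$eqtls), "empty")
  expect_equal(nrow(i0$focal), 0)
})

test_that("counts on a constructed fixture are exact", {
  eq <- data.frame(variant_id = sprintf("rs%02d", 1:100),
                   tissue = "T1", qval_pass = TRUE)
  cl <- data.frame(rsid = sprintf("rs%02d", 1:40), is_derived_hf = TRUE)
  inter <- eqtl_intersect(cl, eq)
  expect_equal(nrow(inter$focal), 40)
  expect_equal(nrow(inter$background), 60)
})

test_that("chi-square statistic and adjusted residuals match closed forms", {
  # 2x2 table O = [[10, 90], [50, 850]]
  O <- matrix(c(10, 50, 90, 850), nrow = 2)
  N <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / N
  stat_hand <- sum((O - E)^2 / E)
  adj_hand <- (O - E) / sqrt(E * outer(1 - rowSums(O) / N,
                                       1 - colSums(O) / N))
  focal <- data.frame(tissue = rep(c("A", "B"), c(10, 90)))
  background <- data.frame(tissue = rep(c("A", "B"), c(50, 850)))
  res <- tissue_composition_test(focal, background)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(unclass(res$adjusted_residuals),
               unclass(adj_hand), tolerance = 1e-12, ignore_attr = TRUE)
  # cross-check against the standardized residuals of stats::chisq.test
  ct <- suppressWarnings(chisq.test(O, correct = FALSE))
  expect_equal(as.numeric(res$adjusted_residuals), as.numeric(ct$stdres),
               tolerance = 1e-10)
})

test_that("contingency margins are conserved and row swap only flips residual signs", {
  fx <- fixture_sim()
  cl <- classify_variants(fx$catalog)
  inter <- eqtl_intersect(cl, fx$eqtls)
  res <- tissue_composition_test(inter$focal, inter$background)
  expect_equal(rowSums(res$expected), rowSums(res$observed))
  expect_equal(colSums(res$expected), colSums(res$observed))
  swapped <- tissue_composition_test(inter$background, inter$focal)
  expect_equal(swapped$statistic, res$statistic)
  expect_equal(unname(swapped$adjusted_residuals["focal", ]),
               unname(-res$adjusted_residuals["focal", ]))
})

test_that("homogeneous composition gives no signal; injected enrichment flags the right tissues", {
  # identical composition at large counts: p ~ 1, nothing flagged
  big <- data.frame(tissue = rep(c("A", "B", "C"), c(400, 300, 300)))
  res <- tissue_composition_test(big, big)
  expect_gt(res$p.value, 0.99)
  expect_false(any(res$flagged))

  # generator with 3x enrichment in two tissues: both flagged positive
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_variants = 1000, n_haplotypes = 50, seed = 8200 + s,
                      tissue_enrichment = c(Pituitary = 3, Cerebellum = 3))
    panel <- gen_haplotypes(cfg)
    vc <- gen_variant_catalog(cfg, panel)
    eq <- gen_eqtl_tables(cfg, vc$catalog, vc$truth, panel)
    cl <- classify_variants(vc$catalog)
    inter <- eqtl_intersect(cl, eq)
    r <- tissue_composition_test(inter$focal, inter$background)
    adj <- r$adjusted_residuals["focal", ]
    flg <- r$flagged["focal", ]
    all(c("Pituitary", "Cerebellum") %in%
          names(which(flg & adj > 0)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("category test flags an enriched category and rejects degenerate tables", {
  cfg <- sim_config(n_variants = 800, n_haplotypes = 50, seed = 8400,
                    category_enrichment = c(UTR5 = 8, NMD_transcript = 8))
  panel <- gen_haplotypes(cfg)
  vc <- gen_variant_catalog(cfg, panel)
  eq <- gen_eqtl_tables(cfg, vc$catalog, vc$truth, panel)
  cl <- classify_variants(vc$catalog)
  inter <- eqtl_intersect(cl, eq)
  r <- category_composition_test(inter$focal, inter$background)
  adj <- r$adjusted_residuals["focal", ]
  expect_true(all(r$flagged["focal", c("UTR5", "NMD_transcript")]))
  expect_true(all(adj[c("UTR5", "NMD_transcript")] > 0))

  deg <- data.frame(variant_id = "rs1", consequence_category = "UTR5")
  expect_error(category_composition_test(deg, deg), "degenerate")
})

test_that("sample-size correlation recovers monotone and null relationships", {
  n <- setNames(seq(100, 240, by = 10), paste0("T", 1:15))
  inc <- setNames(seq_along(n) * 3, names(n))
  r <- sample_size_correlation(inc, n)
  expect_equal(r$rho, 1)
  expect_error(sample_size_correlation(setNames(rep(5, 15), names(n)), n),
               "constant")
  expect_error(sample_size_correlation(inc[1:3], n[1:3]), "four")

  # independent counts: |rho| small, p > 0.05 in most seeds
  null_ok <- vapply(1:100, function(s) {
    set.seed(9000 + s)
    cnt <- setNames(rpois(15, 50), names(n))
    rr <- sample_size_correlation(cnt, n)
    rr$p.value > 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.90)

  # a count 5x above the fit is reported as an outlier
  out <- inc; out["T8"] <- out["T8"] * 5
  ro <- sample_size_correlation(out, n)
  expect_true(ro$fit$outlier[ro$fit$tissue == "T8"])
})

test_that("region-specific sampling test is calibrated and detects forced concentration", {
  # exchangeable labels: empirical p roughly uniform (KS at 150 reps)
  set.seed(11)
  ps <- vapply(1:150, function(i) {
    d <- data.frame(variant_id = sample(sprintf("v%03d", 1:120), 250,
                                        replace = TRUE),
                    tissue = sample(paste0("T", 1:8), 250, replace = TRUE))
    region_specific_sampling_test(d, n_resamples = 50, seed = 5000 + i)$p.value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # all unique eQTLs forced into one tissue: small p
  d2 <- data.frame(
    variant_id = c(sprintf("u%02d", 1:30), rep(sprintf("s%02d", 1:20), 3)),
    tissue = c(rep("T1", 30), rep(paste0("T", 1:3), each = 20)))
  p2 <- region_specific_sampling_test(d2, n_resamples = 200, seed = 1)$p.value
  expect_lt(p2, 0.05)

  expect_error(region_specific_sampling_test(d2, n_resamples = 0), "positive")
})
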