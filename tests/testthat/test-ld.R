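# LD computation and greedy clumping: closed-form r2 cases, oracle
# equivalence and the partition/dominance/monotonicity invariants.

make_panel <- function(H, pos = NULL, chrom = NULL) {
  n <- ncol(H)
  vid <- sprintf("v%03d", seq_len(n))
  colnames(H) <- vid
  structure(list(H = H, chrom = chrom %||% rep("c1", n),
                 pos = pos %||% seq_len(n) * 1000L, vid = vid,
                 rsid = vid),
            class = "haplotype_panel")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("r2 matches hand computations and is symmetric", {
  x <- c(1L, 1L, 0L, 0L)
  # identical copy and complement both give r2 = 1
  p1 <- make_panel(cbind(x, x, 1L - x))
  expect_equal(ld_r2(p1, 1, 2), 1)
  expect_equal(ld_r2(p1, 1, 3), 1)
  # counts AB=1, Ab=1, aB=1, ab=1: pAB = pA pB, r2 = 0
  H <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  p2 <- make_panel(H)
  expect_equal(ld_r2(p2, 1, 2), 0)
  expect_equal(ld_r2(p2, 2, 1), ld_r2(p2, 1, 2))
  # agrees with the squared Pearson correlation
  set.seed(1)
  H3 <- matrix(rbinom(200, 1, 0.4), ncol = 2)
  p3 <- make_panel(H3)
  expect_equal(ld_r2(p3, 1, 2), cor(H3[, 1], H3[, 2])^2, tolerance = 1e-12)
  # monomorphic input is an explicit error
  p4 <- make_panel(cbind(rep(1L, 4), c(1L, 0L, 1L, 0L)))
  expect_error(ld_r2(p4, 1, 2), "monomorphic")
})

test_that("independent variants clump as singletons; a perfect block clumps once", {
  set.seed(2)
  H <- matrix(rbinom(400 * 10, 1, 0.5), nrow = 400)   # mutually independent
  p <- make_panel(H)
  v <- data.frame(variant_id = p$vid, chrom = p$chrom, pos = p$pos,
                  pval = runif(10))
  res <- ld_clump(v, p, r2_threshold = 0.5)
  expect_true(all(res$is_index))
  # one perfect-LD block of 10 variants -> one clump led by the smallest p
  x <- rbinom(50, 1, 0.5)
  Hb <- matrix(rep(x, 10), ncol = 10)
  pb <- make_panel(Hb)
  vb <- data.frame(variant_id = pb$vid, chrom = pb$chrom, pos = pb$pos,
                   pval = seq(0.1, 1, length.out = 10))
  resb <- ld_clump(vb, pb, r2_threshold = 0.1)
  expect_equal(sum(resb$is_index), 1)
  expect_equal(resb$clump_index, rep("v001", 10))
})

test_that("greedy clumping equals the brute-force all-pairs oracle", {
  for (s in 1:20) {
    cfg <- sim_config(n_variants = 100, n_haplotypes = 60, seed = 7000 + s,
                      chrom_lengths = c(c1 = 2e6, c2 = 1e6))
    panel <- gen_haplotypes(cfg)
    set.seed(s)
    v <- data.frame(variant_id = panel$vid, chrom = panel$chrom,
                    pos = panel$pos, pval = runif(100))
    res <- ld_clump(v, panel, r2_threshold = 0.1, window_kb = 250)
    R2 <- suppressWarnings(cor(panel$H))^2
    R2[!is.finite(R2)] <- NA
    want <- oracle_clump(v, R2, 250 * 1000)
    expect_identical(res$clump_index, want)

    # invariants: partition and index dominance
    expect_setequal(res$variant_id, v$variant_id)
    expect_true(all(res$clump_index %in% res$variant_id[res$is_index]))
    pv <- setNames(v$pval, v$variant_id)
    expect_true(all(pv[res$clump_index] <= res$pval + 1e-15))
  }
})

test_that("raising the r2 threshold never decreases the number of clumps", {
  cfg <- sim_config(n_variants = 120, n_haplotypes = 60, seed = 77,
                    chrom_lengths = c(c1 = 2e6))
  panel <- gen_haplotypes(cfg)
  set.seed(77)
  v <- data.frame(variant_id = panel$vid, chrom = panel$chrom,
                  pos = panel$pos, pval = runif(120))
  sizes <- vapply(c(0.05, 0.1, 0.3, 0.6, 0.9),
                  function(th) sum(ld_clump(v, panel, th)$is_index),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(ld_clump(v, panel, r2_threshold = 0), "0, 1")
})

test_that("variants absent from the panel survive as singleton clumps", {
  p <- make_panel(matrix(rbinom(80, 1, 0.5), ncol = 2))
  v <- data.frame(variant_id = c("v001", "v002", "ghost"),
                  chrom = "c1", pos = c(1000, 2000, 3000),
                  pval = c(0.5, 0.2, 0.01))
  expect_warning(res <- ld_clump(v, p), "absent")
  expect_true(res$is_index[res$variant_id == "ghost"])
})

test_that("tissue-specific counts match hand-constructed overlap patterns", {
  clumped <- data.frame(
    variant_id = c("a", "b", "c", "a", "d", "e"),
    tissue = c("T1", "T1", "T1", "T2", "T2", "T3"),
    is_index = TRUE)
  counts <- tissue_specific_counts(clumped)
  # a is shared T1/T2; b,c unique to T1; d unique to T2; e unique to T3
  expect_equal(counts, c(T1 = 2L, T2 = 1L, T3 = 1L))
  # identical sets across tissues -> all zeros
  same <- data.frame(variant_id = rep(c("a", "b"), 2),
                     tissue = rep(c("T1", "T2"), each = 2), is_index = TRUE)
  expect_equal(sum(tissue_specific_counts(same)), 0)
  # fully disjoint sets -> unique counts equal set sizes
  disj <- data.frame(variant_id = letters[1:6],
                     tissue = rep(c("T1", "T2"), each = 3), is_index = TRUE)
  expect_equal(tissue_specific_counts(disj), c(T1 = 3L, T2 = 3L))
})
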