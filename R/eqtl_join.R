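# Intersection of classified variants with significant cis-eQTL tables and
# composition tests (tissue, functional category) of the derived-HF eQTL set
# against the background eQTL set.

#' Intersect classified variants with significant eQTL associations
#'
#' Splits the significant eQTL associations into the focal set (rows whose
#' variant is classified derived high-frequency) and the background set (the
#' rest of the significant, non-derived/non-HF eQTLs), joining on rsID.
#'
#' @param classified output of [classify_variants()].
#' @param eqtls eQTL association table with columns `variant_id` (rsid) and
#'   `qval_pass`.
#' @return list with data frames `focal` and `background`.
#' @export
eqtl_intersect <- function(classified, eqtls) {
  stopifnot(all(c("variant_id", "qval_pass") %in% names(eqtls)))
  hf_ids <- classified$rsid[classified$is_derived_hf & !is.na(classified$rsid)]
  sig <- eqtls[eqtls$qval_pass, , drop = FALSE]
  focal <- sig[sig$variant_id %in% hf_ids, , drop = FALSE]
  background <- sig[!(sig$variant_id %in% hf_ids), , drop = FALSE]
  if (nrow(focal) == 0)
    warning("empty intersection: no significant eQTL on a derived-HF variant")
  list(focal = focal, background = background)
}

# core 2 x K homogeneity machinery shared by the tissue and category tests
.composition_test <- function(focal_counts, background_counts, alpha,
                              monte_carlo_B) {
  O <- rbind(focal = focal_counts, background = background_counts)
  O <- O[, colSums(O) > 0, drop = FALSE]
  if (ncol(O) < 2)
    stop_config("composition test needs at least two groups with counts")
  if (any(rowSums(O) == 0))
    stop_config("composition test needs counts in both the focal and ",
                "background sets")
  N <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / N
  mc <- any(E < 5)
  if (mc) {
    warning("expected cell count < 5; using Monte-Carlo chi-square p-value")
    ct <- suppressWarnings(
      chisq.test(O, simulate.p.value = TRUE, B = monte_carlo_B))
    df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  } else {
    ct <- suppressWarnings(chisq.test(O, correct = FALSE))
    df <- unname(ct$parameter)
  }
  # adjusted (Haberman) residuals: (O - E) / sqrt(E (1 - row share)(1 - col share))
  adj <- (O - E) /
    sqrt(E * outer(1 - rowSums(O) / N, 1 - colSums(O) / N))
  crit <- qnorm(1 - alpha / 2)
  flagged <- abs(adj) > crit
  structure(list(observed = O, expected = E,
                 statistic = unname(ct$statistic), df = df,
                 p.value = ct$p.value, monte_carlo = mc,
                 adjusted_residuals = adj, critical_value = crit,
                 flagged = flagged, alpha = alpha),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Chi-square homogeneity test: X2 =", format(x$statistic, digits = 5),
      if (x$monte_carlo) "(Monte-Carlo p)" else paste0("df = ", x$df),
      ", p =", format.pval(x$p.value), "\n")
  drivers <- colnames(x$flagged)[apply(x$flagged, 2, any)]
  if (length(drivers))
    cat("cells driving significance (|adjusted residual| >",
        round(x$critical_value, 2), "):", paste(drivers, collapse = ", "), "\n")
  invisible(x)
}

#' Tissue composition test of derived-HF eQTLs against the background
#'
#' Builds the 2 x T contingency table of focal vs background significant
#' eQTL counts per tissue and tests homogeneity with a chi-square test;
#' per-cell adjusted residuals compared to the two-sided normal critical
#' value identify the tissues driving a rejection (e.g. pituitary and
#' cerebellum in the real-data analysis this reproduces). When any expected
#' cell is below 5 a Monte-Carlo p-value replaces the asymptotic one.
#'
#' @param focal,background eQTL association data frames with a `tissue`
#'   column (from [eqtl_intersect()]).
#' @param alpha two-sided level for flagging residuals (default 0.05).
#' @param monte_carlo_B table resamples for the small-count fallback.
#' @return a `contingency_result` object.
#' @export
tissue_composition_test <- function(focal, background, alpha = 0.05,
                                    monte_carlo_B = 10000) {
  lev <- sort(unique(c(focal$tissue, background$tissue)))
  .composition_test(table(factor(focal$tissue, levels = lev)),
                    table(factor(background$tissue, levels = lev)),
                    alpha, monte_carlo_B)
}

#' Functional-category composition test
#'
#' As [tissue_composition_test()], but over variant consequence categories
#' (NMD transcript, non-coding transcript, 5'UTR, ...). Counts unique
#' variants per category so one variant tested in many tissues is not
#' multiply counted.
#'
#' @inheritParams tissue_composition_test
#' @return a `contingency_result` object.
#' @export
category_composition_test <- function(focal, background, alpha = 0.05,
                                      monte_carlo_B = 10000) {
  cat_of <- function(d) {
    u <- d[!duplicated(d$variant_id), , drop = FALSE]
    u$consequence_category
  }
  fc <- cat_of(focal); bc <- cat_of(background)
  lev <- sort(unique(c(fc, bc)))
  if (length(unique(fc)) < 1 || length(lev) < 2)
    stop_config("degenerate category table: need at least two categories")
  .composition_test(table(factor(fc, levels = lev)),
                    table(factor(bc, levels = lev)),
                    alpha, monte_carlo_B)
}

#' Correlation of per-tissue eQTL discovery with sample size
#'
#' Spearman correlation between the per-tissue clumped eQTL count and the
#' tissue RNA-seq sample size, plus a degree-2 polynomial least-squares fit
#' whose +/- 1 standard-error band identifies outlier tissues (the
#' real-data analogues being cerebellum, adrenal gland and BA9).
#'
#' @param counts named numeric vector of per-tissue counts.
#' @param samples named numeric vector of per-tissue sample sizes (same
#'   names).
#' @return list with `rho`, `p.value` and a data frame `fit` (tissue, count,
#'   n, fitted value, standard error, outlier flag).
#' @export
sample_size_correlation <- function(counts, samples) {
  tissues <- intersect(names(counts), names(samples))
  if (length(tissues) < 4)
    stop_config("need at least four tissues")
  x <- as.numeric(samples[tissues])
  y <- as.numeric(counts[tissues])
  if (sd(y) == 0)
    stop_config("per-tissue counts are constant; correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  fit <- lm(y ~ poly(x, 2))
  pr <- predict(fit, se.fit = TRUE)
  outlier <- abs(y - pr$fit) > pr$se.fit
  list(rho = unname(ct$estimate), p.value = ct$p.value,
       fit = data.frame(tissue = tissues, count = y, n = x,
                        fitted = pr$fit, se = pr$se.fit, outlier = outlier,
                        stringsAsFactors = FALSE))
}

#' Random-sampling test for region-specific clumped eQTL excess
#'
#' Tests whether any tissue holds more tissue-specific (unique to exactly
#' one tissue) clumped eQTLs than expected given per-tissue totals. Tissue
#' labels of the clumped index variants are resampled without replacement
#' (label permutation, preserving per-tissue totals); the chi-square
#' distance between a unique-count vector and the resample mean is the
#' discrepancy statistic, and the resamples themselves provide its null
#' reference, giving an empirical p-value with the +1 correction.
#'
#' @param clumped data frame of clumped index variants with columns
#'   `variant_id` and `tissue`.
#' @param n_resamples number of label permutations (default 100).
#' @param seed optional seed.
#' @return list with `p.value`, `statistic`, `observed` and `expected`
#'   unique-count vectors, and the vector of resampled statistics.
#' @export
region_specific_sampling_test <- function(clumped, n_resamples = 100,
                                          seed = NULL) {
  if (!is_count(n_resamples))
    stop_config("n_resamples must be a positive count")
  stopifnot(all(c("variant_id", "tissue") %in% names(clumped)))
  lev <- sort(unique(clumped$tissue))
  unique_counts <- function(vid, tis) {
    per_var <- tapply(tis, vid, function(t) unique(t))
    singles <- per_var[lengths(per_var) == 1L]
    table(factor(unlist(singles, use.names = FALSE), levels = lev))
  }
  obs <- unique_counts(clumped$variant_id, clumped$tissue)
  if (sum(obs) == 0) {
    warning("no tissue-specific clumped eQTLs; test skipped")
    return(list(p.value = NA_real_, statistic = NA_real_,
                observed = obs, expected = NULL, resampled = NULL))
  }
  res <- with_seed(seed, {
    sapply(seq_len(n_resamples), function(i) {
      unique_counts(clumped$variant_id, sample(clumped$tissue))
    })
  })
  E <- rowMeans(res)
  chi <- function(v) {
    ok <- E > 0
    sum((v[ok] - E[ok])^2 / E[ok])
  }
  stat_obs <- chi(as.numeric(obs))
  stat_res <- apply(res, 2, chi)
  p <- (1 + sum(stat_res >= stat_obs)) / (n_resamples + 1)
  list(p.value = p, statistic = stat_obs, observed = obs, expected = E,
       resampled = stat_res)
}
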