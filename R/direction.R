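# Regulatory directionality: does the focal allele skew toward down- or
# up-regulation? Slopes are re-oriented to the focal allele's dosage, tested
# against a 50/50 split, compared against a major-ancestral-allele control,
# and tissues are clustered by mean effect-size profiles.

#' Orient eQTL slopes to a focal allele
#'
#' eQTL slopes (normalized effect sizes) refer to ALT-allele dosage; this
#' re-signs them so they describe the dosage effect of the focal allele
#' (derived, or ancestral for the control set). Rows whose variant lacks a
#' resolved ancestral allele are dropped.
#'
#' @param eqtls eQTL table with `variant_id` (rsid) and `slope`.
#' @param classified classified catalog (provides allele orientation).
#' @param focal `"derived"` or `"ancestral"`.
#' @return the joined table with an added `slope_oriented` column.
#' @export
orient_slopes <- function(eqtls, classified, focal = c("derived", "ancestral")) {
  focal <- match.arg(focal)
  cc <- classified[classified$ancestral_resolved & !is.na(classified$rsid), ]
  m <- match(eqtls$variant_id, cc$rsid)
  keep <- !is.na(m)
  out <- eqtls[keep, , drop = FALSE]
  m <- m[keep]
  focal_allele <- if (focal == "derived") cc$derived[m] else cc$ancestral[m]
  flip <- focal_allele == cc$ref[m]
  out$slope_oriented <- ifelse(flip, -out$slope, out$slope)
  out
}

#' Directionality test against the expected 50/50 split
#'
#' Pools up- (positive oriented slope) and down-regulating (negative) eQTL
#' counts and tests the 50% null with a chi-square goodness-of-fit test;
#' exact zero slopes are counted separately and excluded from the binary
#' test. With two or more tissues, per-tissue adjusted residuals on the
#' up/down x tissue table identify tissues driving any skew (the real-data
#' analogue being the substantia nigra in the unclumped set).
#'
#' @param eqtls data frame with `slope_oriented` (see [orient_slopes()]) and
#'   optionally `tissue`.
#' @param alpha two-sided level for flagging per-tissue residuals.
#' @return object of class `direction_result`: counts, chi-square
#'   `statistic`, `p.value`, `n_zero`, and (when available) per-tissue
#'   adjusted residuals with flags.
#' @export
#' @examples
#' d <- data.frame(slope_oriented = c(rep(1, 75), rep(-1, 25)))
#' direction_test(d)$statistic   # 25
direction_test <- function(eqtls, alpha = 0.05) {
  s <- eqtls$slope_oriented
  n_zero <- sum(s == 0)
  s_nz <- s[s != 0]
  if (!length(s_nz))
    stop_config("all slopes are zero; the directionality test is undefined")
  up <- sum(s_nz > 0); down <- sum(s_nz < 0)
  ct <- suppressWarnings(chisq.test(c(up = up, down = down), p = c(0.5, 0.5)))

  per_tissue <- NULL
  if ("tissue" %in% names(eqtls)) {
    d <- eqtls[eqtls$slope_oriented != 0, , drop = FALSE]
    tab <- table(ifelse(d$slope_oriented > 0, "up", "down"), d$tissue)
    if (nrow(tab) == 2 && ncol(tab) >= 2) {
      N <- sum(tab)
      E <- outer(rowSums(tab), colSums(tab)) / N
      adj <- (tab - E) / sqrt(E * outer(1 - rowSums(tab) / N,
                                        1 - colSums(tab) / N))
      per_tissue <- list(adjusted_residuals = adj,
                         flagged = abs(adj) > qnorm(1 - alpha / 2))
    }
  }
  structure(list(up = up, down = down, n_zero = n_zero,
                 statistic = unname(ct$statistic),
                 p.value = ct$p.value, per_tissue = per_tissue,
                 alpha = alpha),
            class = "direction_result")
}

#' @export
print.direction_result <- function(x, ...) {
  cat("Directionality test: up =", x$up, ", down =", x$down,
      "(", x$n_zero, "zero slopes excluded ), X2 =",
      format(x$statistic, digits = 5), ", p =", format.pval(x$p.value), "\n")
  invisible(x)
}

#' Build the major-ancestral-allele control set
#'
#' Mirrors the derived high-frequency selection on the ancestral allele:
#' keeps significant eQTL rows whose variant has a resolved ancestral allele
#' that is the major allele at or above the frequency threshold, with slopes
#' oriented to ancestral dosage. Used to rule out frequency-cutoff artifacts
#' in the directionality result.
#'
#' @param classified classified catalog.
#' @param eqtls eQTL table (significant rows are used).
#' @param threshold ancestral-allele frequency threshold (default 0.90).
#' @return oriented eQTL table for the control variants.
#' @export
build_control_set <- function(classified, eqtls, threshold = 0.90) {
  anc_is_alt <- classified$ancestral_resolved &
    classified$ancestral == classified$alt
  af_anc <- ifelse(anc_is_alt, classified$af_global,
                   1 - classified$af_global)
  ctrl <- classified$ancestral_resolved & af_anc > 0.5 & af_anc >= threshold
  ids <- classified$rsid[ctrl & !is.na(classified$rsid)]
  sig <- eqtls[eqtls$qval_pass & eqtls$variant_id %in% ids, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("empty major-ancestral control set")
    sig$slope_oriented <- numeric(0)
    return(sig)
  }
  orient_slopes(sig, classified, focal = "ancestral")
}

#' Hierarchical clustering of tissues by mean effect size
#'
#' Builds the per-tissue mean normalized-effect-size profile over genes,
#' restricted to genes observed in every retained tissue (tissues without
#' any association are excluded with a warning), computes Euclidean
#' distances and agglomerates with complete linkage. The dendrogram is also
#' returned in Newick form.
#'
#' @param eqtls data frame with `tissue`, `gene_id` and a slope column.
#' @param value name of the slope column (default `"slope"`).
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list with `hclust`, `newick`, the profile `matrix` and the `dist`
#'   object.
#' @export
tissue_clustering <- function(eqtls, value = "slope", linkage = "complete") {
  stopifnot(all(c("tissue", "gene_id", value) %in% names(eqtls)))
  tissues <- sort(unique(eqtls$tissue))
  empty <- setdiff(tissues, unique(eqtls$tissue[!is.na(eqtls[[value]])]))
  if (length(empty)) {
    warning("tissues without associations excluded: ",
            paste(empty, collapse = ", "))
    tissues <- setdiff(tissues, empty)
  }
  if (length(tissues) < 2)
    stop_config("need at least two tissues with associations")
  d <- eqtls[eqtls$tissue %in% tissues, c("tissue", "gene_id", value)]
  mean_mat <- tapply(d[[value]], list(d$gene_id, d$tissue), mean)
  complete <- rowSums(is.na(mean_mat)) == 0
  if (!any(complete))
    stop_config("no gene is observed in every tissue")
  prof <- t(mean_mat[complete, , drop = FALSE])
  dd <- dist(prof)
  hc <- hclust(dd, method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = nwk, profile = prof, dist = dd)
}
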