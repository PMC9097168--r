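# Pairwise r-squared from a haplotype panel and greedy p-value-ordered
# clumping of eQTL variants (Plink-style --clump behaviour at a fixed
# r2 threshold within a physical window).

#' Pairwise r-squared between two panel variants
#'
#' Computed directly from haplotype frequencies:
#' `r2 = (pAB - pA pB)^2 / (pA (1 - pA) pB (1 - pB))`, the standard LD
#' definition; equal to the squared Pearson correlation of the two binary
#' haplotype columns.
#'
#' @param panel a `haplotype_panel` (or any list with a binary matrix `H`).
#' @param v1,v2 column indices or variant ids.
#' @return r-squared in `[0, 1]`.
#' @export
#' @examples
#' p <- gen_haplotypes(sim_config(n_variants = 20, n_haplotypes = 50))
#' ld_r2(p, 1, 2)
ld_r2 <- function(panel, v1, v2) {
  H <- panel$H
  idx <- function(v) if (is.character(v)) match(v, colnames(H)) else v
  x <- H[, idx(v1)]; y <- H[, idx(v2)]
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop_config("r-squared undefined for a monomorphic variant")
  pAB <- mean(x == 1L & y == 1L)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Greedy LD clumping by association p-value
#'
#' Sorts variants by ascending nominal p-value (ties broken by chromosome
#' and position for determinism), repeatedly takes the best unassigned
#' variant as a clump index, and assigns to its clump every unassigned
#' variant on the same chromosome within `window_kb` whose r-squared with
#' the index reaches `r2_threshold`. The output partitions the input; index
#' variants form the LD-pruned ("clumped") set. Variants absent from the
#' panel, or monomorphic in it, cannot be clumped and are retained as
#' singleton clumps with a warning, mirroring Plink's handling of unknown
#' SNPs.
#'
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`,
#'   `pval`.
#' @param panel a `haplotype_panel`; variant ids are matched against both
#'   `vid` and `rsid`.
#' @param r2_threshold clumping r-squared threshold in (0, 1]; default 0.1.
#' @param window_kb physical window half-width in kb (default 250, the Plink
#'   default).
#' @return `variants` with added columns `clump_index` (variant_id of the
#'   index), `r2_to_index` and `is_index`.
#' @export
ld_clump <- function(variants, panel, r2_threshold = 0.1, window_kb = 250) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1)
    stop_config("r2_threshold must lie in (0, 1]")
  stopifnot(all(c("variant_id", "chrom", "pos", "pval") %in% names(variants)))
  v <- variants
  n <- nrow(v)
  col <- match(v$variant_id, panel$vid)
  miss <- is.na(col)
  if (!is.null(panel$rsid))
    col[miss] <- match(v$variant_id[miss], panel$rsid)
  if (anyNA(col))
    warning(sum(is.na(col)), " variant(s) absent from the LD panel kept as ",
            "singleton clumps")

  ord <- order(v$pval, v$chrom, v$pos)
  assigned <- rep(FALSE, n)
  clump_index <- character(n)
  r2_to_index <- rep(NA_real_, n)
  is_index <- rep(FALSE, n)
  H <- panel$H
  win <- window_kb * 1000

  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    is_index[i] <- TRUE
    clump_index[i] <- v$variant_id[i]
    r2_to_index[i] <- 1
    if (is.na(col[i])) next
    x <- H[, col[i]]
    if (sd(x) == 0) next
    cand <- which(!assigned & !is.na(col) & v$chrom == v$chrom[i] &
                    abs(v$pos - v$pos[i]) <= win)
    if (!length(cand)) next
    r2 <- suppressWarnings(as.vector(cor(x, H[, col[cand], drop = FALSE]))^2)
    r2[!is.finite(r2)] <- 0
    take <- cand[r2 >= r2_threshold]
    if (length(take)) {
      assigned[take] <- TRUE
      clump_index[take] <- v$variant_id[i]
      r2_to_index[take] <- r2[r2 >= r2_threshold]
    }
  }
  v$clump_index <- clump_index
  v$r2_to_index <- r2_to_index
  v$is_index <- is_index
  v
}

#' Clump eQTL associations within each tissue
#'
#' Reduces each tissue's significant associations to one row per variant
#' (minimum nominal p across genes) and clumps per tissue. Pooled clumping
#' across tissues is available via `pooled = TRUE`.
#'
#' @param eqtls eQTL table with `variant_id`, `tissue`, `pval_nominal`.
#' @param catalog classified catalog supplying `chrom`/`pos` per rsid.
#' @param panel haplotype panel.
#' @param pooled clump the pooled variant set once instead of per tissue.
#' @inheritParams ld_clump
#' @return data frame of clumping assignments with a `tissue` column (label
#'   `"pooled"` in pooled mode).
#' @export
clump_by_tissue <- function(eqtls, catalog, panel, r2_threshold = 0.1,
                            window_kb = 250, pooled = FALSE) {
  pos <- catalog[!is.na(catalog$rsid), c("rsid", "chrom", "pos")]
  prep <- function(d) {
    agg <- tapply(d$pval_nominal, d$variant_id, min)
    out <- data.frame(variant_id = names(agg), pval = as.numeric(agg),
                      stringsAsFactors = FALSE)
    m <- match(out$variant_id, pos$rsid)
    out$chrom <- pos$chrom[m]
    out$pos <- pos$pos[m]
    out[!is.na(out$chrom), , drop = FALSE]
  }
  if (pooled) {
    res <- ld_clump(prep(eqtls), panel, r2_threshold, window_kb)
    res$tissue <- "pooled"
    return(res)
  }
  parts <- lapply(split(eqtls, eqtls$tissue), function(d) {
    res <- ld_clump(prep(d), panel, r2_threshold, window_kb)
    res$tissue <- d$tissue[1]
    res
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Count tissue-specific clumped index variants
#'
#' An index variant is tissue-specific when it appears in exactly one
#' tissue's clumped set.
#'
#' @param clumped output of [clump_by_tissue()] (per-tissue mode).
#' @return named integer vector of tissue-specific index counts, one entry
#'   per tissue present in the input (zeros kept).
#' @export
tissue_specific_counts <- function(clumped) {
  idx <- clumped[clumped$is_index, c("variant_id", "tissue")]
  lev <- sort(unique(clumped$tissue))
  per_var <- tapply(idx$tissue, idx$variant_id, unique)
  singles <- per_var[lengths(per_var) == 1L]
  tab <- table(factor(unlist(singles, use.names = FALSE), levels = lev))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
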