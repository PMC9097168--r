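# Two-sample Mendelian randomization (Wald ratio) against GWAS summary
# statistics, with instrument selection, allele harmonization, Bonferroni
# correction and approximate-Bayes-factor colocalization.

#' Select top eQTL instruments per gene and tissue
#'
#' Keeps, for each gene x tissue, the variant with the smallest nominal
#' eQTL p-value, retained only if that p-value reaches `p_threshold` and
#' the variant is present in the derived-allele catalog (membership, not
#' the high-frequency subset: high-frequency-only instruments are avoided
#' because pleiotropy and LD can confound the estimates). Ties in p are
#' broken by genomic position for determinism.
#'
#' @param eqtls eQTL table with `variant_id`, `gene_id`, `tissue`, `slope`,
#'   `slope_se`, `pval_nominal`.
#' @param classified classified catalog; rsID-mapped variants with a
#'   resolved ancestral allele define the derived-allele catalog.
#' @param p_threshold top-hit p-value threshold (default 5e-4).
#' @return instrument table, one row per retained gene x tissue, with
#'   `effect_allele`/`other_allele` columns (ALT/REF) for harmonization.
#' @export
select_instruments <- function(eqtls, classified, p_threshold = 5e-4) {
  cc <- classified[classified$ancestral_resolved & !is.na(classified$rsid), ]
  d <- eqtls[eqtls$variant_id %in% cc$rsid, , drop = FALSE]
  if (!nrow(d)) return(d)
  m <- match(d$variant_id, cc$rsid)
  d$pos <- cc$pos[m]
  d$effect_allele <- cc$alt[m]
  d$other_allele <- cc$ref[m]
  d$eaf <- cc$af_global[m]
  key <- paste(d$gene_id, d$tissue, sep = "\r")
  ord <- order(key, d$pval_nominal, d$pos)
  d <- d[ord, , drop = FALSE]
  top <- d[!duplicated(paste(d$gene_id, d$tissue, sep = "\r")), , drop = FALSE]
  out <- top[top$pval_nominal <= p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure instruments with GWAS summary statistics
#'
#' Aligns outcome effects to the exposure effect allele: matching alleles
#' pass through, swapped alleles flip the GWAS beta sign and EAF,
#' incompatible allele sets are dropped (logged), and palindromic variants
#' (A/T, C/G) with effect-allele frequency in `[0.42, 0.58]` are dropped as
#' strand-ambiguous.
#'
#' @param instruments output of [select_instruments()].
#' @param gwas GWAS summary table with `SNP`, `beta`, `se`, `effect_allele`,
#'   `other_allele`, `eaf`.
#' @return data frame of aligned effect pairs: `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` on the exposure effect
#'   allele, plus identifying columns.
#' @export
harmonize_effects <- function(instruments, gwas) {
  m <- match(instruments$variant_id, gwas$SNP)
  keep <- !is.na(m)
  ins <- instruments[keep, , drop = FALSE]
  gw <- gwas[m[keep], , drop = FALSE]

  same <- gw$effect_allele == ins$effect_allele &
    gw$other_allele == ins$other_allele
  swapped <- gw$effect_allele == ins$other_allele &
    gw$other_allele == ins$effect_allele
  incompatible <- !(same | swapped)
  if (any(incompatible))
    message(sum(incompatible), " variant(s) dropped: incompatible alleles")

  beta_out <- ifelse(swapped, -gw$beta, gw$beta)
  eaf_out <- ifelse(swapped, 1 - gw$eaf, gw$eaf)

  pal <- .palindromic(ins$effect_allele, ins$other_allele) &
    eaf_out >= 0.42 & eaf_out <= 0.58
  if (any(pal & !incompatible))
    message(sum(pal & !incompatible),
            " palindromic variant(s) with ambiguous frequency dropped")

  ok <- !incompatible & !pal
  data.frame(variant_id = ins$variant_id[ok],
             gene_id = ins$gene_id[ok],
             tissue = ins$tissue[ok],
             trait = if ("trait" %in% names(gw)) gw$trait[ok] else NA_character_,
             effect_allele = ins$effect_allele[ok],
             beta_exposure = ins$slope[ok],
             se_exposure = ins$slope_se[ok],
             beta_outcome = beta_out[ok],
             se_outcome = gw$se[ok],
             eaf_outcome = eaf_out[ok],
             stringsAsFactors = FALSE)
}

#' Wald-ratio estimate for a single instrument
#'
#' `beta_IV = beta_outcome / beta_exposure`, with the first-order delta
#' standard error `se_IV = |se_outcome / beta_exposure|` and a two-sided
#' normal p-value. A zero exposure effect leaves the ratio undefined and
#' the instrument is rejected.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome aligned effects
#'   (vectors).
#' @return data frame with `beta_iv`, `se_iv`, `p`.
#' @export
#' @examples
#' wald_ratio(0.5, 0.1, 0.2, 0.05)  # beta 0.4, se 0.1
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (any(beta_exposure == 0))
    stop_config("Wald ratio undefined for a zero exposure effect")
  beta_iv <- beta_outcome / beta_exposure
  se_iv <- abs(se_outcome / beta_exposure)
  z <- beta_iv / se_iv
  data.frame(beta_iv = beta_iv, se_iv = se_iv, p = 2 * pnorm(-abs(z)))
}

#' Two-sample MR across genes, tissues and traits
#'
#' Harmonizes the selected instruments against each GWAS trait, computes
#' per-instrument Wald ratios and applies a Bonferroni correction whose
#' family is all gene x trait tests run in the invocation.
#'
#' @param instruments output of [select_instruments()].
#' @param gwas_list named list of GWAS summary tables (one per trait).
#' @return data frame of MR results with `p_bonferroni`.
#' @export
mr_wald <- function(instruments, gwas_list) {
  if (!length(gwas_list)) stop_config("no GWAS traits supplied")
  parts <- lapply(names(gwas_list), function(tr) {
    h <- harmonize_effects(instruments, gwas_list[[tr]])
    if (!nrow(h)) return(NULL)
    h <- h[h$beta_exposure != 0, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    w <- wald_ratio(h$beta_exposure, h$se_exposure,
                    h$beta_outcome, h$se_outcome)
    cbind(h[c("gene_id", "tissue", "variant_id")],
          trait = tr, w, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || !nrow(out)) return(out)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

# Wakefield log approximate Bayes factor (alternative vs null)
.labf <- function(beta, se, sd_prior) {
  z <- beta / se
  V <- se^2
  r <- sd_prior^2 / (sd_prior^2 + V)
  0.5 * (log(1 - r) + r * z^2)
}

#' Approximate-Bayes-factor colocalization of two association signals
#'
#' Computes per-variant Wakefield approximate Bayes factors for each trait
#' (prior effect standard deviation 0.15 per trait, the quantitative-trait
#' convention) and combines them with the single-causal-variant hypothesis
#' priors into posterior probabilities PP0..PP4: no association, trait-1
#' only, trait-2 only, two distinct causal variants, one shared causal
#' variant. Posteriors are normalized to sum to one.
#'
#' @param trait1,trait2 data frames with `snp`, `beta`, `se` over the same
#'   region; rows are matched on `snp` and variants missing a standard
#'   error are dropped.
#' @param p1,p2 prior probabilities that a variant is causal for trait 1 /
#'   trait 2 (default 1e-4).
#' @param p12 prior probability that a variant is causal for both traits
#'   (default 1e-5).
#' @param sd_prior1,sd_prior2 prior effect standard deviations.
#' @return object of class `coloc_result`: `summary` (nsnps and PP0..PP4),
#'   `priors`, and per-variant log-ABFs.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      sd_prior1 = 0.15, sd_prior2 = 0.15) {
  stopifnot(all(c("snp", "beta", "se") %in% names(trait1)),
            all(c("snp", "beta", "se") %in% names(trait2)))
  t1 <- trait1[!is.na(trait1$se) & trait1$se > 0, ]
  t2 <- trait2[!is.na(trait2$se) & trait2$se > 0, ]
  shared <- intersect(t1$snp, t2$snp)
  if (!length(shared))
    stop_config("no shared variant between the two traits")
  if (length(shared) == 1)
    warning("single-variant region: H3 is unidentifiable")
  t1 <- t1[match(shared, t1$snp), ]
  t2 <- t2[match(shared, t2$snp), ]

  l1 <- .labf(t1$beta, t1$se, sd_prior1)
  l2 <- .labf(t2$beta, t2$se, sd_prior2)
  lsum <- l1 + l2

  lH0 <- 0
  lH1 <- log(p1) + logsum(l1)
  lH2 <- log(p2) + logsum(l2)
  lH3 <- log(p1) + log(p2) +
    logdiff(logsum(l1) + logsum(l2), logsum(lsum))
  lH4 <- log(p12) + logsum(lsum)

  all_l <- c(PP0 = lH0, PP1 = lH1, PP2 = lH2, PP3 = lH3, PP4 = lH4)
  pp <- exp(all_l - logsum(all_l))

  structure(list(summary = c(nsnps = length(shared), pp),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 results = data.frame(snp = shared, lABF1 = l1, lABF2 = l2,
                                      stringsAsFactors = FALSE)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  s <- x$summary
  cat("ABF colocalization over", s[["nsnps"]], "variants:\n")
  print(round(s[-1], 4))
  invisible(x)
}
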