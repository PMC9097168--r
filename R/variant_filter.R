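# Classification of variants as Homo sapiens-derived, nearly fixed alleles:
# archaic coverage filters, ancestral-allele resolution, the archaic
# genotype condition (including the gene-flow clause) and the frequency
# rules (global and per-metapopulation).

#' Archaic coverage reliability
#'
#' A genotype call for an archaic individual is considered reliable when its
#' site coverage lies inside the inclusive bounds used for the catalog:
#' 5- to 105-fold for the Altai Neanderthal, 5- to 75-fold for the Vindija
#' Neanderthal and the Denisovan. Coverage failing the bounds masks that
#' individual's genotype rather than discarding the site: the gene-flow
#' clause of the archaic condition explicitly tolerates informative subsets.
#'
#' @param dp_altai,dp_vindija,dp_denisova non-negative integer coverages
#'   (vectors recycled to common length); `NA` counts as unreliable.
#' @return data frame of logicals `altai`, `vindija`, `denisova`, plus `any`
#'   (at least one archaic reliable).
#' @export
#' @examples
#' coverage_pass(4, 50, 76)   # only Vindija reliable
coverage_pass <- function(dp_altai, dp_vindija, dp_denisova) {
  n <- max(length(dp_altai), length(dp_vindija), length(dp_denisova))
  dp_altai <- rep_len(dp_altai, n)
  dp_vindija <- rep_len(dp_vindija, n)
  dp_denisova <- rep_len(dp_denisova, n)
  for (dp in list(dp_altai, dp_vindija, dp_denisova))
    if (any(dp < 0, na.rm = TRUE)) stop_config("coverage must be non-negative")
  ok <- function(dp, hi) !is.na(dp) & dp >= 5L & dp <= hi
  a <- ok(dp_altai, 105L); v <- ok(dp_vindija, 75L); d <- ok(dp_denisova, 75L)
  data.frame(altai = a, vindija = v, denisova = d, any = a | v | d)
}

#' Resolve the ancestral allele of each variant
#'
#' The great-ape multiple-alignment call takes precedence; the macaque
#' (rheMac3) reference allele is used only where the ape call is missing.
#' Variants where both are missing, or where the resolved allele matches
#' neither REF nor ALT, are flagged unresolved and excluded from
#' classification.
#'
#' @param catalog data frame with columns `ref`, `alt`, `anc_ape`,
#'   `anc_macaque`.
#' @return `catalog` with added columns `ancestral`, `ancestral_source`
#'   (`"from_apes"`, `"from_macaque"` or `NA`), `derived` and
#'   `ancestral_resolved`.
#' @export
assign_ancestral <- function(catalog) {
  stopifnot(all(c("ref", "alt", "anc_ape", "anc_macaque") %in% names(catalog)))
  anc <- catalog$anc_ape
  src <- ifelse(!is.na(anc), "from_apes", NA_character_)
  use_mac <- is.na(anc) & !is.na(catalog$anc_macaque)
  anc[use_mac] <- catalog$anc_macaque[use_mac]
  src[use_mac] <- "from_macaque"
  valid <- !is.na(anc) & (anc == catalog$ref | anc == catalog$alt)
  anc[!valid] <- NA_character_
  src[!valid] <- NA_character_
  catalog$ancestral <- anc
  catalog$ancestral_source <- src
  catalog$derived <- ifelse(valid,
                            ifelse(anc == catalog$ref, catalog$alt, catalog$ref),
                            NA_character_)
  catalog$ancestral_resolved <- valid
  catalog
}

# derived-allele count of a diploid genotype string "X/Y"; NA for missing or
# alleles outside {ancestral, derived}
.derived_count <- function(gt, ancestral, derived) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != "./." & !is.na(ancestral)
  if (!any(ok)) return(out)
  parts <- strsplit(gt[ok], "/", fixed = TRUE)
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  anc <- ancestral[ok]; der <- derived[ok]
  valid <- (a1 == anc | a1 == der) & (a2 == anc | a2 == der)
  cnt <- (a1 == der) + (a2 == der)
  cnt[!valid] <- NA_integer_
  out[ok] <- cnt
  out
}

#' Archaic genotype condition for derived-allele classification
#'
#' TRUE when either (1) every reliable archaic genotype carries only the
#' ancestral allele, or (2) the Denisovan is reliable and homozygous
#' ancestral while at least one reliable Neanderthal carries at least one
#' derived allele -- the clause accounting for gene flow from *Homo sapiens*
#' into Neanderthals. With no reliable archaic genotype the condition is
#' undecidable (`NA`) and the variant is excluded.
#'
#' @param gt_altai,gt_vindija,gt_denisova diploid genotype strings
#'   (`"A/G"`, `"./."` for missing).
#' @param rel_altai,rel_vindija,rel_denisova logical reliability flags (from
#'   [coverage_pass()]); a missing genotype is always treated unreliable.
#' @param ancestral,derived resolved alleles.
#' @param het_ancestral_ok if `TRUE`, a heterozygous archaic counts as
#'   "having the ancestral allele" in clause 1; the strict default requires
#'   homozygous ancestral. The Denisovan in clause 2 must be homozygous
#'   ancestral under either reading.
#' @return logical vector (`NA` = undecidable).
#' @export
archaic_condition <- function(gt_altai, gt_vindija, gt_denisova,
                              rel_altai, rel_vindija, rel_denisova,
                              ancestral, derived,
                              het_ancestral_ok = FALSE) {
  ca <- .derived_count(gt_altai, ancestral, derived)
  cv <- .derived_count(gt_vindija, ancestral, derived)
  cd <- .derived_count(gt_denisova, ancestral, derived)
  ra <- rel_altai & !is.na(ca)
  rv <- rel_vindija & !is.na(cv)
  rd <- rel_denisova & !is.na(cd)

  anc_only_max <- if (het_ancestral_ok) 1L else 0L
  anc_ok <- function(cnt, rel) !rel | (cnt <= anc_only_max)
  clause1 <- anc_ok(ifelse(is.na(ca), 0L, ca), ra) &
             anc_ok(ifelse(is.na(cv), 0L, cv), rv) &
             anc_ok(ifelse(is.na(cd), 0L, cd), rd)

  nea_derived <- (ra & !is.na(ca) & ca >= 1L) | (rv & !is.na(cv) & cv >= 1L)
  clause2 <- rd & !is.na(cd) & cd == 0L & nea_derived

  out <- clause1 | clause2
  out[!(ra | rv | rd)] <- NA
  out
}

#' Classify catalog variants as derived, nearly fixed alleles
#'
#' Applies the full rule set: the ancestral allele must be resolvable, the
#' derived allele must be the major allele and reach the frequency threshold
#' globally (and, in the stringent mode, in each of the five 1000 Genomes
#' metapopulations: AFR, AMR, EAS, EUR, SAS), at least one archaic genotype
#' must be reliable, and the archaic condition must hold. Frequencies are
#' compared with `>=` at the threshold; a 0.50/0.50 tie fails the
#' major-allele rule.
#'
#' @param catalog variant catalog data frame (see [gen_variant_catalog()] for
#'   the column dialect); `af_global` and `af_AFR`..`af_SAS` are ALT-allele
#'   frequencies.
#' @param threshold derived-allele frequency threshold in (0.5, 1];
#'   default 0.90.
#' @param stringent require the threshold in every metapopulation (default)
#'   or globally only.
#' @param het_ancestral_ok passed to [archaic_condition()].
#' @return the catalog with ancestral columns plus logical flags
#'   `passes_coverage`, `derived_major`, `hf_global`, `hf_all_metapops`,
#'   `archaic_ok`, `has_rsid` and the conjunction `is_derived_hf`.
#' @export
classify_variants <- function(catalog, threshold = 0.90, stringent = TRUE,
                              het_ancestral_ok = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1)
    stop_config("threshold must lie in (0.5, 1]")
  catalog <- assign_ancestral(catalog)

  rel <- coverage_pass(catalog$dp_altai, catalog$dp_vindija,
                       catalog$dp_denisova)
  catalog$reliable_altai <- rel$altai
  catalog$reliable_vindija <- rel$vindija
  catalog$reliable_denisova <- rel$denisova
  catalog$passes_coverage <- rel$any

  derived_is_alt <- !is.na(catalog$derived) & catalog$derived == catalog$alt
  af_derived <- ifelse(derived_is_alt, catalog$af_global,
                       1 - catalog$af_global)
  pop_cols <- paste0("af_", c("AFR", "AMR", "EAS", "EUR", "SAS"))
  afp <- as.matrix(catalog[, pop_cols])
  afp_derived <- ifelse(matrix(derived_is_alt, nrow(afp), 5L), afp, 1 - afp)

  catalog$af_derived <- ifelse(catalog$ancestral_resolved, af_derived, NA_real_)
  catalog$derived_major <- catalog$ancestral_resolved & af_derived > 0.5
  catalog$hf_global <- catalog$ancestral_resolved & af_derived >= threshold
  catalog$hf_all_metapops <- catalog$ancestral_resolved &
    apply(afp_derived >= threshold, 1L, all)

  arc <- archaic_condition(catalog$gt_altai, catalog$gt_vindija,
                           catalog$gt_denisova,
                           rel$altai, rel$vindija, rel$denisova,
                           catalog$ancestral, catalog$derived,
                           het_ancestral_ok = het_ancestral_ok)
  catalog$archaic_ok <- !is.na(arc) & arc
  catalog$has_rsid <- !is.na(catalog$rsid)

  catalog$is_derived_hf <- catalog$ancestral_resolved &
    catalog$passes_coverage &
    catalog$derived_major &
    catalog$hf_global &
    (if (stringent) catalog$hf_all_metapops else TRUE) &
    catalog$archaic_ok
  attr(catalog, "threshold") <- threshold
  attr(catalog, "stringent") <- stringent
  catalog
}

#' Drop variants without an rsID
#'
#' Variants lacking an rsID cannot be mapped to the eQTL tables and are
#' pruned before the eQTL join; the number dropped is reported.
#'
#' @param variants data frame with an `rsid` column.
#' @return the subset with non-missing rsIDs.
#' @export
drop_unmapped <- function(variants) {
  stopifnot("rsid" %in% names(variants))
  keep <- !is.na(variants$rsid)
  dropped <- sum(!keep)
  if (dropped == nrow(variants) && dropped > 0)
    warning("no variant has an rsID; returning an empty set")
  message(dropped, " variant(s) without rsID dropped")
  variants[keep, , drop = FALSE]
}
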