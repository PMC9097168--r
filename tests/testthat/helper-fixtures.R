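# Shared small fixtures, generated in code (no stored data files).

# memoized medium fixture used by several files
.fix_env <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fix_env$sim)) {
    cfg <- sim_config(n_variants = 800, n_haplotypes = 80, seed = 42,
                      sweep_window_count = 20)
    panel <- gen_haplotypes(cfg)
    vc <- gen_variant_catalog(cfg, panel)
    eqtls <- gen_eqtl_tables(cfg, vc$catalog, vc$truth, panel)
    .fix_env$sim <- list(cfg = cfg, panel = panel, catalog = vc$catalog,
                         truth = vc$truth, eqtls = eqtls)
  }
  .fix_env$sim
}

# a hand-built catalog row; defaults describe a clean derived-HF variant
make_record <- function(af_derived = 0.95, af_pops = rep(0.95, 5),
                        derived_is_alt = TRUE,
                        gt_altai = "A/A", gt_vindija = "A/A",
                        gt_denisova = "A/A",
                        dp_altai = 50, dp_vindija = 40, dp_denisova = 40,
                        anc_ape = "A", anc_macaque = NA_character_,
                        rsid = "rs1") {
  # ancestral allele A, derived allele G
  ref <- if (derived_is_alt) "A" else "G"
  alt <- if (derived_is_alt) "G" else "A"
  af_alt <- if (derived_is_alt) af_derived else 1 - af_derived
  pops <- if (derived_is_alt) af_pops else 1 - af_pops
  data.frame(vid = "v1", chrom = "chr1", pos = 100L, rsid = rsid,
             ref = ref, alt = alt, anc_ape = anc_ape,
             anc_macaque = anc_macaque,
             af_global = af_alt,
             af_AFR = pops[1], af_AMR = pops[2], af_EAS = pops[3],
             af_EUR = pops[4], af_SAS = pops[5],
             gt_altai = gt_altai, gt_vindija = gt_vindija,
             gt_denisova = gt_denisova,
             dp_altai = dp_altai, dp_vindija = dp_vindija,
             dp_denisova = dp_denisova,
             stringsAsFactors = FALSE)
}

# independent literal reading of the archaic clauses, used as the oracle:
# counts are derived-allele counts (0/1/2), rel are reliability flags
oracle_archaic <- function(ca, cv, cd, ra, rv, rd) {
  if (!any(c(ra, rv, rd))) return(NA)
  clause1 <- (!ra || ca == 0) && (!rv || cv == 0) && (!rd || cd == 0)
  clause2 <- rd && cd == 0 && ((ra && ca >= 1) || (rv && cv >= 1))
  clause1 || clause2
}

# independent brute-force clumping oracle: precomputed all-pairs r2 matrix,
# same greedy p-value order
oracle_clump <- function(variants, R2, window_bp) {
  n <- nrow(variants)
  ord <- order(variants$pval, variants$chrom, variants$pos)
  assigned <- rep(FALSE, n)
  index_of <- character(n)
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    index_of[i] <- variants$variant_id[i]
    cand <- which(!assigned & variants$chrom == variants$chrom[i] &
                    abs(variants$pos - variants$pos[i]) <= window_bp)
    hit <- cand[!is.na(R2[i, cand]) & R2[i, cand] >= 0.1]
    assigned[hit] <- TRUE
    index_of[hit] <- variants$variant_id[i]
  }
  index_of
}
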