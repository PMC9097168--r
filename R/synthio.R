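# Synthetic-data generator: emulates every pipeline input (variant catalog
# with archaic genotypes, LD-structured haplotypes, tissue eQTL tables,
# selective-sweep windows, GWAS summaries) with known ground truth.

#' Brain tissues and sample sizes used in simulation
#'
#' The 15 central-nervous-system-related GTEx tissues the analysis targets
#' (adrenal gland included for its HPA-axis role), with plausible v8-scale
#' RNA-seq sample sizes. Sample sizes drive simulated eQTL discovery power,
#' so the discovery-count/sample-size correlation is reproducible in
#' simulation.
#'
#' @return named integer vector of sample sizes, one per tissue.
#' @export
#' @examples
#' gtex_brain_samples()
gtex_brain_samples <- function() {
  c(Adrenal_Gland        = 233L,
    Amygdala             = 129L,
    BA24                 = 147L,
    BA9                  = 175L,
    Caudate              = 194L,
    Cerebellar_Hemisphere = 175L,
    Cerebellum           = 209L,
    Cortex               = 205L,
    Hippocampus          = 165L,
    Hypothalamus         = 170L,
    Nucleus_Accumbens    = 202L,
    Pituitary            = 237L,
    Putamen              = 170L,
    Spinal_Cord          = 126L,
    Substantia_Nigra     = 114L)
}

# duplicate tissue pairs (resampled tissues): first element is the template
.dup_tissue_pairs <- list(c("Cerebellum", "Cerebellar_Hemisphere"),
                          c("Cortex", "BA9"))

.consequence_levels <- c("NMD_transcript", "noncoding_transcript", "UTR5",
                         "UTR3", "missense", "synonymous", "intron",
                         "intergenic")

.base_category_probs <- c(NMD_transcript = 0.03, noncoding_transcript = 0.07,
                          UTR5 = 0.04, UTR3 = 0.08, missense = 0.05,
                          synonymous = 0.06, intron = 0.42, intergenic = 0.25)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Identical
#' configurations (including `seed`) give byte-identical outputs.
#'
#' @param n_variants number of biallelic sites to simulate.
#' @param n_haplotypes number of haplotypes in the LD panel.
#' @param n_tissues number of tissues (<= 15; the first `n_tissues` of
#'   [gtex_brain_samples()]).
#' @param hf_fraction fraction of variants simulated as derived high-frequency
#'   (passing every classification rule by construction).
#' @param sweep_window_count number of sweep windows for the first source
#'   (the second source gets 30% more, with wider windows).
#' @param sweep_enrichment_factor multiplier >= 1; rate at which derived-HF
#'   positions fall inside sweep windows relative to background. 1 means
#'   windows are placed independently of the variants.
#' @param coloc_scenario GWAS/eQTL causal-sharing scenario, one of
#'   `"H0"`..`"H4"` (`H4` = shared causal variant, `H3` = distinct causal
#'   variants in the same region, `H0`-`H2` = one or both traits null).
#' @param seed master seed; every generator call derives its own sub-seed.
#' @param chrom_lengths named vector of chromosome lengths (bp) for the
#'   synthetic genome; variant coordinates are 1-based, windows 0-based
#'   half-open (BED convention).
#' @param n_templates number of template haplotypes for the Markov copying
#'   model.
#' @param switch_rate per-bp template switch rate; LD decays with distance.
#' @param switch_prob optional constant per-site switch probability that
#'   overrides `switch_rate` (useful for limit cases).
#' @param enforce_freq adjust panel columns so realized allele frequencies
#'   respect the per-variant frequency plan (required for the ground-truth
#'   guarantee; disable only to study the raw copying model).
#' @param coverage_fail_frac fraction of archaic genotype calls whose
#'   sequencing coverage is drawn outside the reliable range.
#' @param variants_per_gene number of consecutive variants per simulated gene.
#' @param eqtl_effect_prob per variant x tissue probability of a true
#'   cis-regulatory effect.
#' @param eqtl_effect_sd standard deviation of true effect sizes (slopes).
#' @param tissue_enrichment optional named multipliers on `eqtl_effect_prob`
#'   for derived-HF variants in the named tissues (injects tissue
#'   composition signal).
#' @param category_enrichment optional named multipliers on the consequence
#'   category probabilities for derived-HF variants.
#' @param sweep_width_meanlog lognormal meanlog of sweep-window widths (bp).
#' @param gwas_n GWAS sample size used for summary-statistic standard errors.
#' @param gwas_signal non-centrality (z-score scale) of simulated causal
#'   signals in GWAS/eQTL regional summaries.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_variants = 200, n_haplotypes = 40, seed = 1)
sim_config <- function(n_variants = 2000L,
                       n_haplotypes = 200L,
                       n_tissues = 15L,
                       hf_fraction = 0.2,
                       sweep_window_count = 30L,
                       sweep_enrichment_factor = 1,
                       coloc_scenario = c("H4", "H3", "H2", "H1", "H0"),
                       seed = 1L,
                       chrom_lengths = c(chrS1 = 6e7, chrS2 = 4e7),
                       n_templates = 8L,
                       switch_rate = 5e-6,
                       switch_prob = NULL,
                       enforce_freq = TRUE,
                       coverage_fail_frac = 0.10,
                       variants_per_gene = 10L,
                       eqtl_effect_prob = 0.15,
                       eqtl_effect_sd = 0.6,
                       tissue_enrichment = NULL,
                       category_enrichment = NULL,
                       sweep_width_meanlog = log(2.5e5),
                       gwas_n = 30000L,
                       gwas_signal = 8) {
  coloc_scenario <- match.arg(coloc_scenario)
  if (!is_count(n_variants) || !is_count(n_haplotypes) || !is_count(n_tissues))
    stop_config("n_variants, n_haplotypes and n_tissues must be positive counts")
  if (n_tissues > length(gtex_brain_samples()))
    stop_config("n_tissues cannot exceed ", length(gtex_brain_samples()))
  if (!is.numeric(hf_fraction) || hf_fraction < 0 || hf_fraction > 1)
    stop_config("hf_fraction must lie in [0, 1]")
  if (!is_count(sweep_window_count))
    stop_config("sweep_window_count must be a positive count")
  if (!is.numeric(sweep_enrichment_factor) || sweep_enrichment_factor < 1)
    stop_config("sweep_enrichment_factor must be >= 1")
  if (!is_count(seed + 1) || seed >= .Machine$integer.max)
    stop_config("seed must be a non-negative integer below 2^31 - 1")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop_config("chrom_lengths must be a named vector of positive lengths")
  if (!is.null(tissue_enrichment) &&
      !all(names(tissue_enrichment) %in% names(gtex_brain_samples())))
    stop_config("tissue_enrichment names must be known tissues")
  if (!is.null(category_enrichment) &&
      !all(names(category_enrichment) %in% .consequence_levels))
    stop_config("category_enrichment names must be known categories")
  structure(list(
    n_variants = as.integer(n_variants),
    n_haplotypes = as.integer(n_haplotypes),
    n_tissues = as.integer(n_tissues),
    metapops = c("AFR", "AMR", "EAS", "EUR", "SAS"),
    hf_fraction = hf_fraction,
    sweep_window_count = as.integer(sweep_window_count),
    sweep_enrichment_factor = sweep_enrichment_factor,
    coloc_scenario = coloc_scenario,
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    n_templates = as.integer(n_templates),
    switch_rate = switch_rate,
    switch_prob = switch_prob,
    enforce_freq = isTRUE(enforce_freq),
    coverage_fail_frac = coverage_fail_frac,
    variants_per_gene = as.integer(variants_per_gene),
    eqtl_effect_prob = eqtl_effect_prob,
    eqtl_effect_sd = eqtl_effect_sd,
    tissue_enrichment = tissue_enrichment,
    category_enrichment = category_enrichment,
    sweep_width_meanlog = sweep_width_meanlog,
    gwas_n = as.integer(gwas_n),
    gwas_signal = gwas_signal
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_variants, "variants,", x$n_haplotypes, "haplotypes,",
      x$n_tissues, "tissues, hf_fraction", x$hf_fraction,
      ", seed", x$seed, "\n")
  invisible(x)
}

# Per-variant simulation plan: positions, ground-truth mode (which
# classification rule, if any, the variant is built to fail), target derived
# frequency and panel-count bounds. Deterministic given cfg.
.sim_plan <- function(cfg) {
  s <- stage_seeds(cfg$seed, 2)
  with_seed(s[1], {
    n <- cfg$n_variants
    nh <- cfg$n_haplotypes
    lens <- cfg$chrom_lengths
    n_per <- diff(round(cumsum(c(0, lens)) / sum(lens) * n))
    chrom <- rep(names(lens), n_per)
    pos <- unlist(lapply(seq_along(lens), function(i) {
      sort(sample.int(lens[i], n_per[i]))
    }), use.names = FALSE)

    n_hf <- round(cfg$hf_fraction * n)
    mode <- rep(NA_character_, n)
    hf_idx <- if (n_hf > 0) sample.int(n, n_hf) else integer(0)
    mode[hf_idx] <- "hf"
    rest <- which(is.na(mode))
    if (length(rest)) {
      mode[rest] <- sample(
        c("freq_lo", "freq_mid", "metapop", "archaic", "ancestral", "coverage"),
        length(rest), replace = TRUE,
        prob = c(0.22, 0.33, 0.15, 0.15, 0.10, 0.05))
    }

    target <- numeric(n)
    high <- mode %in% c("hf", "metapop", "archaic", "ancestral", "coverage")
    target[high] <- runif(sum(high), 0.92, 0.99)
    target[mode == "freq_lo"] <- runif(sum(mode == "freq_lo"), 0.01, 0.08)
    target[mode == "freq_mid"] <- runif(sum(mode == "freq_mid"), 0.12, 0.85)

    lo <- integer(n); hi <- integer(n)
    lo[high] <- ceiling(0.91 * nh); hi[high] <- nh
    lo[mode == "freq_lo"] <- pmax(1L, floor(0.005 * nh))
    hi[mode == "freq_lo"] <- max(1L, floor(0.095 * nh))
    lo[mode == "freq_mid"] <- ceiling(0.105 * nh)
    hi[mode == "freq_mid"] <- floor(0.885 * nh)

    derived_is_alt <- runif(n) < 0.5
    rsid <- sprintf("rs%08d", sample.int(9e7, n))
    rsid[runif(n) < 0.05] <- NA_character_

    gene_id <- unlist(lapply(split(seq_len(n), chrom), function(ix) {
      g <- ceiling(seq_along(ix) / cfg$variants_per_gene)
      paste0("G_", chrom[ix[1]], "_", sprintf("%04d", g))
    }), use.names = FALSE)
    # restore original order (split() sorts by chrom levels)
    ord <- order(unlist(split(seq_len(n), chrom), use.names = FALSE))
    gene_id <- gene_id[ord]

    data.frame(
      vid = sprintf("v%06d", seq_len(n)),
      chrom = chrom, pos = pos, rsid = rsid, gene_id = gene_id,
      mode = mode, is_hf = mode == "hf",
      derived_is_alt = derived_is_alt,
      target_derived = target,
      lo_derived = lo, hi_derived = hi,
      stringsAsFactors = FALSE)
  })
}

#' Generate an LD-structured haplotype panel
#'
#' Haplotypes are built by Markov template copying: each haplotype copies one
#' of `n_templates` template haplotypes and switches to a random template
#' between adjacent sites with probability `1 - exp(-switch_rate * distance)`
#' (or the constant `switch_prob`). This produces clumpable haplotype blocks
#' whose LD decays with inter-variant distance. When `enforce_freq` is set
#' (the default), per-site allele counts are adjusted by minimal flips so
#' realized frequencies respect the per-variant frequency plan used by
#' [gen_variant_catalog()].
#'
#' @param cfg a [sim_config()].
#' @return an object of class `haplotype_panel`: a list with the binary
#'   `n_haplotypes x n_variants` matrix `H` (1 = ALT allele), `chrom`, `pos`,
#'   `vid` and `rsid` vectors; the simulation plan is attached as an
#'   attribute.
#' @export
#' @examples
#' panel <- gen_haplotypes(sim_config(n_variants = 100, n_haplotypes = 40))
#' dim(panel$H)
gen_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- .sim_plan(cfg)
  s <- stage_seeds(cfg$seed, 3)[2]
  with_seed(s, {
    n <- cfg$n_variants
    nh <- cfg$n_haplotypes
    nt <- cfg$n_templates

    # target ALT frequency per site (plan targets are on the derived allele)
    p_alt <- ifelse(plan$derived_is_alt, plan$target_derived,
                    1 - plan$target_derived)
    tmpl <- matrix(rbinom(nt * n, 1L, rep(p_alt, each = nt)), nrow = nt)

    # per-site switch probability; a fresh template is always drawn at the
    # first site of each chromosome unless a constant switch_prob is given
    new_chrom <- c(TRUE, plan$chrom[-1] != plan$chrom[-n])
    if (!is.null(cfg$switch_prob)) {
      q <- rep(cfg$switch_prob, n)
    } else {
      d <- c(0, diff(plan$pos))
      d[new_chrom] <- 0
      q <- 1 - exp(-cfg$switch_rate * d)
      q[new_chrom] <- 1
    }

    H <- matrix(0L, nrow = nh, ncol = n)
    cols <- seq_len(n)
    for (h in seq_len(nh)) {
      sw <- runif(n) < q
      sw[1] <- TRUE
      seg <- cumsum(sw)
      ids <- sample.int(nt, seg[n], replace = TRUE)
      H[h, ] <- tmpl[cbind(ids[seg], cols)]
    }

    if (cfg$enforce_freq) {
      lo_alt <- ifelse(plan$derived_is_alt, plan$lo_derived, nh - plan$hi_derived)
      hi_alt <- ifelse(plan$derived_is_alt, plan$hi_derived, nh - plan$lo_derived)
      cnt <- colSums(H)
      for (j in which(cnt < lo_alt)) {
        zeros <- which(H[, j] == 0L)
        H[sample(zeros, lo_alt[j] - cnt[j]), j] <- 1L
      }
      for (j in which(cnt > hi_alt)) {
        ones <- which(H[, j] == 1L)
        H[sample(ones, cnt[j] - hi_alt[j]), j] <- 0L
      }
    }

    dimnames(H) <- list(sprintf("hap%04d", seq_len(nh)), plan$vid)
    structure(list(H = H, chrom = plan$chrom, pos = plan$pos,
                   vid = plan$vid, rsid = plan$rsid),
              plan = plan, class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$H), "haplotypes x", ncol(x$H), "variants on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

# coverage sampler: reliable range is [5, upper]; failing draws fall on
# either tail so both coverage bounds are exercised
.draw_dp <- function(n, upper, fail) {
  dp <- integer(n)
  npass <- sum(!fail)
  if (npass) {
    x <- rnbinom(4L * npass, size = 12, mu = 40)
    x <- x[x >= 5L & x <= upper]
    while (length(x) < npass) {
      extra <- rnbinom(4L * npass, size = 12, mu = 40)
      x <- c(x, extra[extra >= 5L & extra <= upper])
    }
    dp[!fail] <- x[seq_len(npass)]
  }
  nfail <- sum(fail)
  if (nfail) {
    low <- runif(nfail) < 0.5
    out <- integer(nfail)
    out[low] <- sample(0:4, sum(low), replace = TRUE)
    out[!low] <- upper + sample.int(40L, sum(!low), replace = TRUE)
    dp[fail] <- out
  }
  dp
}

.gt <- function(a1, a2) paste(a1, a2, sep = "/")

#' Generate a variant catalog with archaic genotypes and ground truth
#'
#' Emits one record per panel variant: REF/ALT alleles, ancestral-allele
#' calls from the great-ape alignment and/or the macaque reference, global
#' and five-metapopulation derived/ALT frequencies (the global ALT frequency
#' equals the panel column frequency exactly), and diploid genotypes with
#' per-site coverage for the three archaic individuals (Altai, Vindija,
#' Denisova). Variants flagged `is_derived_hf` in the ground truth satisfy
#' every classification rule by construction; all other variants are built to
#' fail at least one named rule (`failure_mode` in the truth table).
#'
#' @param cfg a [sim_config()].
#' @param panel the [gen_haplotypes()] output for the same `cfg`.
#' @return list with elements `catalog` (data frame, one row per variant) and
#'   `truth` (data frame with `vid`, `rsid`, `gene_id`, `is_derived_hf`,
#'   `failure_mode`, `derived` allele and `derived_is_alt`).
#' @export
#' @examples
#' cfg <- sim_config(n_variants = 100, n_haplotypes = 40, seed = 2)
#' cat <- gen_variant_catalog(cfg, gen_haplotypes(cfg))
#' table(cat$truth$failure_mode)
gen_variant_catalog <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "haplotype_panel"))
  plan <- attr(panel, "plan")
  s <- stage_seeds(cfg$seed, 4)[3]
  with_seed(s, {
    n <- nrow(plan)
    nh <- cfg$n_haplotypes
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

    derived <- ifelse(plan$derived_is_alt, alt, ref)
    ancestral <- ifelse(plan$derived_is_alt, ref, alt)

    af_alt <- colMeans(panel$H)
    af_derived <- ifelse(plan$derived_is_alt, af_alt, 1 - af_alt)

    # ancestral-allele sources: ape alignment for most, macaque for ambiguous
    # loci; 'ancestral' mode variants are unresolvable (both missing, or an
    # allele matching neither REF nor ALT)
    anc_ape <- ancestral
    anc_mac <- ifelse(runif(n) < 0.6, ancestral, NA_character_)
    mac_only <- runif(n) < 0.15
    anc_ape[mac_only] <- NA_character_
    anc_mac[mac_only] <- ancestral[mac_only]
    bad <- which(plan$mode == "ancestral")
    if (length(bad)) {
      mism <- runif(length(bad)) < 0.5
      third <- vapply(bad[mism], function(i) {
        sample(setdiff(bases, c(ref[i], alt[i])), 1L)
      }, "")
      anc_ape[bad] <- NA_character_; anc_mac[bad] <- NA_character_
      anc_ape[bad[mism]] <- third
    }

    # metapopulation frequencies on the derived allele, jittered around the
    # global value; HF-style variants are clamped so only the designated
    # rule can fail, 'metapop' variants dip below 0.9 in one population
    J <- matrix(runif(5L * n, -0.04, 0.04), nrow = n)
    afp <- clamp(af_derived + J, 0, 1)
    strictish <- plan$mode %in% c("hf", "archaic", "ancestral", "coverage")
    afp[strictish, ] <- clamp(afp[strictish, , drop = FALSE], 0.905, 1)
    mp <- which(plan$mode == "metapop")
    if (length(mp)) {
      afp[mp, ] <- clamp(afp[mp, , drop = FALSE], 0.905, 1)
      kcol <- sample.int(5L, length(mp), replace = TRUE)
      afp[cbind(mp, kcol)] <- runif(length(mp), 0.80, 0.895)
    }
    # store metapop frequencies ALT-oriented, like the global AF
    afp_alt <- afp
    flipme <- !plan$derived_is_alt
    afp_alt[flipme, ] <- 1 - afp[flipme, , drop = FALSE]

    # archaic genotypes + coverage
    gt_a <- gt_v <- gt_d <- character(n)
    fail_a <- runif(n) < cfg$coverage_fail_frac
    fail_v <- runif(n) < cfg$coverage_fail_frac
    fail_d <- runif(n) < cfg$coverage_fail_frac

    rand_gt <- function(i) {
      k <- sample(c("aa", "ad", "dd", "mm"), 1L, prob = c(0.5, 0.2, 0.2, 0.1))
      switch(k,
             aa = .gt(ancestral[i], ancestral[i]),
             ad = .gt(ancestral[i], derived[i]),
             dd = .gt(derived[i], derived[i]),
             mm = "./.")
    }

    for (i in seq_len(n)) {
      m <- plan$mode[i]
      a <- ancestral[i]; d <- derived[i]
      if (m == "coverage") {
        fail_a[i] <- fail_v[i] <- fail_d[i] <- TRUE
        gt_a[i] <- .gt(a, a); gt_v[i] <- .gt(a, a); gt_d[i] <- .gt(a, a)
      } else if (m == "archaic") {
        fail_a[i] <- fail_v[i] <- fail_d[i] <- FALSE
        sub <- sample(3L, 1L)
        if (sub == 1L) {          # all homozygous derived
          gt_a[i] <- .gt(d, d); gt_v[i] <- .gt(d, d); gt_d[i] <- .gt(d, d)
        } else if (sub == 2L) {   # Denisovan homozygous derived, Neanderthals ancestral
          gt_a[i] <- .gt(a, a); gt_v[i] <- .gt(a, a); gt_d[i] <- .gt(d, d)
        } else {                  # Denisovan heterozygous, Neanderthals ancestral
          gt_a[i] <- .gt(a, a); gt_v[i] <- .gt(a, a); gt_d[i] <- .gt(a, d)
        }
      } else if (m == "hf") {
        clause <- sample(1:2, 1L, prob = c(0.7, 0.3))
        if (clause == 1L) {
          # all reliable archaics homozygous ancestral; masked ones random
          if (fail_a[i] && fail_v[i] && fail_d[i]) fail_a[i] <- FALSE
          gt_a[i] <- if (fail_a[i]) rand_gt(i) else .gt(a, a)
          gt_v[i] <- if (fail_v[i]) rand_gt(i) else .gt(a, a)
          gt_d[i] <- if (fail_d[i]) rand_gt(i) else .gt(a, a)
        } else {
          # gene-flow clause: Denisovan ancestral, one Neanderthal derived
          fail_d[i] <- FALSE
          gt_d[i] <- .gt(a, a)
          nea <- sample(c("altai", "vindija"), 1L)
          cg <- if (runif(1) < 0.5) .gt(a, d) else .gt(d, d)
          if (nea == "altai") {
            fail_a[i] <- FALSE; gt_a[i] <- cg
            gt_v[i] <- if (fail_v[i]) rand_gt(i) else .gt(a, a)
          } else {
            fail_v[i] <- FALSE; gt_v[i] <- cg
            gt_a[i] <- if (fail_a[i]) rand_gt(i) else .gt(a, a)
          }
        }
      } else {
        # freq/metapop/ancestral modes: archaic condition holds (clause 1)
        # so only the designated rule fails
        if (fail_a[i] && fail_v[i] && fail_d[i]) fail_a[i] <- FALSE
        gt_a[i] <- if (fail_a[i]) rand_gt(i) else .gt(a, a)
        gt_v[i] <- if (fail_v[i]) rand_gt(i) else .gt(a, a)
        gt_d[i] <- if (fail_d[i]) rand_gt(i) else .gt(a, a)
      }
    }

    dp_a <- .draw_dp(n, 105L, fail_a)
    dp_v <- .draw_dp(n, 75L, fail_v)
    dp_d <- .draw_dp(n, 75L, fail_d)

    catalog <- data.frame(
      vid = plan$vid, chrom = plan$chrom, pos = plan$pos, rsid = plan$rsid,
      ref = ref, alt = alt,
      anc_ape = anc_ape, anc_macaque = anc_mac,
      af_global = af_alt,
      af_AFR = afp_alt[, 1], af_AMR = afp_alt[, 2], af_EAS = afp_alt[, 3],
      af_EUR = afp_alt[, 4], af_SAS = afp_alt[, 5],
      gt_altai = gt_a, gt_vindija = gt_v, gt_denisova = gt_d,
      dp_altai = dp_a, dp_vindija = dp_v, dp_denisova = dp_d,
      stringsAsFactors = FALSE)

    truth <- data.frame(
      vid = plan$vid, rsid = plan$rsid, chrom = plan$chrom, pos = plan$pos,
      gene_id = plan$gene_id, is_derived_hf = plan$is_hf,
      failure_mode = ifelse(plan$is_hf, "none", plan$mode),
      derived = derived, derived_is_alt = plan$derived_is_alt,
      af_derived = af_derived,
      stringsAsFactors = FALSE)

    list(catalog = catalog, truth = truth)
  })
}

#' Generate tissue-stratified cis-eQTL association tables
#'
#' Simulates GTEx-style significant-pair tables for the configured brain
#' tissues. Within each gene, marginal effects are propagated through the
#' panel LD (`beta_marginal = R beta_true`), so association p-values form
#' clumpable blocks around causal variants. Discovery power scales with the
#' per-tissue sample size, the duplicate tissue pairs
#' (Cerebellum/Cerebellar Hemisphere, Cortex/BA9) share correlated true
#' effects, and the significance flag applies Benjamini-Hochberg control at
#' FDR 0.05 per tissue, mirroring the GTEx convention.
#'
#' @param cfg a [sim_config()].
#' @param catalog,truth the [gen_variant_catalog()] outputs.
#' @param panel the haplotype panel (for LD propagation).
#' @return data frame with columns `variant_id` (rsid), `gene_id`, `tissue`,
#'   `slope`, `slope_se`, `pval_nominal`, `qval_pass` (logical),
#'   `consequence_category`, plus attributes `samples` (named sample sizes)
#'   and `causal` (data frame of true causal events: gene, tissue, vid,
#'   true slope).
#' @export
gen_eqtl_tables <- function(cfg, catalog, truth, panel) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- stage_seeds(cfg$seed, 5)[4]
  with_seed(s, {
    samples <- gtex_brain_samples()[seq_len(cfg$n_tissues)]
    tissues <- names(samples)

    keep <- !is.na(truth$rsid)   # only rsID-mapped variants are eQTL-testable
    idx <- which(keep)
    n <- length(idx)
    genes <- truth$gene_id[idx]

    # consequence categories: a per-variant property; optionally enriched in
    # derived-HF variants
    cat_lab <- character(n)
    pr0 <- .base_category_probs
    pr1 <- pr0
    if (!is.null(cfg$category_enrichment)) {
      pr1[names(cfg$category_enrichment)] <-
        pr1[names(cfg$category_enrichment)] * cfg$category_enrichment
      pr1 <- pr1 / sum(pr1)
    }
    is_hf <- truth$is_derived_hf[idx]
    cat_lab[!is_hf] <- sample(names(pr0), sum(!is_hf), TRUE, prob = pr0)
    if (any(is_hf))
      cat_lab[is_hf] <- sample(names(pr1), sum(is_hf), TRUE, prob = pr1)

    # true effects per variant x tissue
    dup_of <- setNames(rep(NA_character_, length(tissues)), tissues)
    for (p in .dup_tissue_pairs)
      if (all(p %in% tissues)) dup_of[p[2]] <- p[1]

    beta_true <- matrix(0, nrow = n, ncol = length(tissues),
                        dimnames = list(NULL, tissues))
    # template tissues must be drawn before their duplicates
    tissue_order <- c(tissues[is.na(dup_of)], tissues[!is.na(dup_of)])
    for (t in tissue_order) {
      if (!is.na(dup_of[t])) {
        beta_true[, t] <- beta_true[, dup_of[t]] + rnorm(n, 0, 0.1)
        # a duplicate only inherits where the template had an effect
        beta_true[beta_true[, dup_of[t]] == 0, t] <- 0
        next
      }
      p_eff <- rep(cfg$eqtl_effect_prob, n)
      if (!is.null(cfg$tissue_enrichment) && t %in% names(cfg$tissue_enrichment))
        p_eff[is_hf] <- pmin(1, p_eff[is_hf] * cfg$tissue_enrichment[[t]])
      hit <- runif(n) < p_eff
      beta_true[hit, t] <- rnorm(sum(hit), 0, cfg$eqtl_effect_sd)
    }

    # marginal effects through LD, per gene
    beta_marg <- beta_true
    gsplit <- split(seq_len(n), genes)
    for (ix in gsplit) {
      if (length(ix) < 2) next
      sub <- beta_true[ix, , drop = FALSE]
      if (all(sub == 0)) next
      Hs <- panel$H[, idx[ix], drop = FALSE]
      sds <- apply(Hs, 2, sd)
      ok <- sds > 0
      R <- diag(length(ix))
      if (sum(ok) > 1) {
        Rok <- suppressWarnings(cor(Hs[, ok, drop = FALSE]))
        Rok[!is.finite(Rok)] <- 0
        R[ok, ok] <- Rok
      }
      beta_marg[ix, ] <- R %*% sub
    }

    out <- vector("list", length(tissues))
    for (k in seq_along(tissues)) {
      t <- tissues[k]
      se <- 1 / sqrt(samples[[t]])
      slope_hat <- beta_marg[, k] + rnorm(n, 0, se)
      z <- slope_hat / se
      p <- 2 * pnorm(-abs(z))
      pass <- p.adjust(p, method = "BH") < 0.05
      out[[k]] <- data.frame(
        variant_id = truth$rsid[idx], gene_id = genes, tissue = t,
        slope = slope_hat, slope_se = se, pval_nominal = p,
        qval_pass = pass, consequence_category = cat_lab,
        stringsAsFactors = FALSE)
    }
    eqtls <- do.call(rbind, out)
    rownames(eqtls) <- NULL

    causal <- which(beta_true != 0, arr.ind = TRUE)
    causal_df <- data.frame(
      gene_id = genes[causal[, 1]],
      tissue = tissues[causal[, 2]],
      vid = truth$vid[idx][causal[, 1]],
      variant_id = truth$rsid[idx][causal[, 1]],
      beta_true = beta_true[causal],
      stringsAsFactors = FALSE)

    attr(eqtls, "samples") <- samples
    attr(eqtls, "causal") <- causal_df
    eqtls
  })
}

#' Generate selective-sweep window sets for two studies
#'
#' Emits two window sets emulating independent sweep scans: the second source
#' has ~30% more and systematically wider windows (so length normalization is
#' exercised). With `sweep_enrichment_factor = 1` windows are placed
#' uniformly, independent of the variants; for factor `f > 1` a fraction
#' `1 - 1/f` of the windows is centered on derived-HF variant positions, so
#' those positions fall inside windows at an elevated rate.
#'
#' @param cfg a [sim_config()].
#' @param catalog,truth the [gen_variant_catalog()] outputs.
#' @return data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `source`; ground-truth sweep membership per source is attached as the
#'   attribute `in_sweep` (logical matrix, one row per catalog variant).
#' @export
gen_sweep_windows <- function(cfg, catalog, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- stage_seeds(cfg$seed, 6)[5]
  with_seed(s, {
    lens <- cfg$chrom_lengths
    hf_idx <- which(truth$is_derived_hf)
    q <- 1 - 1 / cfg$sweep_enrichment_factor

    one_source <- function(count, meanlog, label) {
      width <- pmax(1e4, round(rlnorm(count, meanlog, 0.5)))
      if (any(width >= sum(lens) / length(lens)) && any(width >= lens))
        stop_config("sweep window wider than a chromosome")
      chrom <- character(count); start <- numeric(count)
      on_hf <- length(hf_idx) > 0 & runif(count) < q
      for (i in seq_len(count)) {
        if (on_hf[i]) {
          j <- sample(hf_idx, 1L)
          chrom[i] <- truth$chrom[j]
          center <- truth$pos[j] + round(runif(1, -width[i] / 4, width[i] / 4))
          start[i] <- center - floor(width[i] / 2)
        } else {
          chrom[i] <- sample(names(lens), 1L, prob = lens)
          start[i] <- floor(runif(1, 0, lens[[chrom[i]]] - width[i]))
        }
        start[i] <- max(0, min(start[i], lens[[chrom[i]]] - width[i]))
      }
      data.frame(chrom = chrom, start = start, end = start + width,
                 source = label, stringsAsFactors = FALSE)
    }

    wA <- one_source(cfg$sweep_window_count, cfg$sweep_width_meanlog, "sweepA")
    wB <- one_source(round(1.3 * cfg$sweep_window_count),
                     cfg$sweep_width_meanlog + log(1.6), "sweepB")
    windows <- rbind(wA, wB)

    pos_df <- data.frame(chrom = truth$chrom, pos = truth$pos)
    insw <- cbind(
      sweepA = position_in_windows(pos_df, wA),
      sweepB = position_in_windows(pos_df, wB))
    attr(windows, "in_sweep") <- insw
    windows
  })
}

#' Generate GWAS summary statistics for one trait
#'
#' Per-gene causal structure follows the configured colocalization scenario:
#' under `H4` the GWAS causal variant is the gene's strongest true eQTL
#' variant; under `H3` it is a distinct variant in the same gene chosen to
#' be in low LD (r-squared < 0.1 where possible) with the eQTL causal; under
#' `H2` a random variant per gene carries the GWAS signal; under `H0`/`H1`
#' the trait is null. Marginal z-scores propagate through panel LD, standard
#' errors follow `1/sqrt(2 n p (1-p))`, and effect/other alleles are emitted
#' in random orientation so harmonization is exercised.
#'
#' @param cfg a [sim_config()].
#' @param catalog,truth the [gen_variant_catalog()] outputs.
#' @param panel the haplotype panel.
#' @param eqtl_causal the `causal` attribute of [gen_eqtl_tables()] (required
#'   for scenarios H3/H4).
#' @param trait trait label.
#' @return data frame with `SNP`, `beta`, `se`, `pval`, `effect_allele`,
#'   `other_allele`, `eaf`, `n`, `trait`; the per-gene GWAS causal variants
#'   are attached as attribute `gwas_causal`.
#' @export
gen_gwas_summary <- function(cfg, catalog, truth, panel, eqtl_causal = NULL,
                             trait = "trait1") {
  stopifnot(inherits(cfg, "sim_config"))
  scen <- cfg$coloc_scenario
  if (scen %in% c("H3", "H4") && is.null(eqtl_causal))
    stop_config("scenarios H3/H4 need the eQTL causal table")
  s <- stage_seeds(cfg$seed, 7)[6]
  trait_seed <- (s + sum(utf8ToInt(trait))) %% (.Machine$integer.max - 1L)
  with_seed(trait_seed, {
    keep <- which(!is.na(truth$rsid))
    n <- length(keep)
    z <- rnorm(n)
    gwas_causal <- data.frame(gene_id = character(0), vid = character(0))

    if (scen %in% c("H2", "H3", "H4")) {
      gsplit <- split(seq_len(n), truth$gene_id[keep])
      picks <- list()
      for (g in names(gsplit)) {
        ix <- gsplit[[g]]
        cvid <- NA_character_
        if (scen == "H2") {
          if (runif(1) < cfg$eqtl_effect_prob * 2) cvid <- truth$vid[keep][sample(ix, 1L)]
        } else {
          ec <- eqtl_causal[eqtl_causal$gene_id == g, , drop = FALSE]
          if (nrow(ec)) {
            e_vid <- ec$vid[which.max(abs(ec$beta_true))]
            if (scen == "H4") {
              cvid <- e_vid
            } else {
              e_col <- match(e_vid, truth$vid[keep])
              Hs <- panel$H[, keep[ix], drop = FALSE]
              x <- panel$H[, keep[e_col]]
              r2 <- suppressWarnings(as.vector(cor(x, Hs))^2)
              r2[!is.finite(r2)] <- 1
              cand <- ix[r2 < 0.1 & truth$vid[keep][ix] != e_vid]
              if (!length(cand)) cand <- ix[order(r2)][1]
              cvid <- truth$vid[keep][sample(rep(cand, 2L), 1L)]
            }
          }
        }
        if (!is.na(cvid)) picks[[g]] <- cvid
      }
      if (length(picks)) {
        gwas_causal <- data.frame(gene_id = names(picks),
                                  vid = unlist(picks, use.names = FALSE),
                                  stringsAsFactors = FALSE)
        for (g in gwas_causal$gene_id) {
          ix <- gsplit[[g]]
          c_col <- match(gwas_causal$vid[gwas_causal$gene_id == g], truth$vid[keep])
          Hs <- panel$H[, keep[ix], drop = FALSE]
          x <- panel$H[, keep[c_col]]
          r <- suppressWarnings(as.vector(cor(x, Hs)))
          r[!is.finite(r)] <- 0
          r[ix == c_col] <- 1
          z[ix] <- z[ix] + r * cfg$gwas_signal
        }
      }
    }

    af <- clamp(catalog$af_global[keep], 0.01, 0.99)
    se <- 1 / sqrt(2 * cfg$gwas_n * af * (1 - af))
    beta <- z * se
    pval <- 2 * pnorm(-abs(z))

    flip <- runif(n) < 0.5
    effect_allele <- ifelse(flip, catalog$ref[keep], catalog$alt[keep])
    other_allele <- ifelse(flip, catalog$alt[keep], catalog$ref[keep])
    beta <- ifelse(flip, -beta, beta)
    eaf <- ifelse(flip, 1 - af, af)

    out <- data.frame(SNP = truth$rsid[keep], beta = beta, se = se,
                      pval = pval, effect_allele = effect_allele,
                      other_allele = other_allele, eaf = eaf,
                      n = cfg$gwas_n, trait = trait,
                      stringsAsFactors = FALSE)
    attr(out, "gwas_causal") <- gwas_causal
    out
  })
}

#' Simulate a matched pair of regional association summaries for coloc
#'
#' Stand-alone generator for colocalization scenarios: builds a small
#' LD-structured haplotype panel for one region and simulates marginal
#' z-scores for two traits (an eQTL-scale trait and a GWAS-scale trait)
#' under the requested hypothesis. `H4` places the same causal variant in
#' both traits, `H3` two distinct causal variants in low LD (r-squared <
#' 0.1 where attainable), `H1`/`H2` one-sided signals, `H0` none.
#'
#' @param scenario one of `"H0"`..`"H4"`.
#' @param n_variants,n_haplotypes region size and panel depth.
#' @param lambda causal signal strength on the z-score scale.
#' @param seed integer seed.
#' @return list with `trait1`, `trait2` (data frames `snp`, `beta`, `se`)
#'   and `truth` (scenario, causal indices, their r-squared).
#' @export
#' @examples
#' reg <- gen_coloc_region("H4", seed = 1)
#' head(reg$trait1)
gen_coloc_region <- function(scenario = c("H4", "H3", "H2", "H1", "H0"),
                             n_variants = 120L, n_haplotypes = 400L,
                             lambda = 8, seed = 1L) {
  scenario <- match.arg(scenario)
  cfg <- sim_config(n_variants = n_variants, n_haplotypes = n_haplotypes,
                    hf_fraction = 0, seed = seed,
                    chrom_lengths = c(chrR = 1e6), switch_rate = 2e-5)
  panel <- gen_haplotypes(cfg)
  with_seed(seed + 977L, {
    H <- panel$H
    maf <- pmin(colMeans(H), 1 - colMeans(H))
    poly <- which(maf >= 0.05)
    c1 <- sample(poly, 1L)
    R1 <- suppressWarnings(as.vector(cor(H[, c1], H)))
    R1[!is.finite(R1)] <- 0; R1[c1] <- 1
    c2 <- NA_integer_; r2_12 <- NA_real_
    if (scenario == "H4") {
      c2 <- c1; r2_12 <- 1
    } else if (scenario == "H3") {
      cand <- poly[R1[poly]^2 < 0.1 & poly != c1]
      c2 <- if (length(cand)) sample(rep(cand, 2L), 1L) else poly[which.min(R1[poly]^2)]
      r2_12 <- R1[c2]^2
    }
    z1 <- rnorm(n_variants)
    z2 <- rnorm(n_variants)
    if (scenario %in% c("H1", "H3", "H4")) z1 <- z1 + R1 * lambda
    if (scenario %in% c("H2", "H3", "H4")) {
      cc <- if (scenario == "H2") c1 else c2
      Rc <- suppressWarnings(as.vector(cor(H[, cc], H)))
      Rc[!is.finite(Rc)] <- 0; Rc[cc] <- 1
      z2 <- z2 + Rc * lambda
    }
    af <- clamp(colMeans(H), 0.01, 0.99)
    se1 <- 1 / sqrt(2 * 500 * af * (1 - af))
    se2 <- 1 / sqrt(2 * 30000 * af * (1 - af))
    list(trait1 = data.frame(snp = panel$vid, beta = z1 * se1, se = se1),
         trait2 = data.frame(snp = panel$vid, beta = z2 * se2, se = se2),
         truth = list(scenario = scenario, causal1 = c1, causal2 = c2,
                      r2_causals = r2_12))
  })
}

#' Generate every pipeline input in one call
#'
#' @param cfg a [sim_config()].
#' @param gwas_traits character vector of trait labels for GWAS summaries;
#'   defaults to the ten synthetic brain-volume traits (four cerebellar
#'   substructures plus six subcortical volumes).
#' @return list with `panel`, `catalog`, `truth`, `eqtls`, `windows`, `gwas`
#'   (named list of per-trait summary tables).
#' @export
simulate_inputs <- function(cfg, gwas_traits = default_gwas_traits()) {
  panel <- gen_haplotypes(cfg)
  vc <- gen_variant_catalog(cfg, panel)
  eqtls <- gen_eqtl_tables(cfg, vc$catalog, vc$truth, panel)
  windows <- gen_sweep_windows(cfg, vc$catalog, vc$truth)
  causal <- attr(eqtls, "causal")
  gwas <- lapply(gwas_traits, function(tr) {
    gen_gwas_summary(cfg, vc$catalog, vc$truth, panel,
                     eqtl_causal = causal, trait = tr)
  })
  names(gwas) <- gwas_traits
  list(panel = panel, catalog = vc$catalog, truth = vc$truth,
       eqtls = eqtls, windows = windows, gwas = gwas)
}

#' Default synthetic brain-volume GWAS trait labels
#' @return character vector of ten trait labels.
#' @export
default_gwas_traits <- function() {
  c("cerebellum_WM_left", "cerebellum_WM_right",
    "cerebellum_cortex_left", "cerebellum_cortex_right",
    "putamen_volume", "hippocampus_volume", "amygdala_volume",
    "thalamus_volume", "caudate_volume", "pallidum_volume")
}
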