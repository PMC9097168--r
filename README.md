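# paleoqtl

Brain cis-eQTL analysis of nearly fixed, *Homo sapiens*-derived alleles.

High-coverage archaic genomes (the Altai and Vindija Neanderthals and a
Denisovan) make it possible to ask which alleles are specific to our
lineage, and tissue-level eQTL resources make it possible to ask what those
alleles do to gene regulation. `paleoqtl` implements that analysis chain
for brain tissues, end to end, for anyone working on human brain evolution
or archaic-comparative regulatory genomics:

1. **Classify** catalog variants as derived high-frequency (HF) alleles:
   derived-allele frequency >= 90% globally and (stringently) in each of
   the five 1000 Genomes metapopulations, ancestral allele resolved from
   great-ape alignments with a macaque (rheMac3) fallback, archaic
   genotypes reliable within coverage bounds (5–105x Altai, 5–75x
   Vindija/Denisovan), and the archaic condition: all reliable archaics
   homozygous ancestral, *or* Denisovan ancestral with a Neanderthal
   carrying the derived allele (gene flow from *H. sapiens* into
   Neanderthals).
2. **Join** with significant cis-eQTL tables over 15 CNS-related tissues
   and test tissue / functional-category composition against the
   background eQTL set (chi-square homogeneity with adjusted residuals,
   `r = (O-E)/sqrt(E(1-rowshare)(1-colshare))`).
3. **Clump** by LD: greedy p-value-ordered clumping at `r² >= 0.1` within
   250 kb, with `r²` computed from a haplotype panel.
4. **Permutation-test** overlap of derived-HF eQTL positions with
   selective-sweep windows (`p = (1 + #{perm >= obs})/(N+1)`), per-tissue
   counts per megabase of window, Wilcoxon and Dunn between-study
   comparisons.
5. **Directionality**: up- vs down-regulation by derived-allele dosage
   against the 50/50 null, with a major-ancestral-allele control.
6. **Causality**: Wald-ratio two-sample Mendelian randomization
   (`beta_IV = beta_outcome/beta_exposure`, `se_IV = |se_outcome/
   beta_exposure|`) of top eQTL instruments (p <= 5e-4) against
   brain-volume GWAS summaries, Bonferroni-corrected, then
   approximate-Bayes-factor colocalization (Wakefield ABFs, priors
   p1 = p2 = 1e-4, p12 = 1e-5) summarized by posteriors PP0–PP4.

A synthetic-data module (`sim_config()`, `simulate_inputs()`,
`gen_coloc_region()`) emulates every input — archaic genotypes with
coverage, LD-structured haplotypes, tissue eQTL tables with realistic
sample-size-driven power, sweep windows with controllable enrichment, GWAS
summaries under colocalization scenarios H0–H4 — with known ground truth,
so the whole pipeline is testable without any external download.

## Worked example

```r
library(paleoqtl)

cfg <- sim_config(n_variants = 2000, n_haplotypes = 200, seed = 5,
                  tissue_enrichment = c(Pituitary = 3, Cerebellum = 3))
res <- run_pipeline(run_config(sim = cfg, seed = 11), out_dir = "run1")

res$summary[c("n_derived_hf", "n_hf_eqtl_variants", "n_egenes", "n_clumped")]
#> $n_derived_hf      [1] 400
#> $n_hf_eqtl_variants [1] 351
#> $n_egenes          [1] 174
#> $n_clumped         [1] 1003

print(res$tissue_test)
#> Chi-square homogeneity test: X2 = 176.25 df = 14 , p = < 2.22e-16
#> cells driving significance (|adjusted residual| > 1.96 ): BA24, BA9, ...
#>   Cerebellum, ... Pituitary, ...

print(res$sweep_tests$sweepA)
#> Permutation overlap test (N = 1000 ): observed = 29 , expected = 26.81 ,
#>   p = 0.3706 , z = 0.448

print(res$direction$unclumped)
#> Directionality test: up = 539 , down = 470 ( 0 zero slopes excluded ),
#>   X2 = 4.7185 , p = 0.029839
```

Reading these numbers: of 2,000 simulated variants, 400 were built as
derived-HF and all 400 are recovered by the classifier; 351 of them carry
a significant eQTL association (on 174 eGenes), reduced to 1,003
tissue-level index variants after clumping. The tissue composition test
rejects homogeneity and its positive residuals include the two tissues the
generator enriched threefold (Pituitary, Cerebellum; neighbouring flags
come from the duplicate-tissue correlation and chance at alpha = 0.05).
The sweep overlap test is null, as it should be at enrichment factor 1.
The directionality p of 0.03 is a type-I fluctuation of this particular
seed — the generator's slopes are symmetric, and over 500 replicates the
rejection rate sits at the nominal 5% (this is one of the acceptance
checks).

Individual stages are plain functions if you bring your own files:
`read_catalog()` + `classify_variants()`, `read_eqtls()` +
`eqtl_intersect()`, `ld_clump()`, `sweep_permutation_test()`,
`mr_wald()`, `coloc_abf()`, etc.

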