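---
title: "Methods: classifying nearly fixed derived alleles and testing their regulatory effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying nearly fixed derived alleles and testing their regulatory effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoqtl)
```

## The analysis

`paleoqtl` implements a population-genetic analysis chain that asks what
*Homo sapiens*-specific, nearly fixed alleles do to gene regulation in the
brain. The chain has six scientific stages, each exposed as ordinary R
functions and orchestrated by `run_pipeline()`:

1. **Classification** (`classify_variants()`): a catalog variant is a
   derived high-frequency (HF) allele when (i) its ancestral allele is
   resolvable from the great-ape alignment call, falling back to the
   macaque (rheMac3) reference only for ambiguous loci; (ii) the derived
   allele is the major allele and reaches 90% frequency globally and — in
   the stringent mode that is the default — in each of the five 1000
   Genomes metapopulations (AFR, AMR, EAS, EUR, SAS); (iii) at least one
   archaic genotype is reliable, where reliability means site coverage
   inside 5–105x for the Altai Neanderthal and 5–75x for the Vindija
   Neanderthal and the Denisovan; and (iv) the archaic condition holds:
   either every reliable archaic genotype is homozygous ancestral, or the
   Denisovan is reliable and homozygous ancestral while a reliable
   Neanderthal carries at least one derived allele. The second clause
   tolerates gene flow from *Homo sapiens* into Neanderthals.
2. **eQTL join and composition tests** (`eqtl_intersect()`,
   `tissue_composition_test()`, `category_composition_test()`): significant
   cis-eQTL associations (FDR 0.05, the GTEx convention) are split into the
   derived-HF focal set and the background, and compared as a 2 x K
   contingency table of per-tissue (or per-consequence-category) counts.
3. **LD clumping** (`ld_clump()`): greedy p-value-ordered clumping at
   r^2 >= 0.1 within 250 kb, computing r^2 from a haplotype panel.
4. **Sweep overlap** (`sweep_permutation_test()`): a permutation test for
   the overlap of (unclumped) derived-HF eQTL positions with
   selective-sweep windows from two independent scans.
5. **Directionality** (`direction_test()`): do derived alleles skew toward
   down- or up-regulation once slopes are oriented to derived-allele
   dosage, with a major-ancestral-allele control set?
6. **Causality** (`select_instruments()`, `mr_wald()`, `coloc_abf()`):
   Wald-ratio two-sample Mendelian randomization of top eQTL instruments
   against brain-volume GWAS summaries, Bonferroni corrected, followed by
   approximate-Bayes-factor colocalization of the surviving signals.

Every stage can run on synthetic inputs with known ground truth
(`simulate_inputs()`), which is how the package tests itself.

## Classification details and chosen readings

The coverage bounds are treated as **inclusive** (a site at exactly 5x or
105x/75x is reliable): the exclusion rule names sites *below* 5-fold and
*above* the upper bound. A coverage-failing archaic is **masked** rather
than the whole site being dropped, because the gene-flow clause explicitly
uses informative subsets; only sites with zero reliable archaics are
excluded as undecidable.

Heterozygous archaic genotypes are ambiguous under "have the ancestral
allele". The strict default requires homozygous ancestral in clause 1,
while a heterozygous Neanderthal does count as "carrying the derived
allele" in clause 2; the relaxed reading (heterozygotes pass clause 1) is
available via `het_ancestral_ok = TRUE`. The Denisovan in clause 2 must be
homozygous ancestral under either reading.

Frequencies are compared with `>=` at the threshold, so 0.90 passes; a
0.50/0.50 tie fails the derived-major rule; the threshold must lie in
(0.5, 1], where monotonicity is guaranteed: raising it never adds variants,
and the stringent set is always a subset of the global-only set (both
property-tested).

## Contingency machinery

`tissue_composition_test()` uses the chi-square test of homogeneity from
`stats::chisq.test()` and computes **adjusted (Haberman) residuals**

r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - rowshare_i)(1 - colshare_j)),

flagging cells with |r| above the two-sided normal critical value at
alpha = 0.05. The residual form is a design choice (the analysis this
replicates reports only "residual analysis"); it equals the standardized
residuals `chisq.test()` reports, which the tests verify against the closed
form. When any expected cell falls below 5 the asymptotic p-value is
replaced by a Monte-Carlo p (10,000 table resamples), since the chi-square
approximation is unreliable there.

The duplicate tissue pairs (Cerebellum / Cerebellar Hemisphere and
Cortex / BA9 are re-sampled tissues) are retained as distinct columns, so
the table matches the per-tissue reporting convention of the source data.

The per-tissue discovery-count/sample-size relationship
(`sample_size_correlation()`) is summarized by a Spearman correlation and a
degree-2 polynomial least-squares fit with a +/-1 standard-error band;
tissues outside the band are reported as outliers. The degree and band are
package choices; the analysis being emulated states only a "polynomial
regression line fit" with a confidence band.

The region-specificity **random sampling test**
(`region_specific_sampling_test()`, default n = 100 resamples) is
deliberately conservative in design because the original procedure is not
fully specified: tissue labels of the clumped index variants are permuted
(sampling without replacement proportional to per-tissue totals), the
tissue-specific (unique-to-one-tissue) count vector is recomputed per
resample, and the chi-square distance to the resample mean serves as the
discrepancy statistic, with the resamples themselves as its null
reference. A plain asymptotic chi-square p on the observed-vs-mean table is
not calibrated; the permutation reference is, which the tests confirm with
a Kolmogorov-Smirnov uniformity check under exchangeable labels.

## Clumping

Clumping is the standard greedy Plink-style reduction: sort by nominal
eQTL p (ties broken by position for determinism), take the best unassigned
variant as index, absorb unassigned variants within the window whose r^2
with the index reaches the threshold, repeat. The default threshold is
**r^2 = 0.1** with a 250 kb window (the Plink default; no window is stated
in the analysis being replicated). Variants missing from the LD panel, or
monomorphic in it, survive as singleton clumps with a warning rather than
being dropped. The implementation is tested for exact equality against a
brute-force all-pairs oracle and for the partition, index-dominance and
threshold-monotonicity invariants. Clumping is applied **per tissue**
(matching the per-tissue reporting of tissue-specific counts); pooled mode
is available via `pooled = TRUE`.

## Sweep permutation test

The overlap unit is the variant position (a width-1 interval); windows are
0-based half-open (BED convention) and merged before counting so the test
is invariant under re-merging. Each permutation redraws all positions
uniformly over the genome, per chromosome proportional to length — the
query-set randomization used by regioneR-style analyses. The empirical p
uses the +1 correction, p = (1 + #{perm >= obs})/(N + 1), so it is floored
at 1/(N+1) and never zero. The **unclumped** variant set is used, because
clumping can move the index away from a sweep window and lose power.
Under the neutral generator (enrichment factor 1) the test's rejection rate
at alpha = 0.05 sits inside the exact binomial 95% interval over 200
simulated datasets, and with 10-fold enrichment the p-value hits the floor
(both checked in the acceptance tests with N = 200 permutations per run;
the pipeline default is N = 1,000).

Between-study comparisons use counts per megabase of merged window length
(to control for window-length differences), a paired two-sided Wilcoxon
signed-rank test across tissues, and a Kruskal-Wallis test followed by
Dunn pairwise z-tests (ties-corrected, Bonferroni-adjusted). The Dunn
statistics are computed in-package from the standard rank formulation.

## Directionality

"Down/up-regulating" is defined by the sign of the eQTL slope **after
orienting it to the focal allele's dosage** (slopes natively refer to ALT
dosage): derived allele for the main analysis, ancestral-major allele
(>= 90%) for the control. The pooled up/down counts are tested against
50/50 with a chi-square goodness-of-fit test; exact zero slopes are
excluded and counted. Per-tissue adjusted residuals on the up/down x
tissue table mirror the pooled-test-plus-per-tissue-commentary design; a
per-tissue pooled alternative is a straightforward variation the user can
run by subsetting. Negating every slope swaps the up/down counts and
leaves the statistic unchanged (tested exactly).

Tissue clustering uses per-tissue mean effect-size profiles over genes.
Genes are restricted to those observed in **every retained tissue**
(complete cases) rather than dropping missing entries pairwise: pairwise
deletion can violate the triangle inequality, and the computed distance
matrix is required to be a metric. Distances are Euclidean, linkage is
complete (both configurable; the emulated analysis names neither), and
the dendrogram is exported as Newick via `ape`.

## Mendelian randomization and colocalization

Instruments are the top eQTL hit per gene x tissue at p <= 5e-4, filtered
by presence in the derived-allele catalog but **not** restricted to the
high-frequency subset (pleiotropy and LD make an HF-only restriction
counter-productive for MR). Harmonization aligns the GWAS effect to the
exposure effect allele, flipping beta and EAF for swapped alleles,
dropping incompatible allele sets, and dropping palindromic variants (A/T,
C/G) with EAF in [0.42, 0.58] — a common convention for strand ambiguity.
The Wald ratio is beta_outcome / beta_exposure with the first-order
standard error |se_outcome / beta_exposure| and a two-sided normal p;
Bonferroni is applied over the family of all gene x trait tests in one
invocation. Simulation shows the nominal 95% intervals cover a simulated
causal ratio at >= 93% with strong instruments.

Colocalization uses per-variant Wakefield approximate Bayes factors,
log ABF = 0.5 (log(1 - r) + r z^2) with r = W/(W + V), V = se^2 and prior
effect standard deviation sqrt(W) = 0.15 per quantitative trait (the
established ABF default; the emulated analysis names no priors), combined
under the single-causal-variant hypotheses H0-H4 with priors p1 = p2 =
1e-4, p12 = 1e-5. Posteriors are normalized (sum to 1 within 1e-9),
single-variant regions leave H3 unidentifiable (warned), and PP4 is
non-decreasing in p12. Because the "shared signal" summary can be read as
PP4 alone or PP3+PP4, both are reported by the acceptance script's
scenario summaries.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is tested;
its defaults are fixed, not tuning knobs.

* **Haplotypes** use Markov template copying: each of `n_haplotypes`
  haplotypes copies one of 8 templates, switching templates between
  adjacent sites with probability 1 - exp(-switch_rate * distance)
  (default 5e-6 per bp). This produces clumpable LD blocks with
  distance-decaying r^2 at desk scale; it is *not* a coalescent and makes
  no claim about realistic allele-frequency spectra or recombination
  hotspots.
* **The catalog** builds each variant to a plan: a configurable fraction
  (default 0.2) is derived-HF by construction, and every other variant is
  built to fail exactly one named rule (low frequency, one metapopulation
  below 0.9, archaic condition, unresolvable ancestral allele, or
  all-archaic coverage failure), so the classifier's ground-truth
  concordance is a meaningful end-to-end check of every rule. Archaic
  coverage is negative-binomial (mean 40, size 12) with failures drawn on
  both tails so both coverage bounds are exercised. Metapopulation
  frequencies jitter around the global value by up to +/-0.04, bounded so
  only the designated rule can fail. The catalog's global allele frequency
  is the panel column frequency exactly.
* **eQTL tables** draw true effects per variant x tissue (probability
  0.15, slope sd 0.6, symmetric around zero so directionality is null by
  default), propagate marginal effects through panel LD within each gene
  (beta_marginal = R beta_true), add sampling noise scaled by
  1/sqrt(sample size) using plausible per-tissue sample sizes
  (`gtex_brain_samples()`), and flag significance with Benjamini-Hochberg
  at 0.05 per tissue. Discovery power therefore rises with sample size,
  reproducing the count/sample-size correlation; duplicate tissue pairs
  share correlated true effects.
* **Sweep windows** come as two sources (the second ~30% more and ~60%
  wider windows, so length normalization matters). With enrichment factor
  f, a fraction 1 - 1/f of windows is centered on derived-HF positions;
  f = 1 places windows uniformly, independent of variants, which is the
  calibration null.
* **GWAS summaries** simulate marginal z-scores through LD from per-gene
  causal variants chosen by scenario (H4 shared with the eQTL causal, H3
  distinct and in r^2 < 0.1, H0-H2 one or both null), with standard errors
  1/sqrt(2 n p (1-p)) at n = 30,000 and randomized allele orientation so
  harmonization is always exercised. `gen_coloc_region()` is the
  region-level counterpart used for colocalization scenario tests.

What passing tests on these data do **not** show: robustness to realistic
demographic structure, genotyping error, overlapping genes, multi-allelic
sites or indels (out of scope), allele-frequency-dependent eQTL discovery
bias, or multi-signal colocalization. The generator is a correctness
harness, not a population-genetic simulator.

## Problem sizes and determinism

Default test-scale sizes are chosen to exercise every code path at desk
scale: 2,000 variants x 200 haplotypes for end-to-end runs, 5,000-variant
catalogs for classifier concordance, 100-variant instances for clumping
oracle equivalence, N = 200 permutations inside calibration loops (the
pipeline default is 1,000), and 50 regions per colocalization scenario.
Every generator call and every stochastic test derives an explicit
sub-seed from one master seed; identical configurations are byte-identical
on rerun, which `run_pipeline()` verifies by hashing every artifact into
its manifest.

## Known limitations

* The classifier consumes a pre-computed catalog dialect (frequencies,
  archaic genotypes and coverages, ancestral calls); it does not recompute
  frequencies from raw genotypes, lift over genome builds, or handle
  indels/multi-allelic sites.
* The LD panel must be phased haplotypes coded 0/1; covariance-shrinkage
  LD estimation is not implemented.
* Single-instrument Wald MR only; IVW/Egger/weighted-median estimators and
  SuSiE-style multi-signal colocalization are out of scope.
* The permutation test randomizes the query positions, not the windows;
  window randomization (circular shifts) is a possible extension and not
  implemented.
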