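---
title: "Haplotype-dose methylation analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-dose methylation analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapmeth)
```

# The scientific problem

A multi-SNP haplotype — here the eight-SNP panel on chromosome 10q24 tagging
the efficient arsenic-metabolism allele around *AS3MT* — can act as a
*cis*-regulatory dose: each individual carries 0, 1 or 2 copies, and the
question is how strongly that copy number predicts DNA methylation at
array CpG probes across the region, and downstream, gene expression.
`hapmeth` implements that analysis end to end:

1. **Haplotype dosage** (`em_haplotype_frequencies`, `count_copies`):
   haplotype frequencies are estimated from unphased genotypes by
   expectation-maximization (the Excoffier–Slatkin gene-counting scheme),
   and each individual's dosage is the posterior mean copy number of the
   target haplotype given their genotypes and those frequencies.
2. **Methylation preprocessing** (`impute_knn`, `screen_components`,
   `residualize_batch`): beta values (methylated fraction, 0–1) are
   completed by k-nearest-probe imputation (k = 10), screened by SVD for
   technical components, and — in a cohort where a component is associated
   with the analysis plate — residualized probe-by-probe on the plate
   indicator.
3. **Allele-dose scan** (`dose_scan`, `bh_fdr`, `fit_dose_models`,
   `kw_screen`): per probe, the Pearson correlation of methylation with
   dosage treated as a continuous 0–2 variable, with two-sided t-based
   p-values and Benjamini–Hochberg FDR computed against a fixed total of
   450,000 comparisons; top probes get univariable
   (`methylation = α + β₁·copies`) and multivariable (adding ln urinary
   arsenic, age, and a cohort-specific binary covariate) OLS models, and
   covariates are screened across copy groups by Kruskal–Wallis.
4. **Sequence context** (`classify_allele_cpg_effect`, `find_cpg_islands`,
   `classify_relation`, `flag_probe_snps`): whether a panel allele creates
   or removes a CpG dinucleotide, a CpGPlot-style sliding-window island
   detector, island/shore/shelf classification, and flags for probes whose
   annotated SNP sits within 10 bp of the interrogated CpG (base-extension
   interference risk).
5. **Regional co-methylation** (`window_profile`, `permutation_null`):
   in sliding windows of 20 consecutive genes, the fraction of
   *between-gene* CpG pairs with |r| > 0.5, compared against a null band
   from permuting the gene order.
6. **Expression integration** (`spearman_pairs`, `expression_models`,
   `relative_expression`): Spearman correlations of methylation or dosage
   with expression assays, OLS models adjusted for ln urinary arsenic and
   RNA integrity (RIN), and scaling of expression relative to the median
   of 2-copy carriers.
7. **Exposure utilities** (`adjust_specific_gravity`,
   `metabolite_percentages`, `glm_metabolites`,
   `het_cpg_signal_ratio`): urinary dilution correction,
   %iAs/%MMA/%DMA summaries, the %DMA-per-copy dose model, and the
   expected half-signal of a heterozygous (CA vs CC) polymorphic CpG.

# Statistical models and assumptions

**Dosage as a continuous predictor.** The scan codes copies 0–2 as a
number, which assumes an additive (allele-dose) effect on the beta scale.
A categorical coding is available in the modelling layer for sensitivity
checks, but additivity is the primary model throughout.

**Expected versus hard-called dosage.** Downstream analyses use the
posterior-mean copy number by default: it is continuous like the 0–2
coding, and it propagates phase uncertainty instead of discarding it.
Hard calls (posterior modes) are kept for group-wise summaries
(`summarize_cohort`) and the Kruskal–Wallis screens. When the EM
likelihood has symmetric tied maxima — the classic single
double-heterozygote, where the two phase couplings are indistinguishable —
the posterior is averaged over the tied solutions, so an unresolvable
individual gets the symmetric expected dosage (e.g. 0.5) rather than an
arbitrary pick. The reported maximum log-likelihood is still that of a
single maximum, so it remains comparable to exhaustive maximization.

**FDR against a fixed m = 450,000.** `bh_fdr` deliberately lets the
step-up denominator exceed the number of p-values supplied: an array-wide
scan adjusts for the full 450,000 comparisons even if fewer probes
survive to analysis. This is conservative relative to the standard
`m = #tests` convention, which is available by passing
`m = length(p_values)` (where it coincides exactly with
`p.adjust(..., "BH")`).

**Pearson p-values.** Two-sided, from the t-distribution on `n − 2`
degrees of freedom over pairwise-complete samples. Degrees of freedom
consumed by a prior plate residualization are not subtracted; with two
plates this is a one-degree difference at n ≈ 100 and is noted here as a
known approximation.

**Regional statistic.** Within-gene probe pairs are excluded because
co-methylation of probes in the same gene is expected and uninformative
about regional coordination. The null permutes *gene order* (probes travel
with their gene), preserving exactly the within-gene structure the
statistic excludes. The band pools window fractions across permutations —
a single permuted profile is one draw from that distribution; pooling is
the stabilized generalization. The threshold is strict (`|r| > 0.5`).

**Specific-gravity adjustment.** The standard urinary dilution correction
`u_as · (sg_ref − 1)/(sg − 1)`, with cohort references 1.020 g/mL
(Andean adults) and 1.012 g/mL (Bangladeshi cohort). It is undefined at
sg ≤ 1 and monotone decreasing in measured specific gravity.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `knn_k` | 10 | probes | standard array imputation choice |
| `fdr_m` | 450,000 | comparisons | array-wide total; override with `#tests` for the standard BH |
| `fdr_alpha` | 0.05 | — | conventional FDR significance |
| `window_genes` | 20 | genes | regional window size |
| `corr_threshold` | 0.5 | \|r\| | strong-pair cut-off, strict inequality |
| `n_permutations` | 100 | — | enough for a stable 97.5th percentile of the pooled null |
| component-screen `alpha` | 0.01 | — | the flagging threshold is not fixed by convention; 0.01 keeps false plate flags rare while a true two-plate shift is overwhelming at any reasonable n |
| island `window`/`min_gc`/`min_obs_exp`/`min_length` | 200 bp / 0.5 / 0.6 / 200 bp | | CpGPlot-style defaults; all configurable |
| shore/shelf bands | 2 kb / 2–4 kb | bp | standard 450K annotation convention |
| SNP flag distance | 10 | bp | base-extension interference is strongest under 10 bp |

# The synthetic cohort generator

`sim_config`/`generate_cohort`/`generate_methylation`/`generate_expression`
emulate the statistical structure the analysis assumes, so every stage is
testable without subject-level data:

* Two cohort presets: an Andean adult cohort (n = 94, haplotype frequency
  0.69, one analysis plate, coca-use covariate) and a cord-blood cohort
  (n = 127, frequency 0.17, two plates with a +0.02 beta shift on the
  second, child-sex covariate).
* Haplotypes are drawn independently per chromosome (Hardy–Weinberg);
  the target haplotype carries the target allele at every panel SNP,
  while non-target haplotypes draw each SNP independently with a 10%
  chance of the target allele — imperfect off-haplotype linkage that
  makes the EM phasing genuinely non-trivial.
* Methylation is `clamp[0,1](baseline + effect·copies + plate shift +
  N(0, 0.05²))`, with the default signal set being twelve probes carrying
  the observed per-copy slopes (magnitudes 0.021–0.33) at their observed
  mean beta levels, on top of null probes with baselines uniform on
  [0.1, 0.9]. Noise SD 0.05 is a free parameter: published per-genotype
  beta ranges constrain spreads to roughly 0.1–0.5 but report no
  within-genotype variance, and 0.05 keeps those ranges attainable.
* 0.1% of beta cells are blanked at random (never a whole probe).
* Expression is coupled to named methylation probes by a Gaussian copula
  with latent correlation `2·sin(π·ρ/6)`, so the *Spearman* correlation is
  ρ in expectation; uncoupled assays are independent log-normals.
* Probes are assigned sequentially to 200 ordered genes of 3–12 probes
  each on one simulated chromosome.
* Covariates: log-normal urinary arsenic around the cohort medians
  (188 vs 68 µg/L), specific gravity near the cohort reference, age, BMI,
  RIN, and urinary metabolite fractions whose %DMA median rises by 5.2
  percentage points per haplotype copy (matching medians of roughly
  73/76/83% across 0/1/2 copies).

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: cell-type composition and its
confounding, probe-specific noise heteroscedasticity, realistic
genome-wide CpG density and island structure, LD decay with distance,
raw-intensity artefacts, and any non-additive (dominance) genetic effect.

## A note on detectability of the weakest effects

Under the generator's conditions (n = 94, dosage SD ≈ 0.65 at frequency
0.69, noise SD 0.05), a per-copy slope β implies a population correlation
`r = β·0.65 / sqrt(β²·0.65² + 0.05²)`. For the largest slopes in the
default set (|β| ≥ 0.05) this gives r ≥ 0.55 and p-values far below the
array-wide BH threshold, but for the smallest (|β| = 0.021–0.042) the
implied r of 0.26–0.48 yields expected p-values between 10⁻² and 10⁻⁶ —
above the ≈1.3×10⁻⁶ needed at rank 12 with m = 450,000. Observed
correlations of ~0.5 for slopes as small as 0.021 are only consistent
with residual SDs near 0.025; at the package's default noise the weakest
probes are genuinely undetectable at array-wide FDR, which the
acceptance suite reports rather than hides. Slope *estimates* remain
unbiased at every effect size.

# Numerical choices

* **KNN imputation** operates probe-wise (rows as neighbours), the array
  convention; distances are Euclidean over co-observed samples rescaled
  by the fraction co-observed, ties broken by probe order for
  determinism, and donors must be observed at the target sample. If
  fewer than k donors exist the available ones are used with a warning.
* **Residualization** defaults to `recentre = TRUE` (residuals plus the
  per-probe grand mean) to stay near the beta scale; `recentre = FALSE`
  gives the literal residuals. Adjusted matrices are exempt from the
  [0,1] invariant and are marked as such on disk.
* **Spearman p-values** use the t-approximation for n > 7 and exhaustive
  permutation enumeration for n ≤ 7, where the approximation is poorest
  and full enumeration (≤ 5040 permutations) is cheap and deterministic.
* **EM initialization**: uniform over data-compatible haplotypes plus
  seeded jitter of 10⁻³, ten restarts, best likelihood kept; missing
  genotypes are summed over in the E-step rather than dropping the
  individual. For panels of ≤ 12 SNPs the enumeration of compatible
  phase pairs is exact.
* **Island detection** evaluates every 1-bp-step window, merges
  overlapping passing windows, and discards merged runs shorter than the
  minimum length; observed/expected is `count(CG)·len/(count(C)·count(G))`
  per window. CG is its own reverse complement, so one strand suffices.
* **Coordinates** are 1-based inclusive in all files and converted to
  0-based half-open only when writing BED.
* **Text precision**: matrices are written with 6 decimals; values
  round-trip bit-exactly at that precision.

# Test and verification sizes

The test suite verifies each operation against independent oracles
(closed-form least squares, exhaustive likelihood maximization,
brute-force window evaluation, permutation nulls) on small fixtures, and
runs the calibration studies at the cohort scale the package targets:
100 replicate null scans of 10,000 probes × 94 samples for type-I error
and FDR control, 50 replicate effect-recovery scans of 5,012 probes, and
regional profiles over 200 genes with 100 permutations. These sizes give
Monte-Carlo errors comfortably below the asserted tolerances.

# Known limitations

* No cell-type deconvolution or empirical-Bayes batch correction; the
  plate fix is exact mean-removal per probe.
* The EM phasing is recombination-free and intended for short panels;
  it is not a reference-panel imputation method.
* Expression preprocessing (background correction, normalization) is out
  of scope; expression matrices are consumed as provided.
* The island detector's boundaries are window-resolution objects: a
  GC-rich block is reported with the full span of every passing window,
  as in the tool it follows, so lengths depend on the window size.
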