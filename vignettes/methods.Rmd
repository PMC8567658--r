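---
title: "Methods: multi-cohort EWAS meta-analysis of sex-differential muscle methylation"
author: "ewasmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort EWAS meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `ewasmeta`: the models,
the defaults and why they are set where they are, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Scope and data model

The pipeline consumes **normalized** beta-value matrices (probes × samples,
values in [0, 1]) with a sample sheet per cohort; raw IDAT preprocessing,
probe-type (BMIQ-style) normalization and batch correction (ComBat-style)
are out of scope — batch enters as a model covariate instead. Probe
filtering removes the union of four mask categories (detection failures,
sex-chromosome probes, cross-hybridizing probes, SNP-associated probes);
cross-hybridizing probes matter particularly here because probes that
cross-react with the X chromosome create spurious autosomal sex signal.

**Modeling scale.** Statistics are computed on beta values directly, so
effect sizes are mean methylation differences in proportion units (×100
gives the percentage scale used in reporting). An M-value (logit2) mode is
available through `beta_to_m()` for users who prefer variance-stabilized
fits, but it is not the default: beta-scale fits keep the effect in the
units the results are reported in. The logit transform clips beta to
[1e−6, 1 − 1e−6] before taking logs.

**Coordinates.** Annotation positions are 1-based points. All interval
inputs (chromatin states, TFBS) are BED dialect, 0-based half-open: a CpG at
1-based position *p* overlaps [s, e) iff s ≤ p − 1 < e. This is enforced in
one place (`bed_to_granges()` shifts starts by +1 into the 1-based closed
convention GenomicRanges uses) and tested at the boundary.

## 2. Per-cohort EWAS

Each cohort is fitted per CpG with ordinary least squares, `DNAm ~ sex +
covariates`, sex coded F = 0 / M = 1 so a positive coefficient means
hypermethylated in males. Interaction designs (e.g. `sex:timepoint`) report
the sex main effect at the reference level of the interacting factor.
Variance moderation uses the standard empirical-Bayes squeeze (limma):
per-probe variances are shrunk toward a prior estimated by matching moments
of the log sample variances to a scaled-F distribution, and moderated t
statistics gain the prior degrees of freedom.

**Repeated measures** are collapsed to within-subject-by-condition means
before fitting. The reference approach is a consensus-correlation mixed
model; averaging is a deliberate simplification that leaves the sex
contrast unbiased (sex is constant within subject) at some loss of
efficiency, and avoids re-implementing REML consensus correlation. The one
thing averaging cannot represent — subject-level variance components
propagating into the standard error — is partly recovered because the
averaged residual variance still reflects between-subject spread.

**Degenerate probes.** Zero-variance probes get `se = NA`, are excluded
from hyperparameter estimation and carry p = 1 throughout. Missing numeric
covariates are imputed by the within-sex mean (the reference analysis used
chained-equation imputation for 3 of 369 individuals; at that rate the
difference is negligible and the simple rule is deterministic).

**Cohort characteristics** are tested with Welch's t for continuous
covariates. For the 2×2 sex-by-category comparison the package uses
Fisher's exact test even though the source table footnote labels every row
"Welch two-sample t-test" — a t-test is not defined for a 2×2 count table,
and the printed p-value for the reconstructed table (93,22;109,50) is in
fact reproduced exactly by the two-sided exact test (p = 0.026).

## 3. Empirical-null calibration

EWAS statistics are biased and inflated by unmeasured technical and
biological structure. Following the empirical-null idea, each cohort's
moderated t vector is modeled as a three-component Gaussian mixture

  f(z) = p₀ N(μ, σ²) + p₊ N(μ₊, s₊²) + p₋ N(μ₋, s₋²),

whose central component is the null: μ is the bias, σ the inflation.
The reference implementation samples this model by Gibbs; `ewasmeta` fits
it by EM with deterministic initialization (μ = median, σ = 1.4826 × raw
MAD, p₀ = 0.9, signal components seeded at μ ± 3σ) so that identical inputs
give identical estimates in tests. The estimand is identical.

Two constraints make the decomposition identifiable in practice:
μ₋ < μ < μ₊, and the signal means are kept at least 2.5 null standard
deviations from the null mean. Without the separation constraint the signal
components drift inward and absorb ordinary null tail mass, biasing σ low
by ~3% on a pure standard-normal input; with it, a 50k standard-normal
vector is recovered with σ within ±0.01 and a planted (μ = 0.2, σ = 1.5,
5% signal at z ≈ 4) configuration within ±0.05/±0.02 (both checked in the
test suite). Convergence is declared when the log-likelihood changes by
less than 1e−6 per score; on non-convergence the (median, MAD) estimator is
returned with a warning.

Calibration rescales z′ = (z − μ)/σ, p′ = 2Φ(−|z′|), and reconstructs the
standard error as se′ = |effect/z′| so that downstream inverse-variance
weights operate on calibrated units while effects stay in Δβ. This is a
declared convention: the alternative (scaling se directly) differs only
when the bias μ is large relative to the score.

## 4. Meta-analysis and DMPs

Fixed-effects inverse-variance weighting combines the calibrated cohorts
per CpG, for CpGs present in ≥ 2 cohorts (the 27K-era cohort lacks most
EPIC probes, which is why the membership rule exists). Cochran's Q is
referred to χ²(k−1) and I² = max(0, (Q−(k−1))/Q)·100; probes with I² > 50%
are flagged as heterogeneous but kept — the threshold is reported, not used
for exclusion. DMPs are BH FDR < 0.005, with ties broken by probe id for
reproducibility. PCA variance-explained-by-sex takes the first five
components of the centred, scaled sample×DMP matrix, picks the one with the
largest |point-biserial correlation| with sex (a deterministic stand-in for
"the component that visually separates the sexes") and reports the adjusted
R² of `PC ~ sex`.

## 5. DMRs

Squared calibrated z are treated as χ²₁ and smoothed along each chromosome
with a Gaussian kernel, σ = λ/C with λ = 1000 bp and C = 2 (the standard
defaults for this family of region callers), truncated at 3σ so the scan is
linear time. With normalized weights w̃ the smoothed statistic
Y = Σ w̃ z² is referred to its Satterthwaite two-moment null
Y ~ c·χ²(ν), c = Σ w̃², ν = 1/c. Isolated CpGs fall back to their own χ²₁
tail. Significant CpGs (BH < 0.005 on smoothed p) are grouped into maximal
runs with gaps ≤ λ; runs of ≥ 2 CpGs become regions carrying three
member-combination statistics — Stouffer (signed meta z, z̄ = Σz/√k),
Fisher (−2Σlog p on χ²(2k)) and the harmonic mean of member FDRs — all of
which must be < 0.005 for significance. The Stouffer and Fisher quantities
are reported on the p scale (the reference tool's output leaves the scale
ambiguous; the column here is labelled explicitly).

**A known approximation limit.** The two-moment null matches mean and
variance but not skewness, so the *body* of the smoothed null p
distribution deviates detectably from uniform at 10k probes (a KS test
picks it up). The *tails* — which are all that BH region calling consumes —
hold their nominal levels (≈0.049 at 0.05, ≈0.005 at 0.005 over repeated
null simulations), and a global-null pipeline produces zero significant
regions in ≥ 24 of 25 seeded replicates. The acceptance checks are
therefore planted-region recovery and null calibration, not bitwise parity
with any particular release of the reference tool, whose internal variance
model is version-dependent.

## 6. Enrichment

Genomic context uses r×c chi-square tests of homogeneity without continuity
correction, with standardized Pearson residuals; cells with |residual| > 4
are flagged as "greater contribution" (the threshold behind the original
figure's asterisks is unstated; 4 is configurable). Probes annotated to two
differing chromatin states are removed, as in the source analysis. The
sex-discordant-state association is a 2×2 with a cross-product odds ratio
oriented as (non-DMP odds)/(DMP odds) — matching the published OR = 0.76,
whose reciprocal 1.3 is the DMP enrichment factor — with a Woolf logit CI
(Haldane–Anscombe 0.5 only when a cell is empty) and Fisher's exact p.

TFBS enrichment builds, per TF dataset, the 2×2 of DMP status × in-TFBS
(half-open overlap) over the tested-CpG background and reports one-sided
Fisher p-values **unadjusted**, ranked by −log10 p: TFBS datasets overlap
heavily, so FDR exchangeability assumptions fail.

Gene-set testing corrects the well-known probe-count bias: a gene covered
by many probes is more likely to contain a significant probe by chance.
A gene is significant if ≥ 1 of its probes is; its bias weight is its probe
count; probes annotated to several genes contribute to each. The default
correction is Monte-Carlo: 10,000 sequential weighted draws of gene sets of
the observed size (this sampling scheme *is* the Wallenius noncentral
hypergeometric), p = (1 + #{overlap ≥ observed})/(n + 1). The closed-form
mode approximates the Wallenius tail by its standard mean/variance normal
approximation with odds equal to the ratio of mean probe counts inside vs
outside the set; the two agree within Monte-Carlo error on the fixtures in
the test suite. The (1+b)/(1+n) estimator is used for every resampling p in
the package — it is the standard conservative choice that never returns 0.

## 7. Methylation–expression integration

DMR-annotated genes (DMGs) are intersected with differential-expression
lists; enrichment of DEGs among DMGs reuses the bias-corrected gene-set
test with the DEG list as the set. Quadrant analysis pairs each
promoter/enhancer DMR (TssA/TssAFlnk → promoter, Enh/EnhG → enhancer) with
its gene's expression effect and reports the inverse-sign fraction per
class; the permutation null shuffles methylation effects **within region
class** (the source description leaves global vs within-class open;
within-class is the stricter null because it preserves class composition).
A gene with several DMRs in one class contributes one pair per DMR.

qPCR validation follows 2^−ΔΔCt: triplicates averaged (triplicates with
SD > 1 Ct discarded), ΔCt against the mean Ct of the two most stable
housekeepers (equivalent to geometric-mean normalization of expression),
Welch t on ΔCt. Housekeeper stability is ranked by Ct variance across
samples — a deliberate, simpler stand-in for multi-algorithm stability
aggregation.

## 8. Fibre-type mediation and hormones

Fibre-type proportion is a *downstream effect* of sex, not a confounder, so
adding it to the sex model would distort the sex coefficient. Instead the
cohorts are split by sex, `DNAm ~ type1_ratio + covariates` is fitted
within each single-sex group (the code refuses `sex` as a regressor), each
group is calibrated against its own empirical null, the groups are combined
with the same IVW machinery, and FDR is adjusted **within the sex-DMP set**
— by the step-up construction this restriction can only gain discoveries on
the subset relative to genome-wide adjustment (verified as a property
test). Note that empirical-null calibration mildly attenuates weak,
moderately common signal (the mixture cannot perfectly separate a 15%
signal fraction at per-group z ≈ 2), so the recovered mediated share sits
one to a few points below the planted share at the test's problem size;
the acceptance band (±5 points around the planted 15%) absorbs this.

Type-I proportion from RNA-seq is MYH7/(MYH7+MYH2+MYH1). Whether
proportions differ by sex is tested with a beta regression written for this
package: Beta(μφ, (1−μ)φ) likelihood, logit mean link, constant log φ, BFGS
with analytic gradients from a logit-OLS start, Wald tests from the inverse
observed information, Smithson–Verkuilen compression for boundary values.
Parameter recovery and ~95% Wald coverage are verified over 200 simulated
replicates.

Hormone scans run within one sex (levels are collinear with sex),
`DNAm ~ hormone + covariates`, BH-adjusted genome-wide and within the
sex-DMP subset; correlated ovarian hormones can be combined into their
first two log-scale principal components first. The free androgen index is
T×100/SHBG. Free testosterone solves the full mass-action equilibrium of
testosterone against SHBG (K = 1.0×10⁹ L/mol) and albumin
(K = 3.6×10⁴ L/mol, default 4.3 g/dL), with ligand depletion of both
binders — a cubic in the free concentration with a unique positive root,
cross-checked against fixed-point iteration to 1e−10. The constants are
standard literature values (the source cites the calculation without
printing them) and are configurable.

## 9. The synthetic generator

`simulate_cohorts()` emulates the statistical structure the analysis
assumes, not array chemistry. Signal is built on the logit2 scale and
mapped through the inverse logit, so beta values respect [0, 1] and
effects attenuate toward the boundaries as on real arrays; planted effects
are sized to achieve their target Δβ at baseline 0.5 (recovery tests
compare on the Δβ scale). Defaults, chosen once to mirror the study
conditions: 10% of probes carry a sex effect; 94% of sex effects are
hypomethylated in males; mean |Δβ| 0.028 (hyper) / 0.035 (hypo); female
type-I fibre proportion Beta(mean 0.52, precision 30) vs male
Beta(0.42, 30) — the source states the direction but no values, so these
create a clearly detectable mediator without being extreme; 15.5% of sex
CpGs also carry a fibre effect; one of three cohorts is typed on 1/20 of
the probes (27K-style) to exercise the ≥ 2-cohort rule. Probes sit in
blocks (8 probes, 150 bp apart, block-level baselines and a block×sample
random effect) so neighbours are correlated and distant probes are not —
the structure DMR calling needs. Batch offsets are per probe×batch;
subject random intercepts appear when repeated measures are generated.

What it does **not** emulate: type I/II probe chemistry, meQTL/CNV
structure, cell-type heterogeneity beyond the single fibre axis, and
non-Gaussian residual tails. Passing recovery tests therefore demonstrate
the pipeline's statistical correctness under its own assumptions, not
robustness to array artefacts — which is exactly what a reference pipeline
should be tested for at desk scale.

Default cohort sizes (80/64/22) echo the real cohorts' relative sizes at
desk scale. The test suite and acceptance script use: 25 null replicates of
20k probes × 3 cohorts of 50; one recovery run of 20k probes × 3 cohorts of
200 (|Δβ| = 0.15 at 10% of probes); a 2k-probe two-cohort run with a single
planted 8-CpG region (|Δβ| = 0.2); a 20k-probe two-cohort (150 samples
each) mediation run with fibre effects of 0.30 Δβ per unit type-I
proportion (the top of the reported effect-size range); and 200
beta-regression replicates at n = 200. These sizes were chosen so each
check exercises the intended asymptotics while the whole suite stays
desk-sized.

## 10. Known limitations

- Averaging repeated measures discards within-subject efficiency; a
  consensus-correlation or mixed-model mode would recover it.
- The empirical-null EM targets the same estimand as the Gibbs reference
  but will differ in finite samples; its separation constraint (2.5σ) is a
  fixed identifiability choice, appropriate when true signal is either
  sparse or strong, and attenuates weak dense signal.
- The Satterthwaite region null is two-moment; its p-value body is slightly
  miscalibrated even though its tails are accurate.
- The Wallenius closed form is a normal approximation; use the Monte-Carlo
  mode when the p-value matters near a decision boundary.
- Random-effects meta-analysis and Stouffer (sample-size-weighted) modes
  are deliberately absent; the fixed-effect model assumes one shared true
  effect per CpG.
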