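# ewasmeta

Meta-analysis of sex-differential DNA methylation in human skeletal muscle —
an R implementation of the full inference chain from per-cohort beta-value
matrices to differentially methylated positions (DMPs), regions (DMRs) and
their biological interpretation.

## The problem

Male and female skeletal muscle differ in fibre-type composition, substrate
metabolism and gene expression. Epigenome-wide association studies (EWAS) of
sex ask, for every CpG site on a methylation array, whether its beta value
(methylated fraction, in [0, 1]) differs between males and females on the
autosomes. Single cohorts are confounded by batch, platform and unmeasured
technical structure, so the robust design is a multi-cohort meta-analysis
with explicit calibration of each cohort's test statistics. `ewasmeta`
provides that pipeline for analysts working with normalized array matrices
(EPIC, 450K or 27K style), plus the downstream analyses that turn a DMP list
into biology: genomic-context enrichment, TFBS enrichment, bias-corrected
gene-set testing, methylation–expression integration, and mediation analyses
for fibre-type proportion and circulating hormones.

## The model

For each cohort *c* and CpG *j*, an ordinary least-squares fit on beta values

&nbsp;&nbsp;&nbsp;&nbsp;DNAm<sub>j</sub> ~ sex + covariates<sub>c</sub>

with empirical-Bayes variance moderation (limma) gives an effect
Δβ<sub>jc</sub> (M − F), a standard error and a moderated t. Each cohort's
score vector is then calibrated against its **empirical null**: a
three-component Gaussian mixture
p₀N(μ,σ²) + p₊N(μ₊,s₊²) + p₋N(μ₋,s₋²) fitted by constrained EM, whose null
component absorbs bias (μ) and inflation (σ) from unmeasured confounding;
calibrated scores are z′ = (z − μ)/σ. Cohorts are combined per CpG by
fixed-effects inverse-variance weighting,

&nbsp;&nbsp;&nbsp;&nbsp;w<sub>c</sub> = 1/se<sub>c</sub>², &nbsp;
β̂ = Σw<sub>c</sub>β<sub>c</sub>/Σw<sub>c</sub>, &nbsp;
se = (Σw<sub>c</sub>)<sup>−1/2</sup>,

with Cochran's Q and I² for heterogeneity, restricted to CpGs present in at
least two cohorts. DMPs are called at Benjamini–Hochberg FDR < 0.005. DMRs
come from a kernel smoother: squared calibrated z treated as χ²₁, smoothed
with a Gaussian kernel (σ = λ/C, defaults 1000 bp/2), referred to a
Satterthwaite moment-matched null, BH-adjusted, and grouped into runs of
significant CpGs ≤ λ apart; a region is significant when its Stouffer,
Fisher and harmonic-mean-FDR statistics are all < 0.005.

A synthetic multi-cohort generator (`simulate_cohorts()`) with known ground
truth — predominantly male-hypomethylated sex effects, fibre-type-mediated
CpGs, batch and block structure, a 27K-style small cohort — makes every
stage testable without access data.

## Worked example

```r
library(ewasmeta)

cfg <- sim_config(n_probes = 20000, n_samples = c(80, 64, 22),
                  frac_sex_cpgs = 0.10, seed = 7)
sim <- simulate_cohorts(cfg)
res <- run_sex_meta(sim$cohorts, sim$annotation)

attr(res$meta, "summary")
#> $n_dmp
#> [1] 122
#> $n_tested
#> [1] 20000
#> $frac_hyper
#> [1] 0.03278689
#> $frac_hypo
#> [1] 0.9672131

sum(res$dmrs$significant)
#> [1] 54

res$nulls[[1]]
#> <null_estimate> bias mu = -0.0741, inflation sigma = 1.0330, p0 = 0.966, lambda_gc = 1.167 (EM converged, 29 iter)
```

Ten percent of probes carry a planted sex effect, but at the generator's
realistic effect sizes (mean |Δβ| ≈ 3%) and these cohort sizes the pipeline
calls only the strongest 122 CpGs at FDR < 0.005 — multi-cohort EWAS at
small n detects the tail of the effect distribution, not all of it. Around
97% of the called DMPs are hypomethylated in males, reflecting the planted
direction mix (94% hypo), and 54 significant regions are formed. The
per-cohort empirical null sits near (0, 1): the genomic inflation visible in
`lambda_gc` comes from true signal, which the mixture's signal components
absorb rather than the null.

Downstream, `sex_state_or()` tests whether DMPs concentrate in chromatin
states that differ between male and female reference muscle,
`gene_set_test()` runs gene-set enrichment corrected for per-gene probe
counts, `quadrant_concordance()` tests inverse methylation–expression
coupling at promoters/enhancers with a permutation null, and
`stratified_fibre_meta()` asks which sex-associated CpGs are mediated by
fibre-type proportion using a sex-stratified meta-analysis (fibre proportion
is a downstream effect of sex, so it cannot be a covariate in the sex
model).

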