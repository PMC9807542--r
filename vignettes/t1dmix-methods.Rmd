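---
title: "Methods: group-level mixture deconvolution of autoantibody-negative type 1 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-level mixture deconvolution of autoantibody-negative type 1 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dmix)
```

## The scientific problem

In clinician-diagnosed type 1 diabetes, islet autoantibody positivity at
diagnosis is around 90% in children but only around 80% in adults. Three
explanations compete for the antibody-negative adult excess: unmeasured
autoantibodies, a discrete low-genetic-risk form of autoimmune diabetes, or
inadvertent inclusion of non-autoimmune diabetes (mostly atypical type 2,
rarely monogenic). The type 1 diabetes genetic risk score (T1DGRS) separates
these hypotheses at the group level: if antibody-negative adults were mostly
true type 1 with false-negative serology, their mean score should match
antibody-positive adults; if they were a mixture containing non-autoimmune
diabetes, the mean should sit between the type 1 and type 2 reference means —
which is what is observed in adults but not in children.

## The estimator and its assumptions

With reference means $\mu_{pos}$ (antibody-positive cases) and $\mu_{ctrl}$
(type 2 controls) and mixed-group mean $m$,

$$\hat p_{T1D} = \frac{m - \mu_{ctrl}}{\mu_{pos} - \mu_{ctrl}},
\qquad \hat p_{NA} = 1 - \hat p_{T1D}.$$

Assumptions, and how the package treats them:

* **Two components.** The antibody-negative group is exactly a mixture of
  populations distributed like the two references. Monogenic diabetes (whose
  mean score is lower still) is folded into the non-autoimmune component, not
  modelled as a third component.
* **Reference validity.** Antibody-positive cases represent type 1 diabetes;
  a triple-antibody-positive reference is available as a sensitivity analysis
  (`sensitivity_reference()`) to guard against false-positive serology.
* **Means only.** The estimator is exactly linear-invertible: for an exact
  mixture mean it recovers the weight to machine precision, and it is
  invariant to affine transformations of the score, so the score's
  normalization convention is irrelevant to all group-level results. Both
  properties are asserted in the test suite.
* **No individual classification.** Only group proportions are estimated; a
  low score does not exclude type 1 diabetes in an individual.

Estimates pushed outside $[0,1]$ by sampling noise are clamped and flagged
(`clamped = TRUE`, with a warning) — never silently truncated. The
denominator guard is $|\mu_{pos}-\mu_{ctrl}| > 10^{-6}$ on the normalized
score scale; below that the references are declared indistinguishable and the
fit errors.

## Confidence intervals and rounding

The default interval on $\hat p_{NA}$ is a **Wald binomial** interval
$\hat p \pm z\sqrt{\hat p(1-\hat p)/n}$ with $n$ the mixed group's size.
This treats the deconvolution estimate as if it were an observed proportion
of $n$ individuals; it is the recipe that reproduces the published intervals
for this estimator (61–73% on the group, 11–15% of all adults, 91–94% on the
adjusted prevalence), which pins down the convention. $z$ is fixed at 1.96
for the 95% level, matching printed tables; other levels use the exact
normal quantile. A percentile bootstrap (resampling all three groups and
re-estimating, default 2000 replicates, seeded) is provided as an
alternative for raw-score input; degenerate resamples are dropped and
counted.

Counts are proportions times $n$ **rounded half away from zero** (base R's
`round()` is round-half-to-even, which does not match reported counts), and
display percentages use the same rule. One consequence worth knowing: from
the rounded published means (0.243/0.271/0.229) the estimate is exactly 2/3,
giving counts 145/218 and an adjusted prevalence of 894/967 = 92.4%; the
published counts 147/218 and 894/965 = 92.6% derive from the unrounded data
means (proportion ≈ 0.672). Both print as 67%, and the package reports
whichever inputs it is given at full precision.

## The score engine

`compute_grs()` decomposes the score into a non-HLA component (dosage-
weighted sum over variants with `is_hla = FALSE`), and an HLA component: a
genotype-level lookup for listed haplotype pairs (the DR3-DQ2/DR4-DQ8
compound heterozygote carries a synergistic weight that an additive model
misses), additive per-copy weights otherwise, plus any `is_hla` tag
variants. Weights are configuration, not constants: published weight sets
are tied to their derivation cohorts and licensing, so the package ships a
**synthetic** 30-variant table (`weights-synthetic-30.tsv`) and synthetic
HLA weights that preserve the qualitative structure. The normalized score
divides raw scores by twice the summed variant weights plus the largest
genotype weight in the HLA table; with non-negative weights this maps all
scores into $[0,1]$. For that reason the shipped synthetic table encodes the
protective DR15-DQ6 haplotype as weight 0 rather than a negative weight, and
expresses its protection through category frequencies instead. All
group-level analyses are invariant to this choice (see above).

Missing dosages are an error by default (mirroring the exclusion of
participants with missing genetic data); lenient mode imputes `2 × EAF` and
logs the imputations per variant.

## Serology thresholds

Positivity thresholds are centiles of non-diabetic control titre
distributions: 97 (GADA), 98 (IA2A), 97.5 (ZnT8A). The percentile definition
is **nearest-rank** — the `ceiling(c/100·n)`-th order statistic — because it
always returns an observed titre, is reproducible across software, and is
conservative; whether the original assays interpolated is not documented, so
interpolation (`quantile` type 7) is available as an option. Ties at the
threshold are positive (`≥`). Insulin autoantibodies are not modelled: they
are unreliable once exogenous insulin treatment has begun.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes,
with the shipped `config-paper-like.json` parameterised to the published
cohort: adults 894 antibody-positive (scores N(0.271, 0.026)) and 218
antibody-negative (a 71:147 mixture of N(0.271, 0.026) and N(0.229, 0.034));
children 642 positive (N(0.277, 0.026)) and 60 negative (N(0.274, 0.034));
1924 type 2 controls (N(0.229, 0.034)); Table-1-style adult clinical rates;
adult HLA category frequencies (6%/15% DR3-DR4 and DR15 in the negative
group vs 19%/3% in the positive). Quantities not published at group level —
per-antibody IA2A/ZnT8A rates, child clinical rates, control HLA — are
single realistic choices listed under `illustrative` in the config.

Design choices:

* **Score-level simulation is the default**; a genotype-level mode samples
  per-variant dosages from group-shifted allele frequencies and scores them
  through the engine, for integration testing of the full path.
* **Ages are shifted-gamma**, moment-matched to the published mean/SD per
  group. A right-skewed model keeps the combined adult median near the
  published 30.95 years; a normal model with the same moments would put it
  near 33.
* **Mixture membership is assigned deterministically** (`round(w·n)` type 1
  draws) so the latent `true_class` fraction equals $1-w$ exactly —
  simulation truth should not itself be noisy. Binomial assignment is
  available in `sample_mixture()`.
* **Seeding**: the global config seed expands to per-group child seeds as
  `seed + 100003·(group index)`, so appending a group never perturbs
  existing ones, and identical config + seed gives byte-identical CSVs.
* Child BMI is generated directly on the adult-adjusted scale; age
  adjustment from paediatric reference data is a pluggable step outside the
  generator.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: mixture membership is independent of age,
clinical features and HLA within a group, so the real age gradient in the
non-autoimmune fraction (45% in younger vs 77% in older adults, driven by
age-varying composition) appears in the synthetic cohort only through the
deterministic difference-parameterised estimator, not in the simulated
strata; titres are not simulated (statuses are Bernoulli); score
distributions are exactly normal, with none of the skew or admixture
structure of real GRS distributions; and nothing about assay drift or
serology measurement error is represented.

## Group statistics

Pooled-variance Student's t is the default two-group test because it
reproduces the published CI (0.024, 0.032) for the 0.028 adult mean score
difference from the published summaries; Welch is a flag. Chi-square is
Pearson without continuity correction — at these sample sizes the correction
is immaterial. The median split places ties in the lower stratum
(`≤ median`), matching the 18–30.95 / >30.95-year convention. ANOVA for
more than two groups is a thin wrapper over `aov`.

## HLA risk categories

`classify_hla()` uses the precedence DR3-DQ2/DR4-DQ8 heterozygote →
DR15-DQ6 carrier → DR3-DQ2 or DR4-DQ8 carrier without DR15-DQ6 → neutral
X/X. The middle step encodes the judgement that mixed pairs such as
DR3-DQ2/DR15-DQ6 belong with the protective-carrier category (the risk-
carrier category is explicitly "without DR15-DQ6"); the precedence is
recorded in every report's provenance block rather than left implicit.

## Problem sizes and determinism in the shipped tests

The test suite regenerates all fixtures in code. Stochastic checks use fixed
seeds chosen once: Monte-Carlo replication of the estimator uses 400
replicates at the full published group sizes (the acceptance script uses
1000); law-of-large-numbers checks use $10^5$ draws; bootstrap coverage uses
120 experiments × 250 resamples at well-separated components ($\Delta\mu =
2\sigma$, n = 200 per group), where the percentile interval's coverage is
expected within binomial error of 95%. End-to-end determinism is asserted as
byte-identical cohort CSVs and report JSON under a repeated seed.

## Known limitations

Wald intervals degenerate to zero width at $\hat p \in \{0, 1\}$ (documented
behaviour, flagged by clamping); the bootstrap alternative does not.
The triple-antibody sensitivity estimate depends on the configured
triple-positive reference mean, which is not published at full precision;
the shipped config therefore treats it as derived from the synthetic cohort
itself rather than asserting a published value. The estimator inherits all
caveats of GRS-based group deconvolution: reference-population mismatch
(ancestry, age of weight-derivation cohorts) biases $\hat p$ in proportion
to the induced shift in reference means.
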