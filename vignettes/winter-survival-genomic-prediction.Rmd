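---
title: "Genomic prediction of winter survival in structured populations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of winter survival in structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wintergp` implements a complete genomic-selection analysis for winter
survival in multi-population perennial-grass breeding panels — the setting
of lowland switchgrass being adapted to northern latitudes, where training
panels combine several diverged breeding populations and validation
material comes from natural populations spread along strong geographic
gradients. This vignette explains the models, the tunable parameters, what
the synthetic-data generator does and does not emulate, and the design
choices made where the problem was genuinely open.

## The analysis path

1. **Trial BLUPs** (`fit_random_model`, `family_values`): plot-level
   survival scores (0–20 scale; 0 = dead, 20 = undamaged) from replicated
   multi-location nurseries are reduced to one value per half-sib family
   by an all-random mixed model. The genomic-prediction response is the
   *non-centered* family value, grand mean + family BLUP, which preserves
   experiment-wise level differences.
2. **Marker QC** (`filter_markers`, `impute_missing`): biallelic dosages
   are filtered on missingness < 20%, MAF > 1/(2N) with N the panel size,
   and a 1-df HWE chi-squared p-value > 1e-4 (all strict); surviving
   missing calls are mean-imputed.
3. **GBLUP** (`grm`, `fit_gblup`, `cross_validate`): the VanRaden genomic
   relationship drives the mixed model `y = 1μ + u + e`,
   `u ~ N(0, σ²ᵤK)`; genomic heritability is `σ²ᵤ/(σ²ᵤ+σ²ₑ)`; accuracy is
   the Pearson correlation between family values and out-of-fold GEBVs
   under 5-fold cross-validation.
4. **Mixed-population Matérn model** (`fit_mpm`): for panels with strong
   structure, the genetic covariance becomes `Ω ∘ G`, the elementwise
   product of the genomic relationship with a Matérn kernel over distances
   between marker-derived principal-component scores.
5. **Validation** (`adjust_gebv`, `geo_correlations`, `geo_regression`,
   `prediction_accuracy`): GEBVs are averaged into population least-squares
   means and tested against minimum winter temperature, latitude and
   longitude of origin, or correlated with phenotype BLUPs of an
   independent trial.
6. **Ploidy screen** (`ref_allele_fractions`, `classify_ploidy`):
   tetraploid and octoploid individuals are separated by the distribution
   of reference-allele read fractions at heterozygous calls.

## Trial mixed models

All terms are random with an intercept-only fixed part, fitted by REML
through `lme4`. The joint multi-location preset uses location, family,
block-within-location and family×location. With plot-level records (one
score per family×block×location cell) the family×block interactions are
confounded with the plot residual, so they are pooled into it; with
per-plant records they would be estimable, but per-plant scoring is out of
scope here. Family-mean broad-sense heritability uses the line-mean form

H² = σ²_f / (σ²_f + σ²_{f×l}/l + σ²_e/(l·r)),

with `l` locations and `r` blocks. This is the standard assembly for a
family-mean basis; the residual pooled into the denominator inevitably
contains the plot-level interaction terms discussed above.

Survival percentages are reported under two conventions —
`score_fraction` (mean score / 20) and `plant_alive` (fraction of scores
above zero) — because the mapping from the 0–20 scale to a percentage is a
reporting choice, not a modelling one; neither is privileged.

## Spectral REML for GBLUP

`fit_gblup` profiles the restricted likelihood over `λ = σ²ₑ/σ²ᵤ` on the
eigenbasis of K (one eigendecomposition per fit, O(n) per candidate λ),
searching `log λ ∈ [−10, 10]` with `optimize()` at tolerance 1e-8 and
guarding both interval ends. Prediction into unobserved individuals uses
the conditional-expectation form

û_test = K[test,train] (K[train,train] + λ̂I)⁻¹ (y_train − μ̂),

which equals the joint mixed-model-equation solution, and collapses to the
ridge-regression marker solution when K = WW′/c. Degenerate inputs are
handled explicitly: a constant response returns a boundary fit with
σ²ᵤ = 0 and a warning; a kernel with eigenvalues below −10⁻⁶·max is
rejected; small negative eigenvalues from floating-point noise are clamped
to zero.

Cross-validation partitions individuals uniformly at random into folds
whose sizes differ by at most one (368 individuals in 5 folds gives
74/74/74/73/73). Both the mean per-replicate accuracy and the accuracy of
replicate-averaged GEBVs are reported, since averaging GEBVs over
replicates is common practice for GBLUP and the two summaries can differ.

## The mixed-population Matérn kernel

The population-differentiation kernel is the standard Matérn family

K(d) = 2^{1−v}/Γ(v) · (√(2v)·d/h)^v · BesselK_v(√(2v)·d/h),  K(0) = 1,

evaluated in log space with exponent-scaled Bessel functions; where the
Bessel term overflows (very large v) the Gaussian limit
`exp(−d²/(2h²))` is substituted, which is the v→∞ limit of the family.
Following the source convention the two parameters are *named* v and h
(called scale and shape there); their standard roles are v = smoothness
and h = range. Distances are Euclidean distances between retained
principal-component scores, each standardized to unit variance so that h
is scale-free — the alternative (eigenvalue-weighted scores) would make h
depend on the marker count and panel size. For independent validation,
PCs are computed on the combined calibration+validation genotypes so that
held-out individuals live in the same coordinate system.

`(v, h)` are estimated by an outer bounded quasi-Newton search on the log
scale (box v ∈ [0.05, 50], h ∈ [10⁻³, 10³], start (0.5, 0.5), three
deterministic restarts), with inner spectral REML for the variance
components given `H(v,h) = Ω ∘ G`. The Schur product theorem keeps H
positive semi-definite. Plain GBLUP is nested at the h → ∞ limit
(Ω → 1); when every interior start ends below the GBLUP restricted
likelihood the fit returns that boundary exactly (h reported as `Inf`), so
the model never fits worse than GBLUP.

The number of components d defaults to the count of leading components
each explaining more than 5% of variance (minimum 1), mirroring the usual
scree-plus-clusters judgement; it is a user-visible argument because that
judgement is data-dependent.

**When does the Matérn product help?** With exactly two subpopulations
the product kernel only decouples the two group means — information the
centered GRM's anti-correlated block structure already carries — so
hold-out accuracy is essentially unchanged (the restricted likelihood
still never decreases, by nesting). The gain appears when several
populations span the PC geometry: Ω then acts as a Gaussian-process prior
over population-level effects, smoothing predictions across genomically
similar populations. That matches the setting the model was designed for
(validation panels of dozens of natural populations), and is how the
package's acceptance checks exercise it: likelihood nesting on
two-subpopulation panels, accuracy gain on a six-subpopulation panel.

## Bayesian whole-genome regression

BayesA, BayesB and the Bayesian lasso are single-chain Gibbs samplers
(compiled, using R's RNG so `set.seed` makes chains bit-reproducible) for
`y = μ + Za + e` with marker-specific shrinkage:

* **BayesA** — scaled-inverse-χ² marker variances, df 4.2, scale matched
  so the expected total marker variance equals `r2 · var(y)` (prior guess
  r2 = 0.5 of variance being genetic);
* **BayesB** — the same slab with a point mass at zero of probability
  π = 0.95 (fixed by default, exposed in `chain_config`);
* **Bayesian lasso** — the normal/exponential (double-exponential)
  mixture with an inverse-Gaussian full conditional for the local scales
  and a Gamma(1.1, 10⁻⁴) hyperprior on λ².

Default chain settings are 20,000 iterations with 5,000 burn-in; the test
suite runs 2,000/500 because the checked properties (null shrinkage,
single-QTL recovery, the ridge limit of BayesA under a fixed common marker
variance) stabilize well before that. Residual-variance calibration was
checked in an identifiable regime (more individuals than markers): with
p ≫ n the partition of variance between markers and residual is weakly
identified and credible intervals for σ²ₑ alone under-cover, which is a
property of the model class, not the sampler.

## The synthetic-data generator

`simulate_study` chains four stages, each seeded by a deterministic child
of the master seed:

* **Genotypes** (`simulate_structured_genotypes`) follow the
  Balding–Nichols construction: ancestral frequency p ~ Uniform over
  `ancestral_maf_range`, subpopulation frequency ~
  Beta(p(1−F)/F, (1−p)(1−F)/F), dosage ~ Binomial(2, freq). F (the `fst`
  knob, default 0.3) is the single structure-strength dial and is
  recovered by the Hudson estimator to within ±0.05. HWE holds within
  subpopulations by construction; pooling creates the Wahlund heterozygote
  deficit that the HWE filter then reacts to, as in any merged panel.
* **Geography** (`assign_geography`): populations draw latitude 28–45°N
  and longitude 75–100 °W; minimum winter temperature is linear in
  latitude plus noise (collinearity ≈ −0.95). Longitude is stored in
  positive degrees West so that a trait increasing from west to east
  correlates *negatively* with the longitude column — the sign convention
  under which the geographic-validation sign pattern (latitude +,
  longitude −, minimum temperature −) is expected. The breeding-value
  cline `geo_gradient·(lat, lon)` (default (0.5, −0.3) score points per
  degree) is applied to population means by `apply_geography`.
* **Phenotypes** (`simulate_trial_phenotypes`): plot score = clip to
  [0, 20] and round of (grand mean 10 + location + block + breeding value
  + family×location + plot residual). QTL effects are rescaled so
  breeding values have standard deviation `genetic_sd` (default 2 score
  points); non-genetic variances are solved from `h2_target` (default
  0.6, the middle of the 0.1–0.9 family-mean range seen across such
  populations) and split 30% to family×location, 70% to the plot
  residual. Clipping and integer rounding are deliberate realism — scores
  near 0 or 20 saturate, as they do for southern material in a hard
  winter — and they shave a few points off the realized heritability.
* **Read depths** (`simulate_allelic_depths`): per heterozygous call,
  total depth ~ Poisson(`mean_depth`), reference reads ~ Binomial(total,
  class fraction); tetraploid heterozygotes sit at fraction 0.5,
  octoploid calls mix the 0.25/0.5/0.75 dosage classes with equal weights
  by default.

**What the generator does not emulate.** Markers are independent given
subpopulation frequencies: there is no recombination map, no LD decay
along chromosomes, and therefore no marker–QTL tagging — causal loci are
part of the genotyped panel. Half-sib families are represented by their
maternal-parent dosages only (no within-family segregation), so
within-population relatedness comes from drift alone, not pedigree.
Consequently, passing tests demonstrate the estimators' correctness and
the qualitative population-structure phenomena (Wahlund effect,
MAF-spectrum contrasts, training-relatedness effects via allele-frequency
divergence, geography-linked population means), but say nothing about
tagging efficiency or LD-based transferability on real data.

## Numerical choices and degenerate inputs

* Missingness is computed as `(n − n_obs)/n`, which is exact for boundary
  comparisons such as "exactly 20% missing is removed".
* Monomorphic markers get HWE p = 1 (the MAF rule removes them); markers
  with no calls are flagged and always removed.
* Mean imputation is per-marker over the whole panel by default — the
  training panel is analysed as one merged population — with a
  within-label option whose empty groups fall back to the panel mean.
* The GRM drops monomorphic markers (they contribute nothing to the
  centered cross-product) and errors when nothing polymorphic remains.
* IBS uses the allele-sharing score 1 − |dᵢ−dⱼ|/2 per marker; with
  missing data each pair averages over its jointly observed markers and a
  pair with none is an error rather than a silent NA.
* The ploidy classifier smooths the read-fraction distribution with a
  Gaussian kernel (bandwidth 0.05) before comparing window masses at
  0.25/0.75 versus 0.5 (half-width 0.08, decision ratio 1): raw histogram
  masses are pathological at moderate depth because binomial fractions
  are quantized (at total depth 10, a tetraploid's 4/10 and 6/10 sites
  fall outside 0.5 ± 0.08). Individuals with fewer than 200 qualifying
  sites are labelled ambiguous rather than guessed.
* Geographic regression excludes minimum temperature from the design by
  construction, because its collinearity with latitude makes joint
  coefficients uninterpretable; correlation tables report it separately.

## Problem sizes in the checks

The test suite and the acceptance script run panels of 120–400
individuals with 300–2,000 markers, 5-fold cross-validation with up to 10
replicates, 2,000-iteration chains, and 10-replicate simulation studies.
These sizes were chosen so that every Monte-Carlo assertion has
comfortable margins while the whole suite stays fast; the estimators
themselves are O(n³) in the panel size through one eigendecomposition per
REML fit and scale to panels in the low thousands.

## Known limitations

* No G×E modelling beyond family×location variance components; locations
  are analysed jointly for training and separately for validation trials.
* No model-based ancestry estimation; grouping comes from labels or PCA.
* Mean imputation only — appropriate for the low post-QC missingness this
  pipeline assumes, not for sparse genotyping designs.
* The ploidy screen distinguishes only tetraploid from octoploid
  read-fraction signatures and assumes heterozygous calls are trusted.
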