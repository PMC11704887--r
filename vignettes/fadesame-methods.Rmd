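---
title: "Models and methods behind fadesame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fadesame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`fadesame` implements, end to end, an analysis linking lifetime
environmental enrichment to the preservation of memory-network fMRI
activity in older adults, together with a synthetic-data generator that
lets every stage run and be validated without any restricted data.

The chain is:

1. **Encoding task**: an incidental visual encoding session with novel
   photographs and two highly familiarized "master" images, followed by
   a recognition test with confidence ratings (1 = definitely new …
   5 = definitely old).
2. **First-level GLM**: per-participant voxelwise t-maps for the
   *novelty* contrast (novel vs. master) and the *subsequent-memory*
   contrast (confidence-weighted parametric modulation of novel
   trials).
3. **Single-value scores** against a young reference cohort: FADE
   (deviation) and SAME (similarity) per contrast — four scores per
   participant.
4. **Enrichment score**: the LEQ leisure items scored 0–5 and summed
   over six activities and two life stages (early life 13–30 y, midlife
   30–65 y) into the EE score (0–60).
5. **Inference with missing items**: Little's MCAR test, then
   full-information maximum-likelihood (FIML) regressions of the four
   scores on EE, with subgroup models, covariate screening, and
   adjusted models.

## Score definitions and conventions

With a network mask $M$, young positive-effect voxels $V^+$ and
negative-effect voxels $V^-$ (per contrast), young per-voxel mean $m_j$
and SD $s_j$, and a participant's t-map $t_j$:

$$\mathrm{FADE} = \overline{t}_{M \setminus V^+} - \overline{t}_{V^+},
\qquad
\mathrm{SAME} = \frac{1}{|V^+|}\sum_{j \in V^+}\frac{t_j - m_j}{s_j}
              + \frac{1}{|V^-|}\sum_{j \in V^-}\frac{m_j - t_j}{s_j}.$$

Pinned conventions, each asserted by a test:

* **Signed, not absolute, deviations in SAME** — only signed deviations
  allow positive scores for super-young patterns, which the observed
  score distributions require.
* **Per-voxel young SD** (not pooled): the finest reading of
  "accounting for reference-sample variability".
* **FADE's "outside" domain is the network complement of $V^+$**, not
  the whole grid (configurable); the scores are defined within the
  memory network.
* SAME of a map equal to the young mean is exactly 0; adding a constant
  to a map leaves FADE unchanged (difference of two means) but shifts
  SAME through the standardized terms — an intended asymmetry of the
  two definitions.
* $V^\pm$ come from voxelwise one-sample t-tests of the young maps at
  an uncorrected one-sided threshold of $p < 0.001$ per tail
  (configurable). A conventional voxelwise threshold keeps the sets
  stable on toy grids; zero-variance voxels are excluded with a
  warning.

## The synthetic cohort generator

The generator reproduces the study's design constants as defaults:
a young reference cohort of $n = 106$; an older cohort of $n = 372$
with subgroup proportions 127/199/46 (OA/SCD/FH); sessions with 88
novel photographs (44 indoor, 44 outdoor), two master images shown 22
times each, 44 recognition foils, and 10 pre-scan familiarization
repetitions; and an LEQ missingness rate of 30/372 participants, each
missing a uniform 1–12 of the 12 scoring items completely at random.

**Maps.** The toy brain is a 12×12×12 grid whose central block is the
"network" mask, with one activation and one deactivation block per
contrast (novelty: +3 / −2; memory: +2.5 / −1.5 noise-SD units).
Young maps are topography plus white noise. An older participant's
topography is multiplied by the preservation shrink
$g(z) = \mathrm{logit}^{-1}(0.5 + 0.8z)$ of a standard-normal latent
$z$ — bounded, monotone, and $g(0) \approx 0.62$, so the average older
adult expresses an attenuated young pattern; the SCD subgroup's latent
is shifted by −0.15, a small simulation knob (not an empirical claim)
giving that subgroup slightly lower mean scores.

**Enrichment coupling (`wire`).** Two modes:

* `"preservation"` (default): the enrichment propensity and the
  preservation latent are bivariate normal with correlation
  `effect_beta`; all four scores move with enrichment.
* `"same_novelty"`: the preservation latent is independent of
  enrichment, and the propensity instead drives a *selective*
  perturbation of the novelty map: −1 per unit gain on the deactivation
  block with a compensating constant on neutral network voxels. The
  compensation keeps the mean over $M \setminus V^+$ unchanged, so the
  FADE score is untouched by construction, while the $V^-$ term of SAME
  moves. This mode exists because a pure shrink of the whole topography
  cannot confine an effect to one score: any scaling of the $V^+$
  amplitudes moves FADE as well.

The selective gain is calibrated in closed form
(`wiring_gain()`): the unwired novelty-SAME variance is
$v_0 = K^2\,\mathrm{var}(g) + 1/|V^+| + 1/|V^-|$ with
$K = (a^+ + |a^-|)/\sigma$, $\mathrm{var}(g)$ integrated numerically
over the subgroup mixture; the gain
$\gamma = \beta\sqrt{v_0/(1-\beta^2)}$ then makes the standardized
propensity–SAME association equal `effect_beta` exactly under the
generative model. No empirical tuning is involved.

**LEQ items.** Item responses come from a cumulative-logit ordinal
model: response $= \#\{\tau_c < z + \varepsilon/d\}$ with logistic
noise, discrimination $d = 3$, equally spaced thresholds (spacing 1.5)
centred at −0.55 plus per-activity offsets (reading and social
frequent; artistic and an additional language rare). These constants
were calibrated once, by simulation, so the cohort's EE score
distribution is realistic — mean ≈ 34, SD ≈ 8 on the 0–60 range,
matching the descriptives reported for the cohort the generator
emulates — and then frozen. The implied score–latent correlation is
≈ 0.98, so ordinal measurement attenuates a wired latent effect of
0.13 to ≈ 0.125 at the score level; the end-to-end recovery tests
bound exactly this quantity. Confidence ratings use the same ordinal
family (thresholds ±0.5, ±1.5; discrimination 2) shifted by a memory
ability latent, with foils rated from the latent's negative — a
perfect memory yields all 5s on old items and all 1s on foils.

**Demographics** (age 69.45 ± 5.77 clamped to 60–87, sex 197:175,
education 14.91 ± 2.9 y, ISEI 61.13 ± 17 clamped to 16–90, eight
scanner sites with decreasing weights) are drawn independently of the
latents by default; `confound_age_ee` and `confound_age_pres` open
standardized paths from age into the enrichment propensity and the
preservation latent, so covariate adjustment can be tested under null
and confounded regimes.

**What the generator does not emulate**: realistic haemodynamic noise
(no drift, no autocorrelation), anatomical structure in the mask,
spatial correlation of map noise, item-level LEQ heterogeneity beyond
activity offsets, or non-random missingness. Passing tests therefore
demonstrate correctness of the *procedures* under a known generative
model, not robustness to real-data artefacts.

## First-level GLM choices

Canonical double-gamma HRF (peak 6 s, undershoot 16 s, no
derivatives), evaluated analytically at scan times for impulse events;
a fixed 3 s inter-trial interval and 2 s TR (the task description
leaves timing open; a fixed ITI keeps the toy design full rank). The
two master images are pooled into one regressor, since the novelty
contrast is novel vs. master, not per-image. The parametric modulator
weights novel-trial impulses by confidence minus the mean confidence;
mean-centering makes the memory t-map invariant to any affine recoding
of the ratings. Drift is a first-order polynomial; no prewhitening
(the generator's noise is white; an AR(1) knob on the generator would
be the natural extension). Degenerate inputs are explicit: sessions
without master trials error, an all-equal confidence vector zeroes the
modulator, which is dropped with a warning.

## FIML and Little's test

Both ride on one engine, `mvn_em()`: EM for the mean and covariance of
a multivariate normal from incomplete data, iterated until the
relative change of the observed-data log-likelihood falls below
1e-10 (or 10,000 iterations), from available-case starting values.
EM guarantees likelihood ascent; determinism at this tolerance makes
desk-scale runs reproducible.

`fiml_regression()` reads the regression parameters off the fitted
joint moments ($B = \Sigma_{xx}^{-1}\sigma_{xy}$). Standard errors are
observed-information: a numerical Hessian of the observed-data
log-likelihood in $(\mu, \mathrm{vech}\,\Sigma)$ at the MLE, mapped
through the delta method. p-values use the normal (z) reference,
mirroring common FIML software. With `scale = TRUE` every variable is
standardized in advance with available-case means and SDs — the
scaling necessarily uses incomplete columns — so coefficients are
standardized betas; affine equivariance of the MVN likelihood makes
this exactly equivalent to rescaling afterwards.

`little_mcar_test()` compares each missingness pattern's observed-
variable means with the EM estimates through the quadratic form
$d^2 = \sum_p n_p(\bar y_p - \hat\mu_{[p]})^\top
\hat\Sigma_{[p]}^{-1}(\bar y_p - \hat\mu_{[p]})$, chi-square with
$\sum_p k_p - k$ df. Complete data (a single pattern) is an explicit
error — the test is inapplicable at df 0. On the generator's
6-category ordinal items the test is very mildly anticonservative
(discreteness), but stays within the calibration band the test suite
asserts.

## Pipeline decisions

* Primary models z-score on the full sample; subgroup models re-scale
  within each subgroup, so subgroup betas reflect subgroup-specific
  variation and are invariant to whole-sample affine transforms.
* Covariate screening uses FIML simple regressions (the same estimator
  as the main models) of each outcome on each candidate; a covariate
  enters the adjusted models if it associates with *any* outcome at
  p < 0.05. The any-outcome rule is the default because it matches the
  reported analysis structure; a per-outcome rule is available in
  `analysis_config()`.
* Sex is coded 0/1; scanner site enters as treatment-coded dummies
  with the largest site as reference, dropping single-participant
  sites with a warning.
* No multiple-testing correction is applied across the four primary
  outcomes; p-values are reported per outcome, unadjusted. This
  mirrors the analysis the pipeline reproduces and is stated here
  prominently.
* The slope-heterogeneity F-test is complete-case least squares
  comparing `score ~ ee` with `score ~ ee * subgroup` (4 added
  parameters for three groups) and reports its own complete-case
  denominator df.
* Scatter output separates roles exactly as FIML implies: points are
  the complete cases; line parameters come from the FIML fit of all
  rows.

## Problem sizes and runtime choices

The shipped validation suite runs the Monte-Carlo studies at the
design scale of the emulated study: 500 replicates for the MCAR
type-I calibration (n = 372, 12 items), 200 replicates for FIML bias
(30 % MCAR, n = 400), and 100 full-pipeline replicates (n young = 106,
n old = 372, 12³ grid) for end-to-end effect recovery. The end-to-end
study runs with `analysis_config(site_adjust = FALSE)`: site is a null
factor in the generator and site adjustment has its own dedicated
test, so leaving the site dummies out of the replicated runs keeps the
study at desk scale without changing what is being validated. The
slow (BOLD) path is validated on smaller 8³ grids where its exactness
properties (noiseless recovery, null calibration) do not depend on
grid size.

## Known limitations

* The FIML implementation covers linear regression under joint
  normality only — no structural-equation models, auxiliary-variable
  variants, MAR sensitivity analyses, or multiple imputation.
* The published score formulas may differ in normalization detail from
  the verbal description they were pinned from; the pinned versions
  satisfy every stated property (sign conventions, zero at the young
  mean, positive maxima), and each property is asserted by a test.
* Binary and categorical covariates (sex, site dummies) are treated as
  jointly normal inside FIML, as is standard practice for FIML
  regression with complete dummies.
* The BOLD path has no motion, slice-timing, smoothing or
  normalization stages; the package starts from clean voxel grids by
  design.
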