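---
title: "Methods: object cues, signal detection, and deep-feature encoding for scene realism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: object cues, signal detection, and deep-feature encoding for scene realism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenecue)
```

## The scientific problem

When people view a photograph of an indoor scene and a GAN-synthesized
counterpart, what determines whether the synthetic scene passes as real, and
whether either can be categorized (bedroom vs. kitchen vs. ...)? Two families
of explanation are considered here:

* **Object co-occurrence structure.** Scenes are built from objects with
  strong statistical regularities: *diagnostic* objects predict the scene
  category (a stove predicts a kitchen), and *anchor* objects are large,
  stationary objects that organize smaller objects around themselves (a sink
  anchors a toothbrush). If synthetic scenes garble this structure, object
  scores should predict which images look real.
* **Visual feature hierarchies.** Features extracted at increasing depths of
  pretrained vision networks capture increasingly abstract structure. If
  realism judgments rest on high-level content rather than low-level texture,
  behavioral scores should be decodable mostly from deep layers — and only
  from *trained* networks, with randomly initialized counterparts as the
  lower bound.

This package implements the full analysis pipeline for both questions plus a
synthetic-data generator that emulates every input with planted ground-truth
parameters. Every inferential step is therefore testable end to end, without
any download, against values the simulation is known to contain.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It defines the
study conditions used throughout:

* **Corpus** (`corpus_spec()`, `gen_corpus()`): five indoor categories, 12
  "home" objects per category occurring with probability 0.5–0.95, sparse
  cross-category clutter (0–0.35, 45% of pairs zero), three anchor objects
  per category with anchor probability 0.6–0.95, and 200 scenes per category
  for the norming corpus. Objects enter scenes independently; empty scenes
  are retained. Anchor flags are probabilities P(functions as anchor |
  present); strict booleans are the 0/1 special case.
* **Experimental images**: 150 real + 150 generated (30 per category), as in
  a typical online study of this kind. Generated images use occurrence
  probabilities blended toward the category-average object profile with
  weight `1 - gan_fidelity` (default fidelity 0.6), emulating the weaker
  object structure of GAN scenes. A simulated segmentation network corrupts
  the truth (miss rate 0.1, false-label rate 0.05 including structural
  elements, probability noise SD 0.1).
* **Observers** (`observer_spec()`, `simulate_2afc()`): equal-variance
  Gaussian signal detection. Evidence is Normal(mu, 1) with mu = d′(duration)
  for real images plus linear shifts of 0.18 per z-unit anchor score and
  +0.08 / −0.15 per z-unit diagnosticity for real / generated images, plus a
  participant intercept (SD 0.3). Default d′ values are back-computed from
  headline AUCs of 0.6 (50 ms) and 0.92 (500 ms) via d′ = √2·Φ⁻¹(AUC); they
  are defaults, not asserted ground truth. Fifty participants respond to
  every image once.
* **Ratings and categorization**: realness ratings of generated images are a
  rounded, clipped linear model (anchor effect 0.15, diagnosticity −0.09,
  trial noise SD 1.2); 5-AFC accuracy is a guessing-corrected logistic model
  P(correct) = 0.2 + 0.8·logistic(0.4 + 0.53·z_diag + 0.48·z_realness −
  1.07·c_duration), errors uniform over the four wrong categories.
* **Features** (`feature_spec()`, `gen_feature_store()`): per model instance
  and layer, X = s(depth)·y·wᵀ + E with E iid standard normal and w a unit
  direction fixed per model (so layers within a model share signal geometry,
  as in real networks). Depth is l/(L−1) ∈ [0, 1]; random-initialization
  instances have s ≡ 0. Seven trained and seven random instances by default.

All randomness flows from one master seed through labeled sub-streams
(corpus, observers, features, analyses), so runs are bit-identical given the
seed, and the corpus stream is untouched by, say, changing the number of
bootstrap replicates.

### What the generator does *not* emulate

Real images, real segmentation networks, and real DNN features; reaction
times; participant random *slopes* (only intercepts); between-participant
counterbalancing of durations (duration is fixed per image); and the
confusion structure of categorization errors. Passing tests therefore show
that the analysis code recovers what the generative model plants — they do
not show that the generative model is the right model of human observers.

## Criterion placement on the confidence scale

Human criterion placement is unobservable here, so the 11 criteria that
partition evidence into the 12-point ordinal scale (6-point confidence ×
binary response) are a convention: equally spaced at step 0.3, centered on
the unbiased point mean(d′)/2. The step size was chosen from the closed-form
bias of the trapezoidal AUC: points of the empirical ROC lie exactly on the
theoretical curve, so the only systematic error is the chord-vs-arc deficit,
which at step 0.3 is at most 0.0023 across d′ ∈ [0.36, 2]. That keeps the
empirical AUC within ±0.005 of Φ(d′/√2) at 10⁵ trials, Monte-Carlo error
included.

## ROC, AUC, and the bootstrap comparison

`empirical_roc()` sweeps the 11 interior cutoffs: hit = P(scale > k | real),
false alarm = P(scale > k | generated); AUC is the trapezoidal integral with
endpoints appended. The headline group statistic is the *unweighted mean of
per-participant AUCs*; pooled-trials AUC is also reported but is attenuated
by between-participant criterion variability (≈0.91 vs 0.92 at the default
intercept SD). `auc_boot_test()` resamples participants with replacement
and, within each, trials within the real/generated strata (implemented as
multinomial redraws of per-participant scale counts, which is algebraically
the same and far faster); the two-sided p-value uses add-one smoothing,
p = min(1, 2·min(tails)·(B+1)⁻¹-style), so p is never exactly zero.

Degenerate hit/false-alarm rates of 0 or 1 are corrected before probit
transformation, by default log-linearly (+0.5 to both counts, +1 to both
Ns, applied unconditionally), or by clipping to 1/(2N).

## Object scores

From the norming corpus, `compute_score_table()` computes

* diagnosticity(o, c) = #scenes of category c containing o / #scenes
  containing o (so each object's diagnosticities sum to 1 over its observed
  categories), and
* anchor-status frequency(o, c) = #category-c scenes where o is flagged
  anchor / #category-c scenes containing o.

Pairs never observed are *absent* from the table rather than zero: at
scoring time, absent evidence is not evidence of absence, and an object
missing for the scene's nominal category simply contributes nothing. Only
when *no* filtered object has an entry does the scene get (0, 0) with an
explicit flag, so downstream regressions keep the scene. Predictions are
filtered at probability strictly > 0.3 and structural elements (window,
wall, floor, door — a deliberately minimal, user-extensible set) removed;
each scene receives the *maximum* score over surviving objects, with the
contributing object recorded. z-transformation (mean 0, sample SD 1) is
applied within each experiment's analysis set, not globally.

Two non-identical glosses of anchor-status frequency circulate (probability
of holding anchor status in a scene category vs. functioning as an anchor in
a given scene); the per-category conditional above is the implemented
reading, documented rather than asserted as canonical.

## Fixed-effects regressions

The paper-style analyses use (generalized) linear *mixed* models. This
package deliberately implements fixed-effects simplifications: its
inferential claims are about recovery of planted fixed effects on synthetic
data, not reproduction of mixed-model numerics. Participant heterogeneity
can be absorbed by centered participant indicator columns
(`build_design(..., participant = )`) — the fixed-effects analogue of random
intercepts. Without them, marginal slope estimates are attenuated by
roughly 1/√(1 + σ²_participant) under the probit observer, which matters for
parameter-recovery checks.

Design matrices use sum contrasts (+1 for the first level in sort order:
50 → +1, "generated" → +1), so the intercept is the grand mean and factor
slopes are half the difference between levels. Binary responses are fit by
IRLS (deviance tolerance 1e-10, max 100 iterations) with Wald z statistics
from the inverse Fisher information; the probit link is the natural match
for threshold responses of the Gaussian evidence model, the logit link the
conventional choice otherwise. Perfect separation and rank deficiency are
rejected with explicit errors. 5-AFC accuracy is fit with a chance floor,
P = 0.2 + 0.8·linkinv(η), by direct maximum likelihood (BFGS with analytic
gradient, SEs from the numerical Hessian) — fitting without the floor is
biased toward zero, which the tests demonstrate. Per-condition simple
slopes ("linear trends") for a continuous × factor interaction are
β_cont ± β_int with SEs from the coefficient covariance; their average
equals the main effect exactly under sum coding.

The full four-way-interaction categorization model is available through
`build_design()`'s interaction list; the default pipeline fits the
main-effects model that the downstream interpretations use.

## Layer-wise encoding analysis

Per (model, layer), behavioral scores are decoded by leave-one-out
cross-validated ridge regression (`loo_ridge_decode()`): predictors are
column-standardized with training-fold statistics, and the penalty is chosen
*within each fold* by closed-form GCV over a 13-point log grid 10⁻¹…10⁵.
The decoding score is the Pearson correlation between LOO predictions and
actual scores; exactly constant predictions score 0.

One numerical subtlety is documented prominently: centering y inside each
training fold plants (n·ȳ − y_i)/(n − 1) in the held-out prediction — a term
perfectly anticorrelated with y_i — so with heavy regularization the *null*
decoding correlation converges to −1 rather than 0. The response is
therefore centered once globally (a single scalar); all multivariate
statistics remain fold-internal. Even so, LOO decoding of pure noise has a
mild negative bias (order −0.1 at 100 images), which is why inference
compares trained against random instances rather than against zero.

`loo_ridge_fixed()` provides the fixed-penalty closed form e_i/(1 − h_ii) on
the design exactly as given; it is algebraically identical to explicit
refits and is verified against them to 1e-8.

Wide layers can first be reduced by sparse random projection
(`srp_project()`): entries ±√s with probability 1/(2s) each, s = √D, scaled
by 1/√k, distance-preserving in expectation (Johnson–Lindenstrauss); with a
target dimension at or above the input width the data pass through
unchanged, with a message.

Layer scores are averaged within 10 equal depth bins ([0, 0.1), …, last bin
closed at 1; empty bins stay missing). Trained-vs-random inference per bin:

* **Permutation test**: statistic mean(trained) − mean(random); group labels
  permuted over all 14 models, the same permutation applied to every bin (so
  model-level structure is preserved); one-sided p = (1 + #{perm ≥ obs}) /
  (n_perm + 1), default n_perm = 10,000. A quoted significance threshold of
  "95.5%" in the source methodology is treated as a typo for 95%; the level
  is an argument.
* **BH-FDR** across bins (via `p.adjust`), rejections at q < 0.05.
* **Bootstrap** mean and percentile 95% CI of the paired per-model
  differences (1000 resamples).
* **JZS Bayes factor** for the paired differences: Cauchy prior scale 0.707
  (the conventional default; a quoted "r = 707" is read as 0.707) on the
  standardized effect, evaluated by adaptive quadrature over the
  inverse-χ²(1) mixing density and verified against an independent
  fine-grid integration to 1e-6 relative error.

Scores are computed per model and then averaged per bin (not pooled across
models), matching a seven-model zoo with per-model scores.

## Numerical choices and degenerate inputs

* z-transform of a constant vector, constant decoding targets, zero-variance
  paired differences, single-class trial tables, >2-level factors, unknown
  categories, and rank-deficient designs all raise explicit errors.
* Probability-0.3 filtering is strictly `>`; a prediction at exactly 0.3 is
  dropped.
* The 12-point scale's AUC is invariant to strictly monotone relabeling;
  tests enforce this.
* All bootstrap/permutation p-values use add-one smoothing; permutation
  replicates below 1000 warn.

## Problem sizes

Default analysis sizes are the study conditions above (50 × 300 trials;
14 × 10 feature matrices of 150 × 30). The test suite exercises the same
code paths at reduced sizes chosen for tight Monte-Carlo bounds at desk
scale — e.g. 10⁵ trials for the closed-form AUC check, 200 replicates for
parameter-recovery coverage, 500 null simulations for permutation
calibration, and 100 null pipelines for familywise FDR calibration.

## Known limitations

* Fixed-effects only; mixed-model variance components, Satterthwaite df,
  effect-size measures, and Bayes-factor model comparison for regressions
  are out of scope by design.
* The generator's anchor and diagnosticity scores enter behavior linearly;
  real effects need not be linear in the scores.
* LOO decoding scores retain a small negative null bias (see above);
  absolute decoding values should not be compared against zero, only
  trained against random.
* The empirical ROC uses the fixed 12-level scale; observers whose criteria
  collapse onto few levels yield coarser, lower-AUC curves.
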