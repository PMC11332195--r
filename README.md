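# scenecue

Analysis pipeline for visual psychophysics experiments on the perceived
realism and categorizability of generated (GAN) indoor scenes, together with
a synthetic-data generator that makes every stage testable end to end.

## Who this is for

Researchers analyzing real-vs-generated scene discrimination experiments
(binary response + 6-point confidence), realness ratings, and 5-alternative
scene categorization, who want to relate behavior to (a) object
co-occurrence statistics and (b) layer-wise deep-network features — and who
want the whole chain validated against planted ground truth before touching
real data.

## What it computes

**Object scores.** From a labeled corpus of scenes,

- diagnosticity(o, c) = P(category c | object o present) =
  #scenes of c containing o / #scenes containing o,
- anchor-status frequency(o, c) = P(o functions as anchor | o present in a
  scene of c).

Segmentation predictions are filtered (probability strictly > 0.3,
structural elements removed) and each scene receives the maximum score over
its surviving objects.

**Signal detection.** Responses and confidence are combined into a 12-point
ordinal scale; sweeping its 11 cutoffs gives the empirical ROC, with
AUC = area under it (AUC = Φ(d′/√2) for an equal-variance Gaussian
observer), d′ = Φ⁻¹(hit) − Φ⁻¹(fa), criterion c = −(Φ⁻¹(hit) + Φ⁻¹(fa))/2.
Two conditions' AUCs are compared by a stratified participant-and-trial
bootstrap (N = 2000). Per-image *realness* is the mean binary response the
image received, per presentation duration.

**Regressions.** Fixed-effects (G)LMs with sum contrasts and Wald
inference: probit models for 2AFC responses on the evidence scale, linear
models for ratings, and a chance-floor logistic model
P(correct) = 0.2 + 0.8·logistic(η) for 5-AFC accuracy. Per-condition simple
slopes of a continuous predictor come from the interaction coefficients.

**Encoding analysis.** Per model instance and layer: leave-one-out
cross-validated ridge regression (per-fold GCV penalty selection, optional
sparse random projection), decoding score r = cor(predicted, actual),
averaged within 10 depth bins; trained-vs-random inference per bin by label
permutation (10,000 draws), BH-FDR across bins, bootstrap CIs of the paired
differences, and default-prior (JZS, r = 0.707) Bayes factors.

## Worked example

```r
library(scenecue)

cfg <- run_config(seed = 3)   # 50 participants, 150 real + 150 generated images
res <- run_exp1(cfg)

res$auc_participant_mean
#>        50       500
#> 0.6185849 0.9184782

res$auc_test[c("diff", "p_value")]
#> $diff      [1] 0.2998933
#> $p_value   [1] 0.0009995002

res$fit_2afc
#> logistic regression (probit link), n = 15000, logLik = -8056.39
#>                term estimate     se statistic p_value   ci_lo   ci_hi
#>         (Intercept)   0.0391 0.0121    3.2469  0.0012  0.0155  0.0628
#>           condition  -0.5609 0.0121  -46.2392  0.0000 -0.5847 -0.5371
#>            duration  -0.3871 0.0119  -32.5255  0.0000 -0.4104 -0.3638
#>            z_anchor   0.1925 0.0127   15.1656  0.0000  0.1676  0.2174
#>              z_diag  -0.0164 0.0118   -1.3951  0.1630 -0.0395  0.0066
#>  condition:duration   0.3746 0.0120   31.3130  0.0000  0.3511  0.3980
#>    condition:z_diag  -0.1188 0.0116  -10.2161  0.0000 -0.1416 -0.0960

res$trend_diag
#>       level      slope         se       ci_lo      ci_hi
#> 1 generated -0.1352219 0.01448067 -0.16360399 -0.1068398
#> 2      real  0.1024099 0.01836878  0.06640712  0.1384127
```

Reading this: the simulated observers discriminate real from generated
images barely above chance at 50 ms (AUC 0.62) and well at 500 ms (AUC
0.92); the bootstrap test confirms the AUC difference. In the probit
regression, the positive `z_anchor` slope (0.19, planted 0.18) says images
whose objects have high anchor-status frequency are more often called
"real", independent of condition and duration; the `condition:z_diag`
interaction unpacks into a negative diagnosticity slope for generated
images (−0.135, planted −0.15) and a positive one for real images (+0.102,
planted +0.08). The encoding table in `res$encoding$comparison` shows
trained-vs-random bin differences that are significant only from mid-depth
bins upward — the deep-feature signature the generator plants.

`run_exp2(cfg, realness = res$realness)` runs the categorization analysis
(diagnosticity 0.56 ± 0.03 recovered for a planted 0.53, realness 0.53 for
0.48, duration −1.04 for −1.07 on seed 3).

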