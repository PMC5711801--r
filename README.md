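# bimphase

Relative-phase analysis and Bayesian factorial modelling of bimanual
finger oscillations.

## What this is for

In the bimanual finger-oscillation task, people rhythmically abduct and
adduct both index fingers to a metronome that ramps through ten speeds
(1.4–3.4 Hz), under instructions to move *symmetrically* (anti-phase in
external space, 180°) or in *parallel* (in-phase, 0°), with palms in the
same or different orientations, and with or without a sagittal mirror that
replaces the view of the right hand by the left hand's reflection. The
scientific questions — how strongly spatial symmetry, muscle homology and
mirrored visual feedback constrain coordination — are answered from the
**relative phase** of the two fingers, estimated once per movement cycle
and dichotomized into correct/incorrect.

`bimphase` is a tested, reusable implementation of that entire analysis
for movement scientists:

* **Kinematics** — interpolation of missing marker samples, zero-phase
  first-order Butterworth smoothing (7.5 Hz), demeaning; segmentation of
  movement cycles at the right finger's maximum→minimum intervals;
  per-cycle least-squares sine fits; relative phase as the difference of
  fitted phases, wrapped to [−90°, 270°). Quadrature and
  carrier-cross-correlation estimators are included as independent
  cross-checks, plus velocity-based movement-dimension QC.
* **Scoring** — correctness within ±50° (or a stricter ±20°) of the
  instructed target, speed pooling (slow = plateaus 1–5, fast = 6–10),
  posture pooling, 20°-bin phase histograms, congruence labels for the
  eight pooled conditions.
* **Model** — a hierarchical Bayesian logistic regression of per-cycle
  accuracy with ±1 sum-to-zero coding of the four factors and all 2-, 3-
  and 4-way interactions, participant intercept deviations, zero-centred
  normal priors whose precisions have inverse-gamma(1, 0.01) hyperpriors,
  an in-package adaptive MCMC sampler, ESS/split-Rhat diagnostics, and the
  95% highest-density-interval relevance rule:

  P(correct) = invlogit(β₀ + Σₖ βₖ·xₖ + u_participant),  xₖ ∈ {−1, +1}

* **Contrasts** — posterior-predictive cell predictions and credible
  difference distributions (mean, 95% HDI, tail fractions), including the
  twelve named homology / mirror / muscle-congruence contrasts, and
  logit↔percent conversion helpers.
* **Synthetic data** — a generator that emulates the study structure
  (20 participants, 2 sessions, 4 repetitions of 16 block conditions,
  50-beat trials at 100 Hz, ≈ 39 analyzable cycles per condition-speed
  cell per participant) with known ground truth at every stage, so the
  whole pipeline is testable end to end.

## Worked example

```r
library(bimphase)

cfg      <- sim_config(n_participants = 4, seed = 8)
sim      <- simulate_experiment(cfg)
cycles   <- analyze_experiment(sim$trajectories, sim$metadata, metronome_schedule())
outcomes <- score_cycles(cycles, sim$metadata, tolerance = 50)

round(100 * tapply(outcomes$correct, list(outcomes$instruction, outcomes$speed_pooled), mean), 1)
#>             fast slow
#> parallel    57.3 88.3
#> symmetrical 90.9 95.4

fit <- fit_model(outcomes, profile = "scaled", seed = 8)
summary(fit)[1:8, ]
#>            parameter   mean hdi_lower hdi_upper  ess           relevance
#>            intercept  1.967     0.124     3.542 1555         contributes
#>          instruction  0.839     0.770     0.912 1779         contributes
#>               mirror -0.022    -0.093     0.044 1642 does-not-contribute
#>              posture  0.125     0.055     0.196 1828         contributes
#>                speed -0.617    -0.684    -0.545 1902         contributes
#>   instruction_mirror -0.038    -0.106     0.033 1832 does-not-contribute
#>  instruction_posture  0.517     0.444     0.583 1665         contributes
#>    instruction_speed  0.277     0.212     0.349 1862         contributes

named_contrast_suite(fit)[c(2, 4, 6, 8), c("name", "mean", "hdi_lower", "hdi_upper")]
#>                                    name  mean hdi_lower hdi_upper
#>         same-different_symmetrical_fast  2.76      2.17      3.35
#>            different-same_parallel_fast  1.79      1.50      2.09
#>  mirrored-non-mirrored_symmetrical_fast  0.65      0.08      1.24
#>     mirrored-non-mirrored_parallel_fast -0.38     -0.68     -0.09
```

Reading the output: accuracy collapses for parallel movements at fast
speeds while symmetrical movements stay near ceiling; on the logit scale
the instruction weight (0.84) is the symmetry advantage, the negative
speed weight the cost of tempo, and instruction × posture (0.52) the
muscle-homology advantage. The positive `same-different_symmetrical_*`
contrasts quantify that homology advantage per instruction × speed cell;
the opposite-signed mirror contrasts show mirrored feedback helping
symmetrical but hurting parallel movement. Because baselines sit near
ceiling, use `logit_to_percent()` / `percent_point_change()` to translate
logit effects into percent-correct: e.g. a 0.26-logit gain at a 3.05-logit
baseline is worth only `percent_point_change(3.05, 0.26)` ≈ 1.0 percentage
points.

A command-line driver with `simulate`, `preprocess`, `score`, `fit`,
`contrast` and `report` subcommands wraps the same functions
(`system.file("cli", "bimphase.R", package = "bimphase")`); every stage
writes delimited-text tables plus a JSON manifest with the seed and input
digests.

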