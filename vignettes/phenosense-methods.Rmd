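---
title: "Methods: smartphone digital phenotyping for adolescent mental-health risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone digital phenotyping for adolescent mental-health risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenosense)
```

## The problem and the pipeline

phenosense implements an end-to-end pipeline for predicting binary
mental-health risk in adolescents from two weeks of smartphone data. Two data
streams enter the pipeline:

* **Active data** — daily self-report items rated 1–7 (mood, sleep quality,
  loneliness, negative thinking, and so on), a form of ecological momentary
  assessment.
* **Passive data** — eight background sensor streams (GPS location, step
  count, app usage, battery, ambient light, background noise, screen
  brightness, and usage of the sensing app itself), reduced to 92 engineered
  per-day features.

Four outcomes anchor the classification tasks, each binarized by a validated
threshold: SDQ total ≥ 16 (internalizing/externalizing risk), SCI ≤ 16
(probable insomnia; identical to < 17 on integer scores), ED-15 > 2.69
(elevated eating-disorder risk; strict inequality on the continuous 0–6
score), and any nonzero response on a 0–4 suicidal-ideation frequency item.
`binarize_outcomes()` applies these; `threshold_config()` makes them
overridable.

The modelling core is *contrastive pretraining followed by frozen-encoder
fine-tuning*. A 2-layer MLP encoder (input → 128 → 64, ReLU) plus a 2-layer
projection head (64 → 64 → 32) is trained with triplet margin loss
`max(d(a,p) − d(a,n) + m, 0)` (non-squared Euclidean distance on projection
outputs, margin m = 1) on triplets built without any outcome labels: an
anchor user-day, a positive from a different day of the same user, a negative
from a different user. This pulls a user's days together and pushes users
apart, suppressing day-to-day noise in favour of a stable per-user
behavioural signature. The encoder is then frozen and a fresh 2-layer head
(64 → 32 → 1) is trained per outcome with class-weighted binary
cross-entropy-with-logits. Day-level probabilities of a held-out user are
averaged into one user-level prediction, thresholded at 0.5.

## Feature engineering

`feature_registry()` fixes the 92 passive features (ambient light 8, app
usage 36, noise 10, battery 8, location 15, in-app usage 3, screen
brightness 8, steps 4). Choices a user of the package should know:

* **Night window** is [22:00, 06:00), half-open, in one local timezone with
  no DST. All timestamps in the package are decimal hours of a study day.
* **Location grid** is latitude/longitude rounded to 3 decimals (~111 m
  cells); location entropy is Shannon entropy in nats over that grid. Home
  is the modal night-window cell across the study, ties broken by the
  earliest-observed cell.
* **GPS jump filtering** drops fixes whose implied speed from the previously
  retained fix exceeds 200 km/h (sequential scan, first fix kept).
* **"Total" of gridded readings** (light, noise, brightness) is the sum of
  the 15-minute samples and therefore depends on the sampling rate, which is
  fixed at 15 minutes.
* **SDs are population SDs** (divide by n) throughout the feature set.
* **Registry fillers**: the printed per-category counts (36 app-usage, 15
  location) exceed the enumerable feature lists; the missing slots are
  filled with documented, semantically adjacent statistics (session-time SD
  day/night, first/last app-use hour, unique categories day/night, max
  distance from the day centroid, normalized entropy) and flagged
  `filler = TRUE` in the registry.
* **Sentinel −1** marks "unavailable" — a disabled sensor, a missed
  self-report, or an empty day. Sentinels are excluded from all statistics
  and re-inserted *after* z-scoring, so −1 always means "unavailable" on
  every scale. Step-count indicators (binary) are never z-scored.
* **Cumulative median**: the day-t value of each feature is the median of
  the user's observed values on days 1..t. A single-day outlier after three
  or more stable days cannot move it, while sustained shifts pass through.
  Days before a feature's first observation stay at the sentinel.
* **Normalization** is fitted on training rows only (means and population
  SDs of observed values) and applied to test rows with those training
  statistics; a zero training SD leaves the column centred with a unit
  divisor and a warning.

## The synthetic cohort generator

No subject-level data were deposited by the study this pipeline re-implements,
so `generate_cohort()` produces a synthetic cohort that emulates the
*published summary structure* and makes every downstream stage testable.

Latent structure: each user has a general severity factor plus four
outcome-specific factors, combined as `sqrt(0.5)·g + sqrt(0.5)·s_k`, giving a
0.5 pairwise trait correlation — the simplest structure reproducing the
published cross-outcome correlation pattern. Outcome scores are scaled
logistic transforms of trait + Gaussian noise (SD 0.6), with the intercept
solved in closed form so the binarized prevalence hits the configured target
exactly in expectation (defaults 30.1%, 33%, 36.9%, 36.9% — the published
cohort proportions).

Active items are clipped, discretized affine functions of the traits, a
shared per-user-day state, a stable per-user response style (SD 0.6), and
day noise, mapped onto 1–7 around the midpoint 4. The shared day state gives
motivation and productivity their strong day-level coupling (target r ≈ 0.7).
The response styles are what keep item–score Spearman correlations near the
published ~0.3–0.5 band: uniformly rescaling loadings cannot lower a
correlation once day noise has averaged out over two weeks, so a stable
person-level nuisance term is the realistic dilution channel (real single
items carry acquiescence and anchoring styles). They also give the
contrastive encoder a genuinely user-stable non-outcome signature to learn,
which is exactly the situation the pretraining is designed for.

Passive behaviour depends on the traits through per-modality effect sizes
(`effect_size_defaults()`; 0 = null cohort). The planted directions follow
the published association anchors: higher severity → fewer steps, more
entertainment-app time, longer app sessions, more nighttime light/brightness
exposure, quieter and less varied acoustic environments, more nighttime
battery drain and in-app sessions, and a small home-location gradient
(the published cohort showed latitude/longitude associations, a school-
geography confound we reproduce as a planted shift). Mobility follows a
two-state dwell/excursion model: dwelling places fixes exactly at the home
cell; excursions visit per-user anchor points, with the excursion rate
falling as severity rises. (The published group-difference figure reports
*higher* location entropy in the high-risk group; we kept the simpler
"severity suppresses excursions" rule, so entropy falls with severity in
synthetic data — a documented simplification; none of the nine published
correlation anchors involves entropy.)

Missingness: the fraction of users on iOS defaults to 78/103; Android-only
streams (light, app usage, noise) and the iOS-only stream (brightness) are
gated accordingly. About 35% of users enable no sensor at all; the rest draw
static Bernoulli enablement per sensor (step count and battery most common).
Active engagement decays geometrically with a constant per-day hazard
calibrated so that the expected fraction still responding on the final day
equals `active_retention_final` (default 14/103). Passive enablement is
static over the study — the published passive-engagement decline is not
modelled, a known limitation.

What passing tests on this generator do *not* show about real data: the
generator has no weekday/weekend structure, no school calendar, no weather,
no measurement drift, no platform-specific sensor biases beyond gating, and
its feature–outcome links are linear in the traits. Results on synthetic
cohorts demonstrate that the pipeline recovers planted structure at
published-magnitude association strengths — not that it would achieve the
same accuracy on a new adolescent cohort.

## Training protocol and numerical choices

* Pretraining: Adam (lr 1e-3), 3 epochs, 256 triplets per batch, epoch
  length ⌈n_rows/256⌉ batches, triplets re-sampled every batch; margin 1.0.
  Distances carry an additive 1e-12 under the square root to keep gradients
  finite at zero distance.
* Fine-tuning: Adam (lr 1e-3), 20 epochs, batch 1024, inverse-frequency
  class weights normalized to average 1. The encoder is frozen — its
  embeddings are computed once, and the test asserts bit-identity of encoder
  weights before/after.
* Hidden widths, ReLU activations and the embedding dimension are
  common-practice defaults exposed in `pretrain_config()` /
  `finetune_config()`. All layers (weights and biases) are initialised
  uniform on ±1/sqrt(fan_in) — the default of the deep-learning framework
  the training protocol was designed around. Under the short fixed
  schedules this matters: it determines how much the hidden pathways can
  move, and smaller schemes measurably prevent the combined-modality model
  from exploiting the passive block.
* The no-pretraining ablation trains the identical architecture end-to-end
  with the supervised objective (nothing frozen, no triplet phase).
* Evaluation: leave-one-subject-out cross-validation; within every fold the
  normalizer, triplet sampling, class weights, pretraining and fine-tuning
  see training rows only (asserted per fold by the audit option). Modality
  comparisons are restricted to users providing both active and passive
  data. Repetition seeds derive deterministically from one master seed and
  re-randomize both model initialisation and triplet sampling.
* Metrics: balanced accuracy is the primary metric; AUC uses the rank
  (Mann–Whitney) formulation with midranks, exact on small user counts;
  AUC-PR is the average-precision step integral. The SD across a single
  repetition is reported as 0, never dropped.
* Paired comparisons: the Wilcoxon signed-rank test is computed by exact
  enumeration (dynamic program over doubled midranks), which stays exact
  under tied differences; zero differences are dropped and all-zero input
  returns p = 1. The paired t-test is the standard closed form.
* Associations: Spearman with midranks on per-user feature *medians* across
  days (the published correlations relate features to per-user scale
  scores; medians are robust to the same outliers the cumulative median
  targets), Benjamini–Hochberg within outcome. Group differences use Welch
  two-sample t-tests on standardized user medians, with the direction of
  the difference reported; sidedness is an argument (default two-sided).
* Attributions: model-agnostic sampling Shapley on the logit scale — random
  feature permutations walked from each background row toward the evaluated
  row. Per (background, permutation) pair the attribution sum telescopes to
  f(x) − f(b), so summed attributions equal the model output minus the mean
  background output to floating-point accuracy. Validated against exhaustive
  2^d Shapley enumeration on small toys. Passive importances are summed
  within sensor categories; active items stay individual.

## Problem sizes used in the test-suite and acceptance script

The stochastic checks run at the study's published scale where it is stated:
null-calibration and signal-recovery cohorts have 100 users over 14 days,
and null calibration uses 10 LOSO repetitions in the test suite (5 in the
faster acceptance script). Signal-recovery experiments use 2 repetitions
per modality (1 in the script), the pretraining-benefit comparison uses 10
paired cohort seeds at 34 users each with doubled day noise, and the
calibration checks of the generator use 600–1000 users. These sizes are the
package's own choices balancing Monte-Carlo error against runtime. Two
properties of these estimates deserve note. First, LOSO balanced accuracies
on a single synthetic cohort carry cohort-level sampling noise of several
points: with ~30–65 evaluated users, chance associations between user-stable
behaviour and the (mutually correlated) outcome labels shift all four
outcomes' estimates coherently, so single-cohort estimates near a decision
band's edge should be read with that in mind. Second, combined-modality
estimates vary more across repetitions and cohorts than active-only ones,
because the passive block's informative columns are observed for only a
minority of users.

## What the synthetic experiments do and do not reproduce

On default-effect cohorts the pipeline recovers planted signal well above
chance for all four outcomes in all three modalities, with the combined
model typically at 0.62–0.78 balanced accuracy — the published range. The
orderings among modalities, however, are only partly reproduced: the
combined model beats passive-only essentially always, but whether it beats
active-only depends on the cohort draw, because the generator's active items
are individually stronger relative to its passive streams than appears to
have been the case in the real cohort. The published pretraining advantage
over an equally-sized end-to-end network does not reproduce on these
cohorts: with the published 3 + 20-epoch schedules, the end-to-end variant
trains strictly more parameters against the labels and matches or slightly
exceeds the frozen-encoder pipeline. The contrastive phase does do what it
claims mechanically — the within/between-user embedding distance ratio
strictly drops from the untrained to the pretrained encoder — so the
discrepancy points at properties of real behavioural data (nonstationarity,
heavy-tailed artefacts, richer user-stable structure) that the generator's
Gaussian trait model does not emulate, rather than at the implementation.

## Known limitations

* The trainer is an exact re-implementation of the published schedule (3 + 20
  epochs at fixed learning rate); with ~1000 training rows this is a small
  number of optimizer steps, so day-level probabilities stay close to 0.5
  and classification rests on the *direction* of the learned logit rather
  than calibrated probabilities.
* Passive-only models hover modestly above chance (as in the published
  study, where one outcome's passive model fell below chance); synthetic
  cohort-to-cohort variability in passive balanced accuracy is large because
  only a minority of users enable the informative sensors.
* The generator emulates summary statistics, not behaviour; see above.
* External validation applies the fixed pipeline to a held-out cohort;
  `site_shift` translates home locations, sensor baselines and opt-in rates,
  and reported metrics may legitimately degrade as the shift grows.
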