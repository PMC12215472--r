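---
title: "Confidence-driven fuzzy weighting for classifier fusion"
author: "fuzzyfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-driven fuzzy weighting for classifier fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyfuse)
```

## The problem

Automated species recognition from camera images — bird monitoring being the
motivating case — typically ends with several convolutional classifiers that
each emit a SoftMax probability vector per image. Any single model has blind
spots, and the blind spots worsen when the subject is partially occluded by
foliage, branches or shadow. Fusing the models helps, but *fixed* fusion
weights treat every image the same: a model that is unreliable on occluded
inputs keeps its full say on exactly the images where it should be ignored.

`fuzzyfuse` implements a per-sample dynamic weighting rule. For image $x$ and
models $M_1, \dots, M_M$ over $K$ classes:

$$p_i(x) = \mathrm{SoftMax}(M_i(x)), \qquad
  c_i(x) = \max_k p_i^{(k)}(x),$$

$$w(x) = \mathrm{normalize}\big(\mathrm{FIS}(c_1(x), \dots, c_M(x))\big),
  \qquad
  EP(x) = \sum_{i=1}^{M} w_i(x)\, p_i(x),$$

where $\mathrm{FIS}$ is a Mamdani fuzzy inference system mapping the vector
of per-model confidence scores to raw weights. The prediction is the argmax
of $EP(x)$. Fixed-weight averaging, mean voting and majority voting are
provided as baselines so the dynamic rule can be compared against them on
the same panels.

The package deliberately stops at the probability interface: classifiers are
upstream, their outputs arrive through a CSV/JSON exchange format, and no
network inference or training happens here.

## The fuzzy inference system

The FIS is the package's core and is fully user-definable; the default built
by `build_default_fis(M)` is the smallest system that is symmetric across
models and monotone in each confidence:

* every confidence input and every raw-weight output lives on $[0, 1]$ with
  three triangular terms — `low` $(0, 0, 0.5)$, `medium`
  $(0.25, 0.5, 0.75)$, `high` $(0.5, 1, 1)$;
* the rule base maps each model's confidence term to the same-named weight
  term for that model (`IF conf_i IS high THEN weight_i IS high`), three
  rules per model, with no cross-model antecedents;
* inference is Mamdani: rule strength is the minimum antecedent degree,
  consequent terms are clipped at the strength, per-output aggregation is
  the pointwise maximum;
* defuzzification is the centroid of the aggregated output membership on a
  discretized universe.

Several aspects of this design were genuinely open and are worth recording:

* **Membership shapes and rule count.** Any complete, symmetric term family
  would do; three triangles is the smallest family whose centroid output is
  strictly increasing in the input over the whole universe, which is the
  behaviour the method needs ("more confident models get more say") without
  further tuning. Users can replace every element through a `format: fis/1`
  YAML/JSON file (`read_fis()`/`write_fis()`).
* **Normalization after inference.** Centroid outputs are not constrained to
  sum to one, so raw weights are normalized afterwards
  (`normalize_weights()`), making $EP(x)$ a convex combination by
  construction. An all-zero raw vector (possible only with a user-supplied
  rule base that fails to fire) falls back to uniform weights rather than
  failing.
* **Per-sample vs panel-average confidences.** Both readings of
  "confidence-driven weighting" are defensible: weights can react to each
  image, or one weight vector can be derived from the panel's mean
  confidences. `fuse_panel(..., conf_mode = "per_sample")` is the default
  because it is the stronger form of adaptivity and subsumes the other;
  `conf_mode = "average"` computes the single shared vector.
* **Centroid grid step.** The output universe is discretized at `step =
  0.001`. The test suite checks the discretized centroid against a brute
  force on a 10× finer grid and sees agreement well within $10^{-3}$;
  refining further changes weights by less than the Monte-Carlo noise of
  any downstream accuracy estimate.

Tie handling is deterministic everywhere: argmax ties resolve to the lowest
class index; majority-vote ties resolve by the highest single-model
confidence among the tied classes, then the lowest index. Majority voting
reports vote shares as its "probability" vector, which is a coarser object
than the averaged distributions of the other strategies and is labelled as
such in the result.

## Evaluation metrics

`metric_report()` assembles accuracy, aggregate precision and recall, the F1
score and the average confidence score (ACS — the mean probability assigned
to the predicted class). Per-class precision/recall are one-vs-rest ratios;
the aggregate is either their unweighted mean (**macro**, the default) or
the support-weighted mean. Macro is the default because published accuracy /
precision pairs in this application area are only mutually consistent under
macro averaging (a weak model can show accuracy far above its macro
precision when a few classes collapse), and because macro exposes exactly
the per-class failures occlusion induces. The reported F1 is the harmonic
mean of the aggregate precision and recall; the per-class table carries
per-class F1 as well. Classes with an undefined ratio (zero denominator)
contribute 0 and are listed in the report rather than silently dropped.

## Statistical validation protocol

Run-level metric series (several evaluation runs per approach) are compared
with `compare_approaches()`: per approach and metric a mean, sample SD
(denominator $n-1$) and a 95% confidence interval, plus a classical one-way
ANOVA per metric across approaches, with the upper-tail F p-value.

The confidence interval uses the **normal** half width $1.96\,s/\sqrt{n}$
by default rather than the Student-t quantile. The package ships a
five-run reference benchmark (`reference_validation_runs()`) whose published
summary table follows the z convention — with $n = 5$ the t multiplier
(2.776) would widen the accuracy interval from ±0.44 to ±0.62 — so the
default reproduces that table exactly, and `student_t = TRUE` provides the
orthodox small-sample interval.

One inconsistency in that benchmark is worth flagging: its published F
statistics for the occluded-image columns (5.42 and 5.35) do not follow
from its own published run values, which give $F \approx 2.70$ (accuracy)
and $\approx 3.02$ (F1) under any one-way ANOVA; the standard-image columns
reproduce exactly. The package reports what the runs give and makes no
attempt to guess how the published occluded cells were produced.

## The prediction simulator

`simulate_panel()` exists so ensemble behaviour can be tested end-to-end
without trained networks. Its generative model:

* true labels are multinomial draws from a (default uniform) class
  distribution;
* each model predicts the true class with its profile's accuracy $a$,
  otherwise a uniformly random other class;
* the probability vector is a Dirichlet draw with concentration
  $\alpha_{top}$ on the predicted class and `spread` elsewhere, and the
  maximum coordinate is swapped onto the predicted class so the stated
  prediction is always the argmax;
* $\alpha_{top}$ is solved at run time by `calibrate_concentration()` —
  bisection on a common-random-number Monte-Carlo estimate of the expected
  maximum — so the mean confidence matches the profile's target. The solve
  is deterministic (internal fixed seed) and memoised; a runtime solve was
  preferred over a pre-computed constant table because profiles may request
  any $(K, \text{target})$ pair and interpolation error would defeat the
  ±0.02 calibration contract the tests enforce;
* the confidence-correctness link `conf_gap` makes correct predictions more
  confident than incorrect ones while preserving the overall mean
  (`conf_gap = 0` gives an uninformative confidence signal — the control
  condition under which fuzzy weighting should, and in tests does, collapse
  to mean voting);
* inter-model error correlation $\rho$ uses a shared per-sample "hardness"
  uniform: each (sample, model) correctness decision uses the shared draw
  with probability $\rho$, an independent one otherwise. $\rho$ is an
  ordinal knob, not a calibrated correlation coefficient.

What the simulator does **not** emulate: class-dependent confusion
structure (errors are uniform over wrong classes), heavy-tailed logit
behaviour, calibration drift between domains, or any image-content
dependence. Consequently, a passing simulator-backed test demonstrates the
fusion machinery's statistical behaviour under its stated assumptions — not
performance on any real photographic dataset.

The study conditions exercised by the acceptance-level tests are fixed
once: three models with accuracies $0.85, 0.85, 0.90$ and confidence
targets $0.90, 0.90, 0.95$ on $K = 10$ classes and $N = 20000$ samples for
the ensemble-lift check; the fuzzy-vs-mean comparison degrades the third
model to $a = 0.60$ (confidence target 0.75, `conf_gap = 0.25`) and uses
ten seeds at $N = 3000$ each. The per-seed size trades Monte-Carlo
resolution against suite runtime; the majority-of-seeds criterion is what
makes the comparison robust to individual-seed noise.

## Challenge-set generation

The augmentation/challenge module mirrors how robustness evaluation sets
are built for occlusion-sensitive recognition:

* `augment_image()` applies seeded zoom, shear, rotation, vertical shift
  and flips; the `"validation"` preset pins the ranges used by the validation
  protocol (rotation 10–20°, horizontal-flip probability 0.1–0.5, vertical
  shift 0–0.1, per-axis scale 0.01–0.1). The flip entry is read as a
  per-image flip *probability* drawn from its range, since a flip has no
  magnitude.
* `add_noise()` interprets "x% noise" as corruption of exactly
  `round(f · width · height)` distinct pixel positions — the only reading
  under which a percentage is well defined — set to pure black or white
  with equal probability (salt-and-pepper; a Gaussian-additive mode is the
  alternative). Presets `td1` (25–40%) and `td2` (40–50%) pin the two
  noise-challenge bands.
* `add_occluders()` composites parametric leaves (filled rotated ellipses,
  green-brown palette), branches (thick segments, bark tones) and shadows
  (semi-transparent dark convex polygons), adding shapes of nominal area
  one fifth of the coverage target until the occlusion mask reaches 97% of
  it; that stopping rule bounds the final coverage within ±20% relative of
  the target, which the tests verify per seed. The occluder geometry and
  palette are this package's own invention and are parameterized rather
  than claimed to match any particular photographic occluder. Occluders are
  placed over the frame uniformly, not aimed at the subject.
* `generate_synthetic_images()` draws procedural bird-like scenes (textured
  background, class-coloured body ellipse, head, beak triangle) purely so
  the pipeline has deterministic raster input; it makes no claim of visual
  realism.

Every randomized operation is a pure function of (input, spec, seed) — the
tests assert bit-identical PNG output under seed reuse — and augmentation
never changes image dimensions or channel count. Geometry is delegated to
EBImage; masks are boolean arrays in the same pixel coordinate frame
(origin top-left).

## Numerical conventions

* SoftMax subtracts the maximum logit before exponentiation.
* Probability vectors must sum to 1 within $10^{-6}$ on ingest and are then
  renormalized; internal arithmetic asserts $10^{-9}$.
* The prediction exchange CSV prints probabilities with 12 decimals so a
  write/read round trip is exact to the printed precision.
* Display rounding (2 decimals for percentages, means, SD, CI and F; 4 for
  p-values) happens only in `print()` methods; everything else stays at
  full precision.

## Limitations

* The default FIS is a reasonable monotone system, not a fitted one; no
  rule learning or Sugeno/TSK inference is provided.
* No probability calibration (e.g. temperature scaling) is applied to
  inputs; badly calibrated upstream models will mislead any
  confidence-driven weighting, fuzzy or otherwise.
* Majority voting's vote-share "probabilities" are not comparable to the
  averaged distributions of the other strategies.
* The simulator's independence and uniform-confusion assumptions are
  idealizations; conclusions about real datasets require real predictions
  fed through the exchange format.
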