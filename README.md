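# fuzzyfuse

Fuzzy-logic dynamic weighting for multi-classifier fusion.

## What it does, and for whom

Ecological image-recognition pipelines (bird monitoring is the motivating
application) usually end with several convolutional classifiers, each
emitting a SoftMax probability vector per image. Fusing them with *fixed*
weights ignores a useful signal: on any one image, each model also reports
how sure it is. `fuzzyfuse` is for people who have per-sample,
per-model class probabilities and want to combine them with weights that
adapt to each sample's confidence pattern — particularly when some inputs
are degraded (occlusion, noise) and the models disagree about them.

For image `x`, models `M_1..M_M` and `K` classes:

```
p_i(x) = SoftMax(M_i(x))                    per-class beliefs of model i
c_i(x) = max_k p_i^(k)(x)                   confidence score of model i
w(x)   = normalize( FIS(c_1(x),...,c_M(x)) )  dynamic weights
EP(x)  = sum_i w_i(x) * p_i(x)              ensemble probability vector
```

`FIS` is a Mamdani fuzzy inference system (triangular membership terms over
confidence, min/max inference, centroid defuzzification) that turns the
confidence vector into raw weights; the default system is symmetric across
models and monotone in each confidence, and every element of it can be
replaced through a `format: fis/1` YAML/JSON definition. Fixed-weight
averaging, mean voting and majority voting are included as baselines, along
with:

* multi-class metrics: accuracy, macro/weighted precision and recall, F1,
  average confidence score (`metric_report()`);
* a run-based statistical validation protocol: mean ± SD, 95% CI, one-way
  ANOVA F and p per metric (`compare_approaches()`);
* challenge-set generation: seeded augmentation, salt-and-pepper noise
  bands, synthetic leaf/branch/shadow occluders, class balancing, and a
  procedural image generator (`generate_synthetic_images()`);
* a calibrated simulator of multi-model classifier outputs with
  controllable accuracy, confidence informativeness and error correlation
  (`simulate_panel()`), so fusion behaviour is testable with no trained
  networks.

## Worked example

Simulate a three-model panel in which the third model is weak (60%
accuracy) but confidence is informative — correct predictions are
systematically more confident — then compare fusion strategies:

```r
library(fuzzyfuse)

profs <- list(model_profile("densenet_a", 0.85, 0.90, conf_gap = 0.25),
              model_profile("densenet_b", 0.85, 0.90, conf_gap = 0.25),
              model_profile("resnet_c",   0.60, 0.75, conf_gap = 0.25))
panel <- simulate_panel(panel_spec(10, 3000, profs, seed = 7))

for (strat in c("mean", "majority", "fuzzy")) {
  out <- fuse_panel(panel, strat)
  cat(sprintf("%-9s accuracy: %.4f\n", strat,
              mean(out$predicted_label == panel$true_labels)))
}
#> mean      accuracy: 0.9710
#> majority  accuracy: 0.9720
#> fuzzy     accuracy: 0.9760
```

The fuzzy combiner outperforms both static fusions because it down-weights
the weak model exactly on the samples where that model is unsure. The full
metric report for the fuzzy fusion:

```r
fz <- fuse_panel(panel, "fuzzy")
metric_report(panel$true_labels, fz$predicted_label, fz$confidence,
              panel$classes)
#> metric_report (macro averaging, N = 3000)
#>   A   97.60%
#>   P   97.61%
#>   R   97.60%
#>   FS  97.60%
#>   ACS 74.28%
```

A, P, R, FS are accuracy and macro precision/recall/F1; ACS is the mean
probability the ensemble assigned to its predicted class (low here because
averaging three disagreeing distributions flattens the winner's mass).

The statistical validation protocol, applied to the five-run reference
benchmark shipped with the package (`reference_validation_runs()`):

```r
compare_approaches(reference_validation_runs())
#> validation_report
#>   fixed_weight_ensemble        accuracy_standard 96.65 +/- 0.50 (SD), +/- 0.44 (95% CI), n = 5
#>   fuzzy_ensemble               accuracy_standard 97.66 +/- 0.42 (SD), +/- 0.37 (95% CI), n = 5
#>   ...
#>   accuracy_standard F(1, 8) = 11.74, p = 0.0090
#>   f1_standard F(1, 8) = 12.82, p = 0.0072
#>   accuracy_occluded F(1, 8) = 2.70, p = 0.1390
#>   f1_occluded F(1, 8) = 3.02, p = 0.1204
```

The F test says the fuzzy ensemble's standard-image advantage over the
fixed-weight ensemble is statistically significant across runs (p < 0.01).
(The benchmark's published occluded-column F statistics differ from what
its own run values give; see the vignette.)

A command-line dispatcher over the same functions is installed at
`system.file("cli", "fuzzyfuse", package = "fuzzyfuse")` with subcommands
`combine`, `evaluate`, `validate`, `simulate`, `fixture`, `augment` and
`challenge`; it exits 2 on input-format errors.

## Layout

```
R/                  data model, FIS, fusion, metrics, validation,
                    challenge-set generation, prediction simulator
inst/cli/fuzzyfuse  command-line dispatcher
inst/extdata/       five-run reference benchmark series (CSV)
scripts/acceptance.R  headline-number reproduction
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, design decisions, limits)
```
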