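# Seeded simulator of multi-model classifier outputs with controllable
# per-model accuracy, confidence profile, confidence-correctness link and
# inter-model error correlation. Probability vectors are Dirichlet draws
# peaked on the predicted class; the peak concentration is solved at run
# time so the expected top probability matches the requested confidence
# target.

.calibration_cache <- new.env(parent = emptyenv())

#' Solve the Dirichlet peak concentration for a confidence target
#'
#' Finds the concentration `alpha_top` such that a K-class Dirichlet draw
#' with one coordinate at `alpha_top` and the rest at `spread` has expected
#' maximum equal to `target` (after the maximum is placed on the predicted
#' class). Solved by bisection on a Monte-Carlo estimate with common random
#' numbers, which makes the estimate continuous and monotone in
#' `alpha_top`; the result is memoised per (K, target, spread).
#'
#' @param k Number of classes (>= 2).
#' @param target Desired mean top probability, in (1/K, 1).
#' @param spread Concentration of the non-peak coordinates (default 1).
#' @param nsim Monte-Carlo sample size for the calibration (default 2000).
#' @return The calibrated `alpha_top`.
#' @export
calibrate_concentration <- function(k, target, spread = 1, nsim = 2000) {
  if (k < 2) stopf("`k` must be >= 2")
  if (target <= 1 / k || target >= 1) {
    stopf("confidence target %.3f unattainable for K = %d (need (1/K, 1))",
          target, k)
  }
  key <- sprintf("%d|%.6f|%.4f", k, target, spread)
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  # common random numbers: fixed uniforms transformed through qgamma
  u <- with_seed(902017, matrix(stats::runif(nsim * k), nsim, k))
  mean_top <- function(alpha_top) {
    g <- matrix(stats::qgamma(u[, -1L], shape = spread), nsim, k - 1L)
    gt <- stats::qgamma(u[, 1L], shape = alpha_top)
    tot <- gt + rowSums(g)
    # the maximum coordinate is assigned to the predicted class
    mean(pmax(gt, apply(g, 1L, max)) / tot)
  }
  lo <- 1e-3; hi <- spread * (k - 1) * target / (1 - target) + 1
  while (mean_top(hi) < target) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mean_top(mid) < target) lo <- mid else hi <- mid
  }
  alpha <- (lo + hi) / 2
  .calibration_cache[[key]] <- alpha
  alpha
}

#' Describe a simulated classifier
#'
#' @param model_id Model name.
#' @param accuracy Probability of predicting the true class, in (0, 1\].
#' @param mean_confidence Target mean top probability over all samples,
#'   in (1/K, 1); checked against K at simulation time.
#' @param conf_gap Confidence-correctness link: correct predictions target
#'   `mean_confidence + (1 - accuracy) * conf_gap`, incorrect ones
#'   `conf_gap` lower, so the overall mean stays on target. `conf_gap = 0`
#'   makes confidence uninformative about correctness.
#' @param spread Dirichlet concentration of non-predicted classes.
#' @return An object of class `model_profile`.
#' @export
model_profile <- function(model_id, accuracy, mean_confidence,
                          conf_gap = 0.15, spread = 1) {
  assert_scalar_number(accuracy, "accuracy", 1e-6, 1)
  assert_scalar_number(mean_confidence, "mean_confidence", 0, 1)
  assert_scalar_number(conf_gap, "conf_gap", 0, 1)
  structure(list(model_id = as.character(model_id), accuracy = accuracy,
                 mean_confidence = mean_confidence, conf_gap = conf_gap,
                 spread = spread),
            class = "model_profile")
}

#' Describe a simulated multi-model panel
#'
#' @param n_classes Number of classes K (>= 2); class names are
#'   `class_01`, `class_02`, ...
#' @param n_samples Number of samples N.
#' @param models List of [model_profile()]s (M >= 2).
#' @param rho Inter-model error correlation in \[0, 1\]: with probability
#'   `rho` a model reuses the sample's shared "hardness" draw when deciding
#'   correctness, so errors co-occur across models; `rho = 0` gives
#'   independent errors, `rho = 1` with equal accuracies gives identical
#'   error sets.
#' @param class_probs Class distribution for the true labels (default
#'   uniform).
#' @param seed Integer seed; the whole panel is a pure function of the spec.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_classes, n_samples, models, rho = 0,
                       class_probs = NULL, seed = 1) {
  if (n_classes < 2) stopf("need >= 2 classes")
  if (!is.list(models) || length(models) < 2L) stopf("need >= 2 model profiles")
  for (m in models) stopifnot(inherits(m, "model_profile"))
  assert_scalar_number(rho, "rho", 0, 1)
  if (is.null(class_probs)) class_probs <- rep(1 / n_classes, n_classes)
  if (length(class_probs) != n_classes || any(class_probs < 0)) {
    stopf("`class_probs` must be %d non-negative values", n_classes)
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_samples = as.integer(n_samples),
                 classes = sprintf("class_%02d", seq_len(n_classes)),
                 models = models, rho = rho,
                 class_probs = class_probs / sum(class_probs),
                 seed = seed),
            class = "panel_spec")
}

#' Draw true labels for a panel spec
#'
#' @param spec A [panel_spec()].
#' @return Character vector of N seeded draws from the class distribution.
#' @export
simulate_labels <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    sample(spec$classes, spec$n_samples, replace = TRUE, prob = spec$class_probs)
  })
}

# internal: one model's N x K probability block given correctness flags
simulate_model_block <- function(labels, profile, classes, correct) {
  n <- length(labels); k <- length(classes)
  if (profile$mean_confidence <= 1 / k) {
    stopf("mean confidence target %.3f unattainable for K = %d",
          profile$mean_confidence, k)
  }
  a <- profile$accuracy
  cc <- profile$mean_confidence + (1 - a) * profile$conf_gap
  ci <- cc - profile$conf_gap
  clamp <- function(x) min(max(x, 1 / k + 0.01), 0.995)
  cc <- clamp(cc); ci <- clamp(ci)
  alpha_c <- calibrate_concentration(k, cc, profile$spread)
  alpha_i <- calibrate_concentration(k, ci, profile$spread)
  true_idx <- match(labels, classes)
  # predicted class: true when correct, else uniform among the others
  shift <- sample.int(k - 1L, n, replace = TRUE)
  pred_idx <- ifelse(correct, true_idx, 1L + (true_idx - 1L + shift) %% k)
  g <- matrix(stats::rgamma(n * k, shape = profile$spread), n, k)
  g[cbind(seq_len(n), pred_idx)] <-
    stats::rgamma(n, shape = ifelse(correct, alpha_c, alpha_i))
  probs <- g / rowSums(g)
  # guarantee the predicted class carries the maximum: swap it in if a
  # non-peak coordinate happened to dominate the draw
  mx <- max.col(probs, ties.method = "first")
  swap <- which(mx != pred_idx)
  if (length(swap) > 0L) {
    tmp <- probs[cbind(swap, mx[swap])]
    probs[cbind(swap, mx[swap])] <- probs[cbind(swap, pred_idx[swap])]
    probs[cbind(swap, pred_idx[swap])] <- tmp
  }
  list(probs = probs, pred_idx = pred_idx)
}

#' Simulate one model's prediction column
#'
#' Each sample is predicted correctly with probability `accuracy`
#' (incorrect predictions are uniform among the other classes); the
#' probability vector is a Dirichlet draw peaked on the predicted class
#' with the peak concentration calibrated to the profile's confidence
#' targets, correct predictions using a higher target than incorrect ones.
#'
#' @param labels Character vector of true labels.
#' @param profile A [model_profile()].
#' @param classes The class vocabulary.
#' @param seed Integer seed.
#' @return N x K probability matrix with one row per sample.
#' @export
simulate_model <- function(labels, profile, classes, seed = 1) {
  stopifnot(inherits(profile, "model_profile"))
  with_seed(seed, {
    correct <- stats::runif(length(labels)) <= profile$accuracy
    simulate_model_block(labels, profile, classes, correct)$probs
  })
}

#' Simulate a full multi-model prediction panel
#'
#' Draws true labels, then each model's predictions. With `rho > 0` the
#' models share a per-sample hardness draw: each (sample, model) decision
#' uses the shared draw with probability `rho` and an independent draw
#' otherwise, so hard samples produce co-occurring errors.
#'
#' @param spec A [panel_spec()].
#' @return A [prediction_panel()] with true labels.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  labels <- simulate_labels(spec)
  n <- spec$n_samples; m <- length(spec$models)
  with_seed(spec$seed + 1L, {
    hard <- stats::runif(n)
    probs <- array(NA_real_, c(n, spec$n_classes, m))
    for (j in seq_len(m)) {
      prof <- spec$models[[j]]
      use_shared <- stats::runif(n) <= spec$rho
      u <- ifelse(use_shared, hard, stats::runif(n))
      correct <- u <= prof$accuracy
      probs[, , j] <- simulate_model_block(labels, prof, spec$classes,
                                           correct)$probs
    }
    prediction_panel(probs, spec$classes,
                     vapply(spec$models, `[[`, character(1), "model_id"),
                     true_labels = labels)
  })
}
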