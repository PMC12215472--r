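# Fusion strategies combining one sample's M model probability vectors:
# weighted averaging (fixed weights), mean voting, majority voting, and the
# fuzzy-weighted combiner in which a FIS maps per-model confidence scores to
# dynamic weights.

as_panel_row <- function(panel_row) {
  if (!is.matrix(panel_row) || nrow(panel_row) < 1L || ncol(panel_row) < 2L) {
    stopf("a panel row must be an M x K matrix with M >= 1 models")
  }
  for (i in seq_len(nrow(panel_row))) {
    panel_row[i, ] <- validate_probs(panel_row[i, ], tol = 1e-6)
  }
  panel_row
}

make_ensemble_result <- function(probs, weights, strategy, classes = NULL,
                                 predicted_index = NULL) {
  probs <- probs / sum(probs)
  if (is.null(predicted_index)) predicted_index <- which.max(probs)
  structure(
    list(probs = probs, weights = weights,
         predicted_index = as.integer(predicted_index),
         predicted_label = if (!is.null(classes)) classes[predicted_index] else names(probs)[predicted_index],
         confidence = unname(probs[predicted_index]),
         strategy = strategy),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result [%s]: class %s (index %d), confidence %.4f\n",
              x$strategy,
              if (is.null(x$predicted_label)) "?" else x$predicted_label,
              x$predicted_index, x$confidence))
  invisible(x)
}

#' Weighted-averaging fusion of one sample
#'
#' Combines the M model probability vectors of one sample into the ensemble
#' probability vector \eqn{EP(x) = \sum_i w_i \, p_i(x)}, a convex
#' combination, and predicts its argmax (lowest index on ties).
#'
#' @param panel_row M x K numeric matrix: model probability vectors in rows
#'   (see [panel_row()]).
#' @param weights Numeric vector of M non-negative weights summing to 1
#'   within `1e-9` (see [normalize_weights()]).
#' @param strategy Strategy name recorded in the result.
#' @return An `ensemble_result` with fields `probs`, `weights`,
#'   `predicted_index`, `predicted_label`, `confidence`, `strategy`.
#' @export
combine_weighted <- function(panel_row, weights, strategy = "weighted") {
  panel_row <- as_panel_row(panel_row)
  if (length(weights) != nrow(panel_row)) {
    stopf("%d weights for %d models", length(weights), nrow(panel_row))
  }
  if (any(weights < -1e-12)) stopf("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stopf("weights sum to %.12f, not 1", sum(weights))
  }
  probs <- as.numeric(weights %*% panel_row)
  names(probs) <- colnames(panel_row)
  make_ensemble_result(probs, setNames(weights, rownames(panel_row)), strategy)
}

#' Mean-voting fusion of one sample
#'
#' Equivalent to [combine_weighted()] with uniform weights `1/M`.
#'
#' @inheritParams combine_weighted
#' @return An `ensemble_result`.
#' @export
mean_vote <- function(panel_row) {
  if (!is.matrix(panel_row) || nrow(panel_row) < 1L) {
    stopf("a panel row must be an M x K matrix with M >= 1 models")
  }
  m <- nrow(panel_row)
  combine_weighted(panel_row, rep(1 / m, m), strategy = "mean")
}

#' Majority-voting fusion of one sample
#'
#' Each model votes for its top class; the modal class wins. Ties are broken
#' by the highest single-model confidence among the tied classes, then by
#' the lowest class index. The reported "probabilities" are the vote shares
#' (votes / M).
#'
#' @inheritParams combine_weighted
#' @return An `ensemble_result` whose `probs` are vote shares.
#' @export
majority_vote <- function(panel_row) {
  panel_row <- as_panel_row(panel_row)
  m <- nrow(panel_row); k <- ncol(panel_row)
  votes_idx <- apply(panel_row, 1L, which.max)
  conf <- panel_row[cbind(seq_len(m), votes_idx)]
  counts <- tabulate(votes_idx, nbins = k)
  top <- which(counts == max(counts))
  if (length(top) > 1L) {
    # highest single-model confidence among tied classes, then lowest index
    best_conf <- vapply(top, function(cl) max(conf[votes_idx == cl]), numeric(1))
    top <- top[best_conf == max(best_conf)]
  }
  winner <- min(top)
  shares <- counts / m
  names(shares) <- colnames(panel_row)
  make_ensemble_result(shares, setNames(rep(1 / m, m), rownames(panel_row)),
                       "majority", predicted_index = winner)
}

#' Fuzzy-weighted fusion of one sample
#'
#' Extracts each model's confidence score (the maximum entry of its
#' probability vector), runs the fuzzy inference system to obtain raw
#' dynamic weights, normalizes them to a convex weight vector, and combines
#' the probability vectors by weighted averaging. With a symmetric rule base
#' and equal confidences this reduces exactly to [mean_vote()].
#'
#' @inheritParams combine_weighted
#' @param f A [fis()] configured for M inputs, e.g. [build_default_fis()].
#' @return An `ensemble_result`; the dynamic weights used for this sample
#'   are recorded in its `weights` field.
#' @export
fuzzy_combine <- function(panel_row, f) {
  panel_row <- as_panel_row(panel_row)
  if (fis_arity(f) != nrow(panel_row)) {
    stopf("FIS has %d inputs but the row has %d models",
          fis_arity(f), nrow(panel_row))
  }
  confidences <- apply(panel_row, 1L, max)
  w <- normalize_weights(infer_weights(confidences, f))
  combine_weighted(panel_row, w, strategy = "fuzzy")
}

#' Fuse every sample of a prediction panel
#'
#' Applies one fusion strategy to each sample and returns a tidy result
#' table in the combined-output contract: `sample_id`, `predicted_label`,
#' `confidence`, one probability column per class, one weight column per
#' model (`weight_<model>`).
#'
#' @param panel A [prediction_panel()].
#' @param strategy `"fuzzy"`, `"weighted"`, `"mean"` or `"majority"`.
#' @param weights Fixed weights for `strategy = "weighted"`.
#' @param f A [fis()] for `strategy = "fuzzy"` (default
#'   [build_default_fis()] for the panel's model count).
#' @param conf_mode For the fuzzy strategy: `"per_sample"` runs the FIS on
#'   each sample's confidences (dynamic per-sample weights); `"average"`
#'   runs it once on the panel-mean confidences and applies that single
#'   weight vector to every sample.
#' @return A `data.frame` with one row per sample; its `"strategy"`
#'   attribute records the rule used.
#' @export
fuse_panel <- function(panel,
                       strategy = c("fuzzy", "weighted", "mean", "majority"),
                       weights = NULL, f = NULL,
                       conf_mode = c("per_sample", "average")) {
  stopifnot(inherits(panel, "prediction_panel"))
  strategy <- match.arg(strategy)
  conf_mode <- match.arg(conf_mode)
  n <- length(panel$sample_ids); m <- length(panel$model_ids)
  k <- length(panel$classes)
  if (strategy == "weighted") {
    if (is.null(weights)) stopf("strategy 'weighted' needs `weights`")
    weights <- normalize_weights(weights)
  }
  fixed_w <- NULL
  if (strategy == "fuzzy") {
    if (is.null(f)) f <- build_default_fis(m)
    if (fis_arity(f) != m) stopf("FIS arity %d != %d models", fis_arity(f), m)
    if (conf_mode == "average" && n > 0L) {
      avg_conf <- rowMeans(vapply(seq_len(n),
                                  function(i) panel_confidences(panel, i),
                                  numeric(m)))
      fixed_w <- normalize_weights(infer_weights(avg_conf, f))
    }
  }
  prob_mat <- matrix(NA_real_, n, k, dimnames = list(NULL, panel$classes))
  w_mat <- matrix(NA_real_, n, m,
                  dimnames = list(NULL, paste0("weight_", panel$model_ids)))
  predicted <- character(n); confidence <- numeric(n)
  for (i in seq_len(max(n, 0L))) {
    row <- panel_row(panel, i)
    res <- switch(strategy,
      mean = mean_vote(row),
      majority = majority_vote(row),
      weighted = combine_weighted(row, weights),
      fuzzy = if (is.null(fixed_w)) fuzzy_combine(row, f)
              else combine_weighted(row, fixed_w, strategy = "fuzzy"))
    prob_mat[i, ] <- res$probs
    w_mat[i, ] <- res$weights
    predicted[i] <- panel$classes[res$predicted_index]
    confidence[i] <- res$confidence
  }
  out <- data.frame(sample_id = panel$sample_ids,
                    predicted_label = predicted,
                    confidence = confidence,
                    prob_mat, w_mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "strategy") <- strategy
  out
}

#' Write fused results in the combined-output CSV contract
#'
#' @param combined A table from [fuse_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_combined <- function(combined, path) {
  utils::write.csv(combined, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
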