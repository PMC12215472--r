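#' Numerically stable softmax
#'
#' Maps a vector of classifier logits to a normalized class-probability
#' vector, \eqn{p_k = e^{z_k} / \sum_j e^{z_j}}. The maximum logit is
#' subtracted before exponentiation, so the result is invariant to adding a
#' constant to all logits and immune to overflow.
#'
#' @param logits Numeric vector of length K >= 2; all entries must be finite.
#' @return Numeric probability vector of the same length, summing to 1.
#' @examples
#' softmax(c(1, 2, 3))
#' @export
softmax <- function(logits) {
  if (!is.numeric(logits) || length(logits) < 2L) {
    stopf("`logits` must be a numeric vector of length >= 2")
  }
  bad <- which(!is.finite(logits))
  if (length(bad) > 0L) {
    stopf("non-finite logit at index %s (value: %s)",
          bad[1L], format(logits[bad[1L]]))
  }
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Validate a class-probability vector
#'
#' Checks non-negativity and unit sum (tolerance `tol`), then renormalizes so
#' downstream arithmetic sees an exactly normalized vector.
#'
#' @param p Numeric vector of K class probabilities.
#' @param tol Allowed deviation of `sum(p)` from 1 (default `1e-6`, the
#'   ingest tolerance; internal code uses `1e-9`).
#' @return The renormalized probability vector.
#' @export
validate_probs <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || length(p) < 2L || any(!is.finite(p))) {
    stopf("probability vector must be finite numeric of length >= 2")
  }
  if (any(p < -1e-12)) stopf("probability vector has negative entries")
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stopf("probabilities sum to %.6f, not 1 (tolerance %g)", s, tol)
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Top-class prediction from a probability vector
#'
#' Returns the index of the largest class probability (lowest index on ties)
#' and the associated confidence score, i.e. the maximum SoftMax output.
#'
#' @param p A class-probability vector (validated with [validate_probs()]).
#' @return List with `index` (1-based) and `confidence` (`p[index]`).
#' @examples
#' predict_label(c(0.2, 0.5, 0.3))
#' @export
predict_label <- function(p) {
  p <- validate_probs(p, tol = 1e-6)
  idx <- which.max(p)   # which.max returns the first (lowest) maximising index
  list(index = as.integer(idx), confidence = unname(p[idx]))
}

#' Construct a prediction panel
#'
#' A prediction panel holds aligned per-sample class-probability vectors from
#' M models over a shared, ordered label vocabulary — the unit every fusion
#' strategy consumes.
#'
#' @param probs Numeric array of dimension N x K x M (samples x classes x
#'   models), or a list of M N x K matrices.
#' @param classes Character vector of K >= 2 distinct class names; its order
#'   is the canonical column order everywhere.
#' @param model_ids Character vector of M model names.
#' @param sample_ids Character vector of N sample names (default `"s1"...`).
#' @param true_labels Optional character vector of N true labels, each a
#'   member of `classes`.
#' @return An object of class `prediction_panel`.
#' @export
prediction_panel <- function(probs, classes, model_ids,
                             sample_ids = NULL, true_labels = NULL) {
  if (is.list(probs)) {
    probs <- simplify2array(probs)
    if (length(dim(probs)) == 2L) dim(probs) <- c(dim(probs), 1L)
  }
  if (!is.array(probs) || length(dim(probs)) != 3L) {
    stopf("`probs` must be an N x K x M array or list of N x K matrices")
  }
  classes <- as.character(classes)
  if (length(classes) < 2L || anyDuplicated(classes)) {
    stopf("`classes` must hold >= 2 distinct names")
  }
  model_ids <- as.character(model_ids)
  if (anyDuplicated(model_ids)) stopf("duplicate model ids")
  n <- dim(probs)[1L]; k <- dim(probs)[2L]; m <- dim(probs)[3L]
  if (k != length(classes)) stopf("probs has %d class columns, expected %d", k, length(classes))
  if (m != length(model_ids)) stopf("probs has %d model slices, expected %d", m, length(model_ids))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n)) else {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
      stopf("`sample_ids` must be %d distinct names", n)
    }
  }
  if (!is.null(true_labels)) {
    true_labels <- as.character(true_labels)
    if (length(true_labels) != n) stopf("`true_labels` must have length %d", n)
    unknown <- setdiff(stats::na.omit(true_labels), classes)
    if (length(unknown) > 0L) {
      stopf("true label '%s' is not in the vocabulary", unknown[1L])
    }
  }
  if (n > 0L) {
    for (j in seq_len(m)) {
      block <- probs[, , j, drop = FALSE]
      dim(block) <- c(n, k)
      if (any(!is.finite(block))) stopf("non-finite probability in model '%s'", model_ids[j])
      if (any(block < -1e-12)) stopf("negative probability in model '%s'", model_ids[j])
      sums <- rowSums(block)
      bad <- which(abs(sums - 1) > 1e-6)
      if (length(bad) > 0L) {
        stopf("sample %d of model '%s' has probabilities summing to %.6f",
              bad[1L], model_ids[j], sums[bad[1L]])
      }
      block <- pmax(block, 0)
      probs[, , j] <- block / rowSums(block)
    }
  }
  dimnames(probs) <- list(sample_ids, classes, model_ids)
  structure(
    list(classes = classes, model_ids = model_ids, sample_ids = sample_ids,
         true_labels = true_labels, probs = probs),
    class = "prediction_panel"
  )
}

#' @export
print.prediction_panel <- function(x, ...) {
  cat(sprintf("prediction_panel: %d samples x %d classes x %d models\n",
              length(x$sample_ids), length(x$classes), length(x$model_ids)))
  cat("  models:", paste(x$model_ids, collapse = ", "), "\n")
  cat("  true labels:", if (is.null(x$true_labels)) "absent" else "present", "\n")
  invisible(x)
}

#' Extract one sample's predictions as an M x K matrix
#'
#' @param panel A [prediction_panel()].
#' @param i Sample index or sample id.
#' @return M x K matrix (models in rows, classes in columns).
#' @export
panel_row <- function(panel, i) {
  stopifnot(inherits(panel, "prediction_panel"))
  if (is.character(i)) i <- match(i, panel$sample_ids)
  m <- t(panel$probs[i, , , drop = TRUE])
  if (length(panel$model_ids) == 1L) m <- matrix(panel$probs[i, , 1L], nrow = 1L)
  dimnames(m) <- list(panel$model_ids, panel$classes)
  m
}

#' Per-model confidence scores of one sample
#'
#' The confidence score of model i is the maximum entry of its probability
#' vector for the sample.
#'
#' @inheritParams panel_row
#' @return Named numeric vector of M confidences.
#' @export
panel_confidences <- function(panel, i) {
  apply(panel_row(panel, i), 1L, max)
}

# ---- exchange format -------------------------------------------------------

#' Write a prediction panel in the CSV exchange format
#'
#' One row per (sample, model): `sample_id,model_id,true_label,<class...>`,
#' probabilities printed with 12 decimals so a write/read round trip is exact
#' to the printed precision. A `.json` extension writes the JSON mirror.
#'
#' @param panel A [prediction_panel()].
#' @param path Output file path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(panel, path) {
  stopifnot(inherits(panel, "prediction_panel"))
  n <- length(panel$sample_ids); m <- length(panel$model_ids)
  rows <- vector("list", n * m)
  r <- 0L
  for (i in seq_len(max(n, 0L))) {
    truth <- if (is.null(panel$true_labels)) "" else panel$true_labels[i]
    for (j in seq_len(m)) {
      r <- r + 1L
      rows[[r]] <- data.frame(
        sample_id = panel$sample_ids[i], model_id = panel$model_ids[j],
        true_label = truth,
        t(panel$probs[i, , j]), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (n == 0L) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(panel$classes)),
                                    panel$classes), check.names = FALSE)
    cbind(data.frame(sample_id = character(0), model_id = character(0),
                     true_label = character(0)), empty)
  } else {
    do.call(rbind, rows)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    for (cl in panel$classes) df[[cl]] <- round(df[[cl]], 12)
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    for (cl in panel$classes) df[[cl]] <- sprintf("%.12f", df[[cl]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a prediction panel from the CSV/JSON exchange format
#'
#' Expects header `sample_id,model_id,true_label,<class_1>,...,<class_K>`;
#' the class columns define the vocabulary order. Rows whose probabilities do
#' not sum to 1 within `1e-6` are rejected with their line number.
#'
#' @param path Input file path (`.csv`, or a `.json` mirror with the same
#'   field names).
#' @return A [prediction_panel()].
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), check.names = FALSE)
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "model_id", "true_label")
  if (length(df) < 5L || !identical(names(df)[1:3], need)) {
    stopf("exchange format requires columns %s followed by >= 2 class columns",
          paste(need, collapse = ","))
  }
  classes <- names(df)[-(1:3)]
  if (anyDuplicated(classes)) stopf("duplicate class column in header")
  pm <- as.matrix(df[, classes, drop = FALSE])
  storage.mode(pm) <- "double"
  if (nrow(df) > 0L) {
    if (any(!is.finite(pm))) {
      stopf("non-numeric probability on line %d", which(rowSums(!is.finite(pm)) > 0)[1L] + 1L)
    }
    sums <- rowSums(pm)
    bad <- which(abs(sums - 1) > 1e-6)
    if (length(bad) > 0L) {
      stopf("probabilities on line %d sum to %.6f, not 1", bad[1L] + 1L, sums[bad[1L]])
    }
  }
  sample_ids <- unique(df$sample_id)
  model_ids <- unique(df$model_id)
  n <- length(sample_ids); m <- length(model_ids); k <- length(classes)
  if (nrow(df) != n * m) {
    stopf("expected %d rows (%d samples x %d models), found %d",
          n * m, n, m, nrow(df))
  }
  probs <- array(NA_real_, c(n, k, m))
  truth <- rep(NA_character_, n)
  si <- match(df$sample_id, sample_ids)
  mi <- match(df$model_id, model_ids)
  for (r in seq_len(nrow(df))) {
    if (!is.na(probs[si[r], 1L, mi[r]])) {
      stopf("duplicate (sample, model) pair on line %d", r + 1L)
    }
    probs[si[r], , mi[r]] <- pm[r, ]
    tl <- df$true_label[r]
    if (!is.na(tl) && nzchar(tl)) truth[si[r]] <- tl
  }
  if (n > 0L && any(is.na(probs))) stopf("missing model block: some (sample, model) pairs absent")
  if (all(is.na(truth))) truth <- NULL
  prediction_panel(probs, classes, model_ids, sample_ids, truth)
}
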