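# Fuzzy inference system: membership functions over model confidence,
# a Mamdani rule base, and centroid defuzzification producing the raw
# dynamic ensemble weights.

#' Create a membership function
#'
#' Piecewise-linear membership functions on \[0, 1\]: `triangular` with
#' breakpoints (a, b, c) peaking at b, or `trapezoidal` with (a, b, c, d)
#' flat at 1 between b and c. Degenerate edges (e.g. a == b) give a shoulder
#' that sits at degree 1 on the boundary, so terms such as `(0, 0, 0.5)`
#' behave like left shoulders.
#'
#' @param shape `"triangular"` or `"trapezoidal"`.
#' @param breakpoints Non-decreasing numeric vector of 3 (triangular) or 4
#'   (trapezoidal) values in \[0, 1\].
#' @return An object of class `membership_function`.
#' @export
membership_function <- function(shape = c("triangular", "trapezoidal"),
                                breakpoints) {
  shape <- match.arg(shape)
  np <- if (shape == "triangular") 3L else 4L
  if (!is.numeric(breakpoints) || length(breakpoints) != np) {
    stopf("%s membership needs %d breakpoints", shape, np)
  }
  if (is.unsorted(breakpoints)) stopf("breakpoints must be non-decreasing")
  if (any(breakpoints < 0 | breakpoints > 1)) {
    stopf("breakpoints must lie in [0, 1]")
  }
  structure(list(shape = shape, breakpoints = as.numeric(breakpoints)),
            class = "membership_function")
}

#' Membership degree of crisp values
#'
#' @param mf A [membership_function()].
#' @param x Numeric vector of crisp values.
#' @return Degrees in \[0, 1\], piecewise-linear in `x`.
#' @export
membership_degree <- function(mf, x) {
  b <- mf$breakpoints
  if (mf$shape == "triangular") {
    a <- b[1]; p <- b[2]; c <- b[3]
    left  <- if (p > a) (x - a) / (p - a) else as.numeric(x >= a)
    right <- if (c > p) (c - x) / (c - p) else as.numeric(x <= c)
    pmax(0, pmin(left, right, 1))
  } else {
    a <- b[1]; p <- b[2]; q <- b[3]; c <- b[4]
    left  <- if (p > a) (x - a) / (p - a) else as.numeric(x >= a)
    right <- if (c > q) (c - x) / (c - q) else as.numeric(x <= c)
    pmax(0, pmin(left, right, 1))
  }
}

#' Create a fuzzy (linguistic) variable
#'
#' @param name Variable name.
#' @param terms Named list of [membership_function()]s (e.g. low/medium/high).
#'   Together the terms must cover the whole \[0, 1\] universe: every point
#'   needs at least one term with positive degree.
#' @return An object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, terms) {
  if (!is.list(terms) || is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stopf("`terms` must be a named list of membership functions")
  }
  for (tm in terms) stopifnot(inherits(tm, "membership_function"))
  grid <- seq(0, 1, by = 0.001)
  cover <- Reduce(`+`, lapply(terms, membership_degree, x = grid))
  if (any(cover <= 0)) {
    stopf("terms of '%s' do not cover the whole [0,1] universe", name)
  }
  structure(list(name = name, universe = c(0, 1), terms = terms),
            class = "fuzzy_variable")
}

#' Fuzzify a crisp value
#'
#' @param value Crisp value in \[0, 1\] (values within 1e-9 outside are
#'   clamped; anything further out is rejected).
#' @param variable A [fuzzy_variable()].
#' @return Named numeric vector of membership degrees, one per term.
#' @export
fuzzify <- function(value, variable) {
  stopifnot(inherits(variable, "fuzzy_variable"))
  assert_scalar_number(value, "value")
  if (value < -1e-9 || value > 1 + 1e-9) {
    stopf("value %g outside the [0,1] universe of '%s'", value, variable$name)
  }
  value <- min(max(value, 0), 1)
  vapply(variable$terms, membership_degree, numeric(1), x = value)
}

#' Create a fuzzy rule
#'
#' Antecedent clauses are AND-combined (minimum); the consequent assigns a
#' term of one output variable.
#'
#' @param antecedent Named character vector or list: `c(conf_1 = "high")`
#'   means "conf_1 IS high"; several entries are joined by AND.
#' @param consequent Single named character: `c(weight_1 = "high")`.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent) {
  antecedent <- unlist(antecedent)
  consequent <- unlist(consequent)
  if (is.null(names(antecedent)) || any(!nzchar(names(antecedent)))) {
    stopf("antecedent clauses must be named by input variable")
  }
  if (length(consequent) != 1L || is.null(names(consequent))) {
    stopf("consequent must name exactly one output variable term")
  }
  structure(list(antecedent = antecedent, consequent = consequent),
            class = "fuzzy_rule")
}

#' Assemble a fuzzy inference system
#'
#' Mamdani system mapping M model confidences to M raw weights: rule
#' strength is the minimum antecedent degree, each consequent term is
#' clipped at that strength, per-output aggregation is the pointwise
#' maximum, and centroid defuzzification on a discretized output universe
#' yields the crisp raw weight.
#'
#' @param inputs List of [fuzzy_variable()]s, one per model confidence, in
#'   model order.
#' @param outputs List of [fuzzy_variable()]s, one raw weight each.
#' @param rules List of [fuzzy_rule()]s; every referenced variable and term
#'   must exist, and every output must be the consequent of at least one
#'   rule.
#' @param step Grid step for the discretized centroid (default 0.001).
#' @return An object of class `fuzzy_inference_system`.
#' @export
fis <- function(inputs, outputs, rules, step = 0.001) {
  for (v in c(inputs, outputs)) stopifnot(inherits(v, "fuzzy_variable"))
  in_names <- vapply(inputs, `[[`, character(1), "name")
  out_names <- vapply(outputs, `[[`, character(1), "name")
  if (anyDuplicated(c(in_names, out_names))) stopf("variable names must be distinct")
  assert_scalar_number(step, "step", 1e-6, 0.5)
  names(inputs) <- in_names
  names(outputs) <- out_names
  hit <- setNames(logical(length(outputs)), out_names)
  for (r in rules) {
    stopifnot(inherits(r, "fuzzy_rule"))
    for (v in names(r$antecedent)) {
      if (!v %in% in_names) stopf("rule references unknown input '%s'", v)
      if (!r$antecedent[[v]] %in% names(inputs[[v]]$terms)) {
        stopf("input '%s' has no term '%s'", v, r$antecedent[[v]])
      }
    }
    ov <- names(r$consequent)
    if (!ov %in% out_names) stopf("rule references unknown output '%s'", ov)
    if (!r$consequent[[1]] %in% names(outputs[[ov]]$terms)) {
      stopf("output '%s' has no term '%s'", ov, r$consequent[[1]])
    }
    hit[ov] <- TRUE
  }
  if (!all(hit)) {
    stopf("output '%s' is never the consequent of a rule", names(hit)[!hit][1L])
  }
  grid <- seq(0, 1, by = step)
  # cache output term memberships on the grid; centroid reuses them per call
  grid_mu <- lapply(outputs, function(v) {
    vapply(v$terms, membership_degree, numeric(length(grid)), x = grid)
  })
  structure(list(inputs = inputs, outputs = outputs, rules = rules,
                 defuzzifier = "centroid", step = step,
                 grid = grid, grid_mu = grid_mu),
            class = "fuzzy_inference_system")
}

#' @export
print.fuzzy_inference_system <- function(x, ...) {
  cat(sprintf("fuzzy_inference_system: %d inputs, %d outputs, %d rules, centroid step %g\n",
              length(x$inputs), length(x$outputs), length(x$rules), x$step))
  invisible(x)
}

#' Number of confidence inputs of a FIS
#' @param f A [fis()].
#' @return Integer arity.
#' @export
fis_arity <- function(f) length(f$inputs)

#' Build the default confidence-to-weight FIS
#'
#' One confidence input and one raw-weight output per model, each with
#' triangular terms low = (0, 0, 0.5), medium = (0.25, 0.5, 0.75),
#' high = (0.5, 1, 1), and a rule base that maps each model's confidence
#' term to the same-named weight term for that model (3 rules per model).
#' The construction is symmetric across models and monotone in each
#' confidence, so more confident models never receive smaller raw weights.
#'
#' @param m Number of models (>= 2).
#' @param step Centroid grid step (default 0.001).
#' @return A [fis()] with `m` inputs, `m` outputs and `3 m` rules.
#' @export
build_default_fis <- function(m, step = 0.001) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != round(m)) {
    stopf("`m` must be an integer >= 2")
  }
  m <- as.integer(m)
  terms3 <- function() list(
    low = membership_function("triangular", c(0, 0, 0.5)),
    medium = membership_function("triangular", c(0.25, 0.5, 0.75)),
    high = membership_function("triangular", c(0.5, 1, 1))
  )
  inputs <- lapply(seq_len(m), function(i) fuzzy_variable(paste0("conf_", i), terms3()))
  outputs <- lapply(seq_len(m), function(i) fuzzy_variable(paste0("weight_", i), terms3()))
  rules <- list()
  for (i in seq_len(m)) {
    for (term in c("low", "medium", "high")) {
      rules[[length(rules) + 1L]] <- fuzzy_rule(
        setNames(term, paste0("conf_", i)),
        setNames(term, paste0("weight_", i)))
    }
  }
  fis(inputs, outputs, rules, step = step)
}

#' Infer raw weights from model confidences
#'
#' Runs Mamdani inference: fuzzify each confidence, compute rule strengths
#' (min over antecedent degrees), clip each consequent term at its rule's
#' strength, aggregate per output by pointwise max, and defuzzify by the
#' discretized centroid. An output whose aggregated membership is
#' identically zero defuzzifies to 0.
#'
#' @param confidences Numeric vector in \[0, 1\], length equal to
#'   [fis_arity()].
#' @param f A [fis()].
#' @return Numeric vector of M non-negative raw weights.
#' @export
infer_weights <- function(confidences, f) {
  stopifnot(inherits(f, "fuzzy_inference_system"))
  if (length(confidences) != length(f$inputs)) {
    stopf("got %d confidences for a %d-input system",
          length(confidences), length(f$inputs))
  }
  degrees <- mapply(function(v, x) fuzzify(x, v), f$inputs, confidences,
                    SIMPLIFY = FALSE)
  out_names <- names(f$outputs)
  agg <- setNames(vector("list", length(out_names)), out_names)
  for (r in f$rules) {
    strength <- min(mapply(function(v, t) degrees[[v]][[t]],
                           names(r$antecedent), r$antecedent))
    if (strength <= 0) next
    ov <- names(r$consequent)
    clipped <- pmin(strength, f$grid_mu[[ov]][, r$consequent[[1]]])
    agg[[ov]] <- if (is.null(agg[[ov]])) clipped else pmax(agg[[ov]], clipped)
  }
  vapply(out_names, function(ov) {
    mu <- agg[[ov]]
    if (is.null(mu) || sum(mu) <= 0) return(0)
    sum(f$grid * mu) / sum(mu)
  }, numeric(1))
}

#' Normalize raw weights to a convex weight vector
#'
#' @param raw Numeric vector of non-negative raw weights.
#' @return Weights summing to 1; if the raw weights sum to less than
#'   `1e-12` the uniform vector `1/M` is returned.
#' @examples
#' normalize_weights(c(2, 2, 4))
#' @export
normalize_weights <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 1L || any(!is.finite(raw))) {
    stopf("`raw` must be finite numeric")
  }
  if (any(raw < 0)) stopf("raw weights must be non-negative")
  s <- sum(raw)
  if (s < 1e-12) return(rep(1 / length(raw), length(raw)))
  raw / s
}

# ---- serialization ---------------------------------------------------------

mf_to_list <- function(mf) list(shape = mf$shape, breakpoints = mf$breakpoints)
var_to_list <- function(v) {
  list(name = v$name, terms = lapply(v$terms, mf_to_list))
}
var_from_list <- function(l) {
  terms <- lapply(l$terms, function(t) {
    membership_function(t$shape, unlist(t$breakpoints))
  })
  fuzzy_variable(l$name, terms)
}

#' Write a FIS definition file
#'
#' Serializes the system to a versioned YAML (or JSON, by extension)
#' document with a `format: fis/1` header; [read_fis()] restores it
#' exactly.
#'
#' @param f A [fis()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_fis <- function(f, path) {
  stopifnot(inherits(f, "fuzzy_inference_system"))
  doc <- list(
    format = "fis/1",
    defuzzifier = f$defuzzifier,
    step = f$step,
    inputs = lapply(unname(f$inputs), var_to_list),
    outputs = lapply(unname(f$outputs), var_to_list),
    rules = lapply(f$rules, function(r) {
      list(`if` = as.list(r$antecedent), then = as.list(r$consequent))
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Read a FIS definition file
#'
#' @param path A `format: fis/1` YAML or JSON file written by [write_fis()]
#'   or by hand.
#' @return A [fis()].
#' @export
read_fis <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!identical(doc$format, "fis/1")) {
    stopf("unsupported FIS file format: %s", format(doc$format))
  }
  inputs <- lapply(doc$inputs, var_from_list)
  outputs <- lapply(doc$outputs, var_from_list)
  rules <- lapply(doc$rules, function(r) {
    fuzzy_rule(unlist(r$`if`), unlist(r$then))
  })
  fis(inputs, outputs, rules, step = doc$step %||% 0.001)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
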