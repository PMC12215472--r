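# Run-based statistical validation: per-approach run summaries
# (mean +/- SD, normal-approximation 95% CI) and one-way ANOVA with
# F statistic and upper-tail p-value for comparing metric series across
# ensembling approaches.

#' Summarize a run series
#'
#' Mean and sample standard deviation (denominator n - 1) of a series of
#' run-level metric values; no rounding is applied (display formatting is
#' the caller's concern).
#'
#' @param values Numeric vector of n >= 2 finite run-level values
#'   (percent scale by convention).
#' @return List with `mean`, `sd`, `n`.
#' @export
run_summary <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values))) {
    stopf("need >= 2 finite run values")
  }
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

#' 95% confidence interval for a run-series mean
#'
#' Half width `z * SD / sqrt(n)` with z = 1.96 (normal approximation) by
#' default. The orthodox small-sample interval using the Student t quantile
#' `qt(0.975, n - 1)` is available via `student_t = TRUE`; note the two can
#' differ noticeably at n = 5 (t multiplier 2.776 vs 1.96).
#'
#' @inheritParams run_summary
#' @param student_t Use the Student t quantile instead of 1.96.
#' @return List with `mean`, `sd`, `n`, `ci_low`, `ci_high`,
#'   `ci_half_width`.
#' @export
ci95 <- function(values, student_t = FALSE) {
  s <- run_summary(values)
  z <- if (student_t) stats::qt(0.975, s$n - 1) else 1.96
  hw <- z * s$sd / sqrt(s$n)
  c(s, list(ci_low = s$mean - hw, ci_high = s$mean + hw, ci_half_width = hw))
}

#' One-way ANOVA over k run series
#'
#' Classical (equal-variance) one-way analysis of variance:
#' F = MS_between / MS_within with df_between = k - 1 and
#' df_within = sum(n_g - 1). The fit is delegated to [stats::aov()]; the
#' p-value is the upper-tail F probability.
#'
#' @param groups Named list of k >= 2 numeric vectors, each with n >= 2
#'   finite values.
#' @return List with `F`, `df_between`, `df_within`, `p_value`, and
#'   `group_summaries` (one [run_summary()] row per group).
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("need >= 2 groups")
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (!is.numeric(g) || length(g) < 2L || any(!is.finite(g))) {
      stopf("group '%s' needs >= 2 finite values", nm)
    }
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  f_stat <- tab["group", "F value"]
  df1 <- tab["group", "Df"]
  df2 <- tab["Residuals", "Df"]
  summaries <- do.call(rbind, lapply(names(groups), function(nm) {
    s <- run_summary(groups[[nm]])
    data.frame(group = nm, mean = s$mean, sd = s$sd, n = s$n,
               stringsAsFactors = FALSE)
  }))
  list(F = unname(f_stat), df_between = unname(df1), df_within = unname(df2),
       p_value = f_pvalue(f_stat, df1, df2), group_summaries = summaries)
}

#' Upper-tail p-value of the F distribution
#'
#' @param f Observed F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return `P(F_{df1,df2} >= f)`.
#' @export
f_pvalue <- function(f, df1, df2) {
  assert_scalar_number(f, "f", lower = 0)
  if (df1 < 1 || df2 < 1) stopf("degrees of freedom must be >= 1")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Compare ensembling approaches over runs
#'
#' Takes a long run table (columns `approach`, `metric`, `run_id`, `value`)
#' and emits, per (approach, metric), a run summary with the 95% CI, and,
#' per metric, a one-way ANOVA across approaches — the standard layout for
#' validating that a performance difference between ensembling strategies
#' is statistically significant rather than run-to-run noise.
#'
#' @param runs `data.frame` with columns `approach`, `metric`, `run_id`,
#'   `value`.
#' @param student_t Passed to [ci95()].
#' @return An object of class `validation_report`: list with `summaries`
#'   (approach x metric rows: mean, sd, n, ci) and `anova` (one row per
#'   metric: F, dfs, p_value).
#' @export
compare_approaches <- function(runs, student_t = FALSE) {
  need <- c("approach", "metric", "run_id", "value")
  if (!is.data.frame(runs) || !all(need %in% names(runs))) {
    stopf("`runs` must have columns %s", paste(need, collapse = ", "))
  }
  approaches <- unique(runs$approach)
  metrics <- unique(runs$metric)
  for (m in metrics) {
    have <- unique(runs$approach[runs$metric == m])
    if (!setequal(have, approaches)) {
      stopf("metric '%s' is missing for approach '%s'",
            m, setdiff(approaches, have)[1L])
    }
  }
  summaries <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(approaches, function(a) {
      v <- runs$value[runs$approach == a & runs$metric == m]
      s <- ci95(v, student_t = student_t)
      data.frame(approach = a, metric = m, mean = s$mean, sd = s$sd, n = s$n,
                 ci_low = s$ci_low, ci_high = s$ci_high,
                 ci_half_width = s$ci_half_width, stringsAsFactors = FALSE)
    }))
  }))
  anova_tab <- do.call(rbind, lapply(metrics, function(m) {
    groups <- lapply(setNames(approaches, approaches), function(a) {
      runs$value[runs$approach == a & runs$metric == m]
    })
    res <- anova_oneway(groups)
    data.frame(metric = m, F = res$F, df_between = res$df_between,
               df_within = res$df_within, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }))
  structure(list(summaries = summaries, anova = anova_tab),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n")
  s <- x$summaries
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-28s %-10s %.2f +/- %.2f (SD), +/- %.2f (95%% CI), n = %d\n",
                s$approach[i], s$metric[i], s$mean[i], s$sd[i],
                s$ci_half_width[i], s$n[i]))
  }
  a <- x$anova
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-10s F(%d, %d) = %.2f, p = %.4f\n",
                a$metric[i], a$df_between[i], a$df_within[i], a$F[i],
                a$p_value[i]))
  }
  invisible(x)
}

#' Write a validation report
#'
#' @param report A [compare_approaches()] result.
#' @param json_path Output JSON path (`summaries` and `anova` keys);
#'   optional when `csv_path` is given.
#' @param csv_path Optional CSV path for the summary rows (the ANOVA rows
#'   are written next to it with an `_anova.csv` suffix).
#' @return The primary path written, invisibly.
#' @export
write_validation_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  if (is.null(json_path) && is.null(csv_path)) {
    stopf("give `json_path` and/or `csv_path`")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(summaries = report$summaries,
                              anova = report$anova),
                         json_path, dataframe = "rows", digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$summaries, csv_path, row.names = FALSE)
    utils::write.csv(report$anova,
                     sub("\\.csv$", "_anova.csv", csv_path),
                     row.names = FALSE)
  }
  invisible(if (!is.null(json_path)) json_path else csv_path)
}
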