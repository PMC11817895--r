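#' Paired comparison of plan metric tables
#'
#' Compares two per-patient metric tables (e.g. the same cohort planned on
#' two delivery systems) metric by metric with the paired Wilcoxon
#' signed-rank test. Zero differences are discarded (the standard zero-
#' discard convention); the exact distribution is used for n <= 25 untied
#' non-zero pairs and the normal approximation with continuity and tie
#' correction otherwise. All-zero difference vectors are degenerate: the
#' test is undefined and reported as p = 1 with a flag. Two-sided by
#' default. Raw p-values are reported without multiple-testing adjustment.
#'
#' @param a,b Data frames with an identifier column (`by`) and one numeric
#'   column per metric; same patients, same ordering requirement is enforced
#'   by joining on `by`.
#' @param by Identifier column name; default `"patient_id"`.
#' @param metrics Metric columns to compare; default all shared numeric
#'   columns.
#' @param alpha Significance level for the `significant` flag; default 0.05.
#' @return A tibble of class `plan_comparison`: `metric`, `n`, `n_nonzero`,
#'   `statistic` (V, sum of positive ranks), `p_value`, `method`,
#'   `significant`, `degenerate`.
#' @export
compare_plans <- function(a, b, by = "patient_id", metrics = NULL,
                          alpha = 0.05) {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  if (!by %in% names(a) || !by %in% names(b)) {
    abort(sprintf("Both tables need the identifier column '%s'.", by))
  }
  if (nrow(a) != nrow(b) || !setequal(a[[by]], b[[by]])) {
    abort("Cohorts differ: the two tables must cover the same patients.")
  }
  if (is.null(metrics)) {
    metrics <- intersect(names(a), names(b))
    metrics <- metrics[metrics != by]
    metrics <- metrics[vapply(a[metrics], is.numeric, TRUE) &
                         vapply(b[metrics], is.numeric, TRUE)]
  }
  if (!length(metrics)) abort("No shared numeric metric columns to compare.")
  merged <- dplyr::inner_join(a[, c(by, metrics)], b[, c(by, metrics)],
                              by = by, suffix = c("_a", "_b"))
  rows <- purrr::map(metrics, function(m) {
    x <- merged[[paste0(m, "_a")]]
    y <- merged[[paste0(m, "_b")]]
    n <- sum(stats::complete.cases(x, y))
    if (n < 6) {
      abort(sprintf("Metric '%s': need >= 6 paired observations, got %d.", m, n))
    }
    res <- signed_rank_test(x, y)
    tibble::tibble(
      metric = m, n = n, n_nonzero = res$n_nonzero,
      statistic = res$statistic, p_value = res$p_value, method = res$method,
      significant = !res$degenerate & res$p_value < alpha,
      degenerate = res$degenerate
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("plan_comparison", class(out))
  out
}

#' Paired Wilcoxon signed-rank test with explicit conventions
#'
#' Thin wrapper over [stats::wilcox.test()] fixing the conventions used
#' throughout this package: two-sided, zero differences discarded, exact
#' distribution for n <= 25 non-zero untied pairs, normal approximation
#' with continuity and tie correction otherwise; an all-zero difference
#' vector returns p = 1 flagged as degenerate rather than an error.
#'
#' @param x,y Paired numeric vectors.
#' @return List: `statistic` (V), `p_value`, `n_nonzero`, `method`
#'   (`"exact"`, `"normal-approximation"` or `"degenerate"`), `degenerate`.
#' @export
signed_rank_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  nz <- d[d != 0]
  if (!length(nz)) {
    return(list(statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  use_exact <- length(nz) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(nz, exact = use_exact, correct = TRUE)
  )
  list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_nonzero = length(nz),
    method = if (use_exact) "exact" else "normal-approximation",
    degenerate = FALSE
  )
}

#' @export
print.plan_comparison <- function(x, ...) {
  cat(sprintf("<plan_comparison> %d metric(s), alpha = %g\n",
              nrow(x), attr(x, "alpha") %||% 0.05))
  NextMethod()
}

#' Tidy a plan comparison
#'
#' @param x A `plan_comparison`.
#' @param ... Unused.
#' @return The comparison as a plain tibble.
#' @export
tidy.plan_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarize a plan comparison
#'
#' @param x A `plan_comparison`.
#' @param ... Unused.
#' @return One-row tibble: number of metrics, significant count, minimum
#'   p-value.
#' @export
glance.plan_comparison <- function(x, ...) {
  tibble::tibble(
    n_metrics = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    min_p_value = min(x$p_value, na.rm = TRUE),
    alpha = attr(x, "alpha") %||% 0.05
  )
}
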