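#' Parse a clinical-goal expression
#'
#' Goals are written the way constraint tables print them:
#' `"Dmax < 10 Gy"`, `"Dmax < 120%"`, `"Dmean < 5 Gy"`, `"D50% < 20 Gy"`,
#' `"V12 Gy < 3 cm3"`, `"V100% > 95%"`. `Dmax` denotes the near-maximum
#' dose D0.01cc (see [max_dose()]); a percent threshold on a D-metric is
#' relative to the prescription dose.
#'
#' @param text Goal string.
#' @param structure Structure the goal applies to.
#' @param fractions Fraction count this goal applies to (`NA` = any).
#' @param advisory Logical; advisory goals are reported but never pass/fail
#'   (used for as-low-as-reasonably-achievable entries).
#' @return A one-row tibble (class `goal_spec`) with columns `structure`,
#'   `metric`, `metric_arg`, `comparator`, `threshold`, `unit`, `fractions`,
#'   `advisory`, `text`.
#' @export
parse_goal <- function(text, structure, fractions = NA_integer_,
                       advisory = FALSE) {
  s <- gsub("\\s+", " ", trimws(text))
  m <- regmatches(s, regexec(
    "^(Dmax|Dmean|D([0-9.]+) ?%|V([0-9.]+) ?Gy|V([0-9.]+) ?%) ?([<>]) ?([0-9.]+) ?(Gy|%|cm3|cc)$",
    s
  ))[[1]]
  if (!length(m)) {
    abort(sprintf("Cannot parse goal '%s' for structure '%s'.", text, structure))
  }
  token <- m[2]
  metric <- if (token == "Dmax") "Dmax"
  else if (token == "Dmean") "Dmean"
  else if (m[3] != "") "Dx%"
  else if (m[4] != "") "VxGy"
  else "Vx%"
  arg <- suppressWarnings(as.numeric(c(m[3], m[4], m[5])[c(m[3], m[4], m[5]) != ""][1]))
  unit <- if (m[8] == "cc") "cm3" else m[8]
  valid <- switch(metric,
    "Dmax" = unit %in% c("Gy", "%"),
    "Dmean" = unit %in% c("Gy", "%"),
    "Dx%" = unit %in% c("Gy", "%"),
    "VxGy" = unit == "cm3",
    "Vx%" = unit == "%"
  )
  if (!valid) {
    abort(sprintf("Goal '%s': unit '%s' is not valid for metric %s.", text, unit, metric))
  }
  threshold <- as.numeric(m[7])
  if (!is.finite(threshold) || threshold <= 0) {
    abort(sprintf("Goal '%s': threshold must be > 0.", text))
  }
  out <- tibble::tibble(
    structure = structure, metric = metric,
    metric_arg = if (metric %in% c("Dmax", "Dmean")) NA_real_ else arg,
    comparator = m[6], threshold = threshold, unit = unit,
    fractions = as.integer(fractions), advisory = isTRUE(advisory), text = s
  )
  class(out) <- c("goal_spec", class(out))
  out
}

#' Read a clinical-goal table from YAML or JSON
#'
#' The config mirrors a printed constraint table: a list of entries with
#' `structure`, `goal` (the printed expression, e.g. `"Dmax < 13 Gy"`),
#' optional `fractions` (integer; omitted = applies to any fractionation)
#' and optional `advisory`. Parse errors name the offending entry.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return A `goal_spec` tibble, one row per goal.
#' @export
read_goal_table <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  entries <- cfg$goals %||% cfg
  rows <- purrr::imap(entries, function(e, i) {
    if (is.null(e$structure) || is.null(e$goal)) {
      abort(sprintf("Goal table entry %d: needs `structure` and `goal`.", i))
    }
    tryCatch(
      parse_goal(e$goal, e$structure,
                 fractions = e$fractions %||% NA_integer_,
                 advisory = e$advisory %||% FALSE),
      error = function(err) {
        abort(sprintf("Goal table entry %d (%s): %s", i, e$structure,
                      conditionMessage(err)))
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("goal_spec", class(out))
  out
}

#' Evaluate clinical goals against a plan
#'
#' Computes the achieved value for every goal applicable to the plan's
#' fractionation, compares it to the threshold, and reports pass/fail with
#' the margin (achieved minus threshold, in threshold units). `Dmax` is the
#' near-maximum dose to the hottest 0.01 cm^3 by default (`dmax_mode =
#' "d001cc"`); `dmax_mode = "voxel"` switches to the single hottest voxel.
#' Percent thresholds on dose metrics are relative to the prescription.
#' Goals for structures absent from the plan are reported with `achieved =
#' NA` and `passed = NA`. Advisory goals are never pass/fail.
#'
#' @param plan An [rt_plan()].
#' @param goals A `goal_spec` tibble from [read_goal_table()] or
#'   [parse_goal()].
#' @param dmax_mode `"d001cc"` (default) or `"voxel"`.
#' @return A tibble of class `goal_report`: the goal columns plus
#'   `achieved`, `passed`, `margin`.
#' @export
evaluate_goals <- function(plan, goals, dmax_mode = c("d001cc", "voxel")) {
  dmax_mode <- match.arg(dmax_mode)
  goals <- dplyr::filter(
    goals,
    is.na(.data$fractions) | .data$fractions == plan$n_fractions
  )
  rows <- purrr::pmap(goals, function(structure, metric, metric_arg, comparator,
                                      threshold, unit, fractions, advisory,
                                      text, ...) {
    if (!structure %in% names(plan$structures)) {
      return(tibble::tibble(achieved = NA_real_, passed = NA))
    }
    dvh <- cumulative_dvh(plan, structure)
    gy_value <- switch(metric,
      "Dmax" = if (dmax_mode == "d001cc") {
        max_dose(dvh)
      } else {
        dvh$dose_gy[1]
      },
      "Dmean" = mean_dose(plan, structure),
      "Dx%" = dose_at_volume(dvh, metric_arg),
      NA_real_
    )
    achieved <- switch(metric,
      "VxGy" = volume_at_dose(dvh, dose_gy = metric_arg),
      "Vx%" = 100 * sum(dvh$volume_cc[dvh$dose_gy >= metric_arg / 100 * plan$rx_dose]) /
        attr(dvh, "total_volume_cc"),
      if (unit == "%") normalized_dose(gy_value, plan$rx_dose) else gy_value
    )
    passed <- if (advisory) NA else if (comparator == "<") {
      achieved < threshold
    } else {
      achieved > threshold
    }
    tibble::tibble(achieved = achieved, passed = passed)
  })
  out <- dplyr::bind_cols(goals, dplyr::bind_rows(rows))
  out <- dplyr::mutate(out, margin = .data$achieved - .data$threshold)
  class(out) <- c("goal_report", class(out))
  out
}

#' Write a goal report with stable formatting
#'
#' Deterministic bytes for a given plan and goal table: rows keep the table
#' order and floats are printed with a fixed format, so identical inputs
#' produce identical report files. A footer records that `Dmax` means the
#' dose to the hottest 0.01 cm^3 and that p-values/goals carry no
#' multiple-testing adjustment.
#'
#' @param report A `goal_report` from [evaluate_goals()].
#' @param path Output file; format from extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_goal_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.6g", x)))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(
        units = list(length = "mm", dose = "Gy", volume = "cm3"),
        dmax_definition = "dose to hottest 0.01 cm3",
        multiple_testing = "none",
        goals = df
      ),
      path, auto_unbox = TRUE, pretty = TRUE, na = "null"
    )
  } else {
    write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Plot a goal report
#'
#' Bar chart of achieved value relative to threshold (percent of threshold),
#' colored by pass/fail.
#'
#' @param object A `goal_report`.
#' @param ... Unused.
#' @export
autoplot.goal_report <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$achieved))
  df$label <- paste(df$structure, df$text)
  ggplot2::ggplot(df, ggplot2::aes(
    x = 100 * .data$achieved / .data$threshold,
    y = stats::reorder(.data$label, .data$achieved / .data$threshold),
    fill = .data$passed
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 100, linetype = 2) +
    ggplot2::labs(x = "Achieved (% of threshold)", y = NULL, fill = "Passed") +
    ggplot2::theme_minimal()
}
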