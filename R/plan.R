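#' Assemble a treatment plan
#'
#' A plan bundles a dose grid, a structure set, and the prescription
#' (dose in Gy and fraction count). All structures must share the dose grid's
#' geometry; resample the dose onto the structure grid first with
#' [align_dose_to_grid()] if they differ. `primary_target` must name exactly
#' one structure with role `"target"`; its volume is the TV used by the
#' gradient and conformity metrics.
#'
#' @param dose A [dose_grid()].
#' @param structures A list of [structure_mask()] objects (names taken from
#'   the structures themselves).
#' @param rx_dose Prescription dose in Gy (> 0).
#' @param n_fractions Number of fractions (>= 1).
#' @param primary_target Name of the primary target structure. Defaults to
#'   the single target-role structure if unambiguous.
#' @return An object of class `rt_plan`.
#' @export
rt_plan <- function(dose, structures, rx_dose, n_fractions = 1L,
                    primary_target = NULL) {
  if (!inherits(dose, "dose_grid")) abort("`dose` must be a dose_grid.")
  if (inherits(structures, "structure_mask")) structures <- list(structures)
  if (!length(structures) || !all(vapply(structures, inherits, TRUE, "structure_mask"))) {
    abort("`structures` must be a list of structure_mask objects.")
  }
  names(structures) <- vapply(structures, `[[`, "", "name")
  if (anyDuplicated(names(structures))) abort("Structure names must be unique.")
  for (s in structures) {
    if (!same_geometry(dose, s)) {
      abort(sprintf(
        "Structure '%s' is not on the dose grid; resample the dose first.",
        s$name
      ))
    }
  }
  rx_dose <- as.numeric(rx_dose)
  if (!is.finite(rx_dose) || rx_dose <= 0) abort("`rx_dose` must be > 0 Gy.")
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L) abort("`n_fractions` must be >= 1.")
  targets <- names(structures)[vapply(structures, `[[`, "", "role") == "target"]
  if (is.null(primary_target)) {
    if (length(targets) != 1L) {
      abort("`primary_target` is required when the plan has != 1 target structure.")
    }
    primary_target <- targets
  }
  if (!primary_target %in% targets) {
    abort(sprintf("`primary_target` '%s' is not a target-role structure.", primary_target))
  }
  structure(
    list(
      dose = dose, structures = structures, rx_dose = rx_dose,
      n_fractions = n_fractions, primary_target = primary_target
    ),
    class = "rt_plan"
  )
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf(
    "<rt_plan> Rx %.4g Gy in %d fx, primary target '%s'\n",
    x$rx_dose, x$n_fractions, x$primary_target
  ))
  print(x$dose)
  for (s in x$structures) print(s)
  invisible(x)
}

#' Fetch a structure from a plan by name
#'
#' @param plan An [rt_plan()].
#' @param structure Structure name.
#' @export
plan_structure <- function(plan, structure) {
  s <- plan$structures[[structure]]
  if (is.null(s)) {
    abort(sprintf("Plan has no structure named '%s'.", structure))
  }
  s
}

#' Dose values inside a structure
#'
#' @inheritParams plan_structure
#' @return Numeric vector of per-voxel doses (Gy) inside the mask.
#' @export
structure_doses <- function(plan, structure) {
  s <- plan_structure(plan, structure)
  plan$dose$values[s$mask]
}

#' One-row summary of plan-quality metrics
#'
#' Computes the standard plan-quality panel for the primary target: target
#' volume (cm^3), V100% coverage (%), Paddick and RTOG conformity indices,
#' homogeneity index, gradient index, near-maximum dose D0.01cc (Gy and %Rx).
#'
#' @param x An [rt_plan()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.rt_plan <- function(x, ...) {
  tv <- structure_volume_cc(plan_structure(x, x$primary_target))
  dmax <- max_dose(x, x$primary_target)
  tibble::tibble(
    rx_dose_gy = x$rx_dose,
    n_fractions = x$n_fractions,
    target = x$primary_target,
    target_volume_cc = tv,
    coverage_pct = coverage(x, x$primary_target),
    paddick_ci = paddick_ci(x),
    rtog_ci = rtog_ci(x),
    homogeneity_index = homogeneity_index(x, x$primary_target),
    gradient_index = gradient_index(x),
    dmax_001cc_gy = dmax,
    dmax_001cc_pct_rx = normalized_dose(dmax, x$rx_dose)
  )
}
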