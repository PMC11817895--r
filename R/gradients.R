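#' Steepest border gradient profile, SBG(x)
#'
#' The steepest border gradient at the x%Rx isodose level is the highest
#' percent-of-prescription dose fall-off per millimetre realized anywhere on
#' the border: `SBG(x) = (100 - x) / d_min(x)` in %Rx/mm, where `d_min(x)`
#' is the shortest 3D distance from the x% prescription isodose surface to
#' the prescription (100%) isodose surface. Distances are recorded for the
#' 50-90%Rx levels by default and converted to %/mm. Levels whose isodose
#' surface does not exist in the grid are skipped with a warning; levels
#' whose surfaces are truncated by the grid are flagged (`truncated`), where
#' the distance is a lower bound and the SBG an upper bound.
#'
#' @param plan An [rt_plan()].
#' @param levels Percent-of-Rx levels; default `c(50, 60, 70, 80, 90)`.
#' @param component `"all"` (default) measures the shortest distance over
#'   all connected components of each isodose surface; `"nearest"` restricts
#'   the x% surface to the component nearest the primary target (useful when
#'   satellite low-dose islands exist far from the target).
#' @return A tibble of class `c("sbg_profile", "gradient_profile")` with
#'   columns `level_pct`, `d_min_mm`, `sbg_pct_per_mm`, `truncated`.
#' @export
sbg_profile <- function(plan, levels = seq(50, 90, by = 10),
                        component = c("all", "nearest")) {
  component <- match.arg(component)
  rx_surface <- extract_isodose(plan$dose, plan$rx_dose)
  rows <- purrr::map(levels, function(x) {
    level <- plan$rx_dose * x / 100
    surf <- tryCatch(extract_isodose(plan$dose, level), error = function(e) NULL)
    if (is.null(surf) || !nrow(surf$vertices)) {
      warn(sprintf("No %g%%Rx isodose surface in the grid; level skipped.", x))
      return(NULL)
    }
    comps <- NULL
    if (component == "nearest") {
      comps <- nearest_component(surf, plan)
    }
    d <- min_surface_distance(surf, rx_surface, components = comps)
    tibble::tibble(
      level_pct = x,
      d_min_mm = as.numeric(d),
      sbg_pct_per_mm = (100 - x) / as.numeric(d),
      truncated = isTRUE(attr(d, "lower_bound"))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "rx_dose") <- plan$rx_dose
  class(out) <- c("sbg_profile", "gradient_profile", class(out))
  out
}

# id of the surface component whose vertices come closest to the target mask
nearest_component <- function(surface, plan) {
  s <- plan_structure(plan, plan$primary_target)
  sub <- which(s$mask, arr.ind = TRUE)
  ax <- grid_axes(s)
  pts <- cbind(ax$x[sub[, 1]], ax$y[sub[, 2]], ax$z[sub[, 3]])
  comps <- sort(unique(surface$vertex_component))
  comps <- comps[comps > 0]
  if (length(comps) <= 1) return(comps)
  dists <- vapply(comps, function(cid) {
    pv <- surface$vertices[surface$vertex_component == cid, , drop = FALSE]
    min_pointset_distance_cpp(pv, pts, max(s$spacing) * 4)
  }, numeric(1))
  comps[which.min(dists)]
}

#' Volume gradient profile, VG(x)
#'
#' `VG(x) = VOL(x%Rx) / TV`: the volume enclosed by the x% prescription
#' isodose surface (all connected components) over the primary target
#' volume. VG measures how fast dose spreads in volume outside the target
#' and is profiled from the 100% Rx level down to the 20% level by default.
#' VG at 100%Rx is the RTOG conformity index. Levels whose isodose region
#' touches the grid boundary are flagged: the volume is then a lower bound.
#'
#' @param plan An [rt_plan()].
#' @param levels Percent-of-Rx levels; default `seq(20, 100, by = 10)`.
#' @return A tibble of class `c("vg_profile", "gradient_profile")` with
#'   columns `level_pct`, `volume_cc`, `vg`, `truncated`.
#' @export
vg_profile <- function(plan, levels = seq(20, 100, by = 10)) {
  tv <- structure_volume_cc(plan_structure(plan, plan$primary_target))
  if (tv <= 0) abort("Primary target volume must be > 0.")
  vv <- voxel_volume_cc(plan$dose)
  v <- plan$dose$values
  d <- dim(v)
  rows <- purrr::map(sort(levels, decreasing = TRUE), function(x) {
    level <- plan$rx_dose * x / 100
    above <- v >= level
    n_above <- sum(above)
    if (n_above == 0) {
      warn(sprintf("No voxels at or above %g%%Rx; level skipped.", x))
      return(NULL)
    }
    trunc <- any(above[1, , ]) || any(above[d[1], , ]) ||
      any(above[, 1, ]) || any(above[, d[2], ]) ||
      any(above[, , 1]) || any(above[, , d[3]])
    tibble::tibble(
      level_pct = x,
      volume_cc = n_above * vv,
      vg = n_above * vv / tv,
      truncated = trunc
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "rx_dose") <- plan$rx_dose
  attr(out, "target_volume_cc") <- tv
  class(out) <- c("vg_profile", "gradient_profile", class(out))
  out
}

#' Traditional gradient index
#'
#' `GI = VOL(50%Rx) / VOL(100%Rx)`, the ratio of the volume enclosed by the
#' 50% prescription isodose to the volume enclosed by the prescription
#' isodose; identically `VG(50) / VG(100)`.
#'
#' @param plan An [rt_plan()].
#' @return Dimensionless GI.
#' @export
gradient_index <- function(plan) {
  vg <- vg_profile(plan, levels = c(50, 100))
  if (nrow(vg) < 2) abort("Both the 50%% and 100%%Rx isodose volumes are required.")
  vg$vg[vg$level_pct == 50] / vg$vg[vg$level_pct == 100]
}

#' Paddick and RTOG conformity indices
#'
#' `paddick_ci()` computes `PCI = TV_PIV^2 / (TV * PIV)`, where TV is the
#' target volume, PIV the volume enclosed by the prescription isodose, and
#' TV_PIV the target volume covered by the prescription isodose. PCI is at
#' most 1.0, with 1.0 indicating perfect conformity. `rtog_ci()` computes
#' `PIV / TV` (1.0 is ideal; > 1 over-covers, < 1 under-covers). All three
#' volumes use the same voxel-center counting rule, so `rtog_ci()` equals
#' `VG(100)` exactly and PCI = 1 exactly when the prescription isodose
#' region coincides with the target.
#'
#' @param plan An [rt_plan()].
#' @return Dimensionless index.
#' @export
paddick_ci <- function(plan) {
  s <- plan_structure(plan, plan$primary_target)
  piv_mask <- plan$dose$values >= plan$rx_dose
  n_t <- sum(s$mask)
  n_p <- sum(piv_mask)
  if (n_p == 0) abort("Prescription isodose volume is empty.")
  n_tp <- sum(s$mask & piv_mask)
  (n_tp^2) / (n_t * n_p)
}

#' @rdname paddick_ci
#' @export
rtog_ci <- function(plan) {
  s <- plan_structure(plan, plan$primary_target)
  piv_mask <- plan$dose$values >= plan$rx_dose
  n_p <- sum(piv_mask)
  if (n_p == 0) abort("Prescription isodose volume is empty.")
  n_p / sum(s$mask)
}

#' Combined gradient report
#'
#' One tidy table with the SBG and VG profiles of a plan, suitable for CSV
#' or JSON export: columns `level_pct`, `d_min_mm`, `sbg_pct_per_mm`,
#' `volume_cc`, `vg`, `truncated`.
#'
#' @param plan An [rt_plan()].
#' @param sbg_levels,vg_levels Level grids for the two profiles.
#' @inheritParams sbg_profile
#' @return A tibble of class `gradient_report`.
#' @export
gradient_report <- function(plan, sbg_levels = seq(50, 90, by = 10),
                            vg_levels = seq(20, 100, by = 10),
                            component = c("all", "nearest")) {
  sbg <- sbg_profile(plan, sbg_levels, component = component)
  vg <- vg_profile(plan, vg_levels)
  out <- dplyr::full_join(
    dplyr::rename(sbg, truncated_sbg = "truncated"),
    dplyr::rename(vg, truncated_vg = "truncated"),
    by = "level_pct"
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$level_pct))
  out <- dplyr::mutate(
    out,
    truncated = dplyr::coalesce(.data$truncated_sbg, FALSE) |
      dplyr::coalesce(.data$truncated_vg, FALSE),
    truncated_sbg = NULL, truncated_vg = NULL
  )
  class(out) <- c("gradient_report", "gradient_profile", class(out))
  out
}

#' Plot a gradient profile
#'
#' SBG profiles plot %Rx/mm against the isodose level; VG profiles plot the
#' (dimensionless, log-scaled) volume ratio against the level.
#'
#' @param object An `sbg_profile`, `vg_profile` or `gradient_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gradient_profile <- function(object, ...) {
  if ("sbg_pct_per_mm" %in% names(object) && !"vg" %in% names(object)) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(.data$level_pct, .data$sbg_pct_per_mm)) +
        ggplot2::geom_line() +
        ggplot2::geom_point(ggplot2::aes(shape = .data$truncated)) +
        ggplot2::labs(x = "Isodose level (%Rx)", y = "SBG (%Rx/mm)") +
        ggplot2::theme_minimal()
    )
  }
  if ("vg" %in% names(object) && !"sbg_pct_per_mm" %in% names(object)) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(.data$level_pct, .data$vg)) +
        ggplot2::geom_line() +
        ggplot2::geom_point(ggplot2::aes(shape = .data$truncated)) +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "Isodose level (%Rx)", y = "VG = VOL(%Rx)/TV") +
        ggplot2::theme_minimal()
    )
  }
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("level_pct", "sbg_pct_per_mm", "vg")],
    c("sbg_pct_per_mm", "vg"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(stats::na.omit(long),
                  ggplot2::aes(.data$level_pct, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Isodose level (%Rx)", y = NULL) +
    ggplot2::theme_minimal()
}
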