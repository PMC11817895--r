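#' Exact cumulative dose-volume histogram
#'
#' Builds the cumulative DVH of a structure from the sorted per-voxel doses
#' with no binning: every voxel contributes its own volume at its own dose,
#' so downstream metrics carry no bin-width tolerance. Partial-volume voxels
#' are not modeled (a voxel is in or out per the mask).
#'
#' @param plan An [rt_plan()].
#' @param structure Structure name.
#' @return A tibble of class `dvh_curve`, one row per voxel, sorted by
#'   descending dose, with columns `dose_gy`, `volume_cc` (this voxel),
#'   `cum_volume_cc` (volume receiving at least `dose_gy`) and
#'   `cum_volume_pct`. Attributes: `structure`, `total_volume_cc`, `rx_dose`.
#' @examples
#' \dontrun{
#' dvh <- cumulative_dvh(plan, "PTV")
#' dose_at_volume(dvh, 50) # median dose
#' }
#' @export
cumulative_dvh <- function(plan, structure) {
  s <- plan_structure(plan, structure)
  doses <- structure_doses(plan, structure)
  if (!length(doses)) abort(sprintf("Structure '%s' is empty.", structure))
  vv <- voxel_volume_cc(s)
  ord <- order(doses, decreasing = TRUE)
  doses <- doses[ord]
  total <- vv * length(doses)
  out <- tibble::tibble(
    dose_gy = doses,
    volume_cc = vv,
    cum_volume_cc = cumsum(rep(vv, length(doses))),
    cum_volume_pct = 100 * cumsum(rep(vv, length(doses))) / total
  )
  attr(out, "structure") <- s$name
  attr(out, "total_volume_cc") <- total
  attr(out, "rx_dose") <- plan$rx_dose
  class(out) <- c("dvh_curve", class(out))
  out
}

new_dvh_from_voxels <- function(doses, volumes, structure = "structure",
                                rx_dose = NA_real_) {
  ord <- order(doses, decreasing = TRUE)
  doses <- doses[ord]
  volumes <- rep(volumes, length.out = length(doses))[ord]
  total <- sum(volumes)
  out <- tibble::tibble(
    dose_gy = doses,
    volume_cc = volumes,
    cum_volume_cc = cumsum(volumes),
    cum_volume_pct = 100 * cumsum(volumes) / total
  )
  attr(out, "structure") <- structure
  attr(out, "total_volume_cc") <- total
  attr(out, "rx_dose") <- rx_dose
  class(out) <- c("dvh_curve", class(out))
  out
}

as_dvh <- function(x, structure) {
  if (inherits(x, "dvh_curve")) x else cumulative_dvh(x, structure)
}

#' Dose to the hottest x% of a structure (Dx)
#'
#' Dx is the dose received by the hottest x percent of the structure volume
#' on the cumulative DVH: the smallest dose d such that the volume receiving
#' at least d does not exceed x% of the total, with linear interpolation
#' between adjacent sorted voxel doses. D100 is the minimum voxel dose; as
#' x tends to 0 the value tends to the maximum voxel dose.
#'
#' @param dvh A `dvh_curve` from [cumulative_dvh()].
#' @param x Percent of structure volume, in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, x) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 100)) {
    abort("`x` must be in (0, 100].")
  }
  total <- attr(dvh, "total_volume_cc")
  dose_at_absolute_volume(dvh, x / 100 * total)
}

# dose at an absolute cumulative volume (cm^3), linear between sorted voxels
dose_at_absolute_volume <- function(dvh, v_cc) {
  cumv <- dvh$cum_volume_cc
  d <- dvh$dose_gy
  vapply(v_cc, function(v) {
    if (v <= cumv[1]) return(d[1])
    if (v >= cumv[length(cumv)]) return(d[length(d)])
    approx(cumv, d, xout = v, ties = "ordered")$y
  }, numeric(1))
}

#' Near-maximum dose: dose to the hottest sub-volume
#'
#' The maximum dose reported by this package follows the near-maximum
#' convention: the dose to the hottest 0.01 cm^3 of the structure, obtained
#' by accumulating sorted-descending voxel volumes up to `volume_cc` and
#' interpolating within the straddling voxel. Structures smaller than
#' `volume_cc` fall back to the hottest voxel with a warning.
#'
#' @param plan An [rt_plan()] (or a `dvh_curve`).
#' @param structure Structure name (ignored when `plan` is already a DVH).
#' @param volume_cc Hot sub-volume in cm^3; default 0.01.
#' @return Dose in Gy.
#' @export
max_dose <- function(plan, structure, volume_cc = 0.01) {
  dvh <- as_dvh(plan, structure)
  total <- attr(dvh, "total_volume_cc")
  if (total < volume_cc) {
    warn(sprintf(
      "Structure volume %.4g cm^3 < %.4g cm^3; reporting hottest voxel dose.",
      total, volume_cc
    ))
    return(dvh$dose_gy[1])
  }
  dose_at_absolute_volume(dvh, volume_cc)
}

#' Volume receiving at least a given dose (VxGy)
#'
#' @param plan An [rt_plan()] (or `dvh_curve`).
#' @param structure Structure name.
#' @param dose_gy Dose threshold in Gy.
#' @return Volume in cm^3 receiving >= `dose_gy` (exact voxel count, no
#'   interpolation).
#' @export
volume_at_dose <- function(plan, structure, dose_gy) {
  dvh <- as_dvh(plan, structure)
  sum(dvh$volume_cc[dvh$dose_gy >= dose_gy])
}

#' Target coverage V100%
#'
#' Percent of the target volume receiving at least the prescription dose.
#'
#' @param plan An [rt_plan()].
#' @param target Target structure name; defaults to the plan's primary target.
#' @return Coverage in percent.
#' @export
coverage <- function(plan, target = plan$primary_target) {
  s <- plan_structure(plan, target)
  doses <- structure_doses(plan, target)
  100 * sum(doses >= plan$rx_dose) / length(doses)
}

#' Homogeneity index (D2 - D98) / D50
#'
#' 0.0 indicates perfect dose uniformity in the target; hot-core plans
#' (prescription at a low percent of the maximum) score far higher than
#' plateau plans.
#'
#' @inheritParams coverage
#' @return Dimensionless HI >= 0 (up to DVH interpolation tolerance).
#' @export
homogeneity_index <- function(plan, target = plan$primary_target) {
  dvh <- cumulative_dvh(plan, target)
  d2 <- dose_at_volume(dvh, 2)
  d98 <- dose_at_volume(dvh, 98)
  d50 <- dose_at_volume(dvh, 50)
  if (d50 <= 0) abort("D50 is zero; homogeneity index undefined.")
  (d2 - d98) / d50
}

#' Mean structure dose
#'
#' Volume-weighted mean dose over the structure.
#'
#' @inheritParams volume_at_dose
#' @return Dose in Gy.
#' @export
mean_dose <- function(plan, structure) {
  mean(structure_doses(plan, structure))
}

#' Normalize a dose metric to the prescription
#'
#' OAR dose metrics are reported as a percent of the prescription dose so
#' that plans with different prescriptions compare on one scale.
#'
#' @param dose_gy Dose in Gy.
#' @param rx_dose Prescription dose in Gy.
#' @return 100 * dose / Rx, in percent.
#' @examples
#' normalized_dose(13, 45) # 28.9%
#' @export
normalized_dose <- function(dose_gy, rx_dose) {
  if (any(rx_dose <= 0)) abort("`rx_dose` must be > 0.")
  100 * dose_gy / rx_dose
}

#' Export a DVH as CSV
#'
#' Columns: dose (Gy), cumulative volume (cm^3), cumulative volume (%).
#'
#' @param dvh A `dvh_curve`.
#' @param path Output file.
#' @export
write_dvh_csv <- function(dvh, path) {
  df <- data.frame(
    dose_gy = dvh$dose_gy,
    volume_cc = dvh$cum_volume_cc,
    volume_pct = dvh$cum_volume_pct
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a cumulative DVH
#'
#' @param object A `dvh_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dose_gy, .data$cum_volume_pct)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(
      x = "Dose (Gy)", y = "Volume (%)",
      title = sprintf("Cumulative DVH: %s", attr(object, "structure"))
    ) +
    ggplot2::theme_minimal()
}
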