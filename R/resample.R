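#' Resample a dose grid onto another grid geometry
#'
#' Trilinear interpolation of the dose at the target grid's voxel centers.
#' Dose is smooth, so it is the dose — never the binary masks — that gets
#' resampled when a structure set and a dose grid disagree. Target voxels
#' outside the source extent are returned as 0 but counted and flagged in the
#' `n_outside` attribute rather than silently zeroed; wholly disjoint grids
#' are an error.
#'
#' @param dose A [dose_grid()].
#' @param target A `dose_grid` or [structure_mask()] whose geometry to adopt.
#' @return A [dose_grid()] on the target geometry, with attribute
#'   `n_outside` (count of extrapolated voxels).
#' @export
align_dose_to_grid <- function(dose, target) {
  if (!inherits(dose, "dose_grid")) abort("`dose` must be a dose_grid.")
  if (same_geometry(dose, target)) {
    out <- dose_grid(dose$values, dose$spacing, dose$origin)
    attr(out, "n_outside") <- 0L
    return(out)
  }
  d <- grid_dim(target)
  ax <- grid_axes(target)
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z))
  vals <- trilinear_cpp(
    dose$values, dim(dose$values), dose$spacing, dose$origin, pts
  )
  n_outside <- sum(is.na(vals))
  if (n_outside == length(vals)) {
    abort("Target grid is disjoint from the dose grid extent.")
  }
  if (n_outside > 0) {
    warn(sprintf(
      "%d of %d target voxels fall outside the dose grid; set to 0 and flagged.",
      n_outside, length(vals)
    ))
    vals[is.na(vals)] <- 0
  }
  out <- dose_grid(array(vals, dim = d), target$spacing, target$origin)
  attr(out, "n_outside") <- n_outside
  out
}

# interpolate the dose field of a plan/grid at arbitrary mm points
interp_dose <- function(dose, pts) {
  trilinear_cpp(dose$values, dim(dose$values), dose$spacing, dose$origin,
                as.matrix(pts))
}
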