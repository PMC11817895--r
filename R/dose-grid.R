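#' Construct a 3D dose grid
#'
#' A dose grid is a 3D scalar field of absorbed dose sampled at voxel centers
#' on a regular axis-aligned grid in patient coordinates. All lengths are in
#' mm, doses in Gy; the voxel volume is `prod(spacing)` mm^3. `origin` is the
#' physical position of the center of voxel `[1, 1, 1]` and voxel indices are
#' interpreted axis-aligned (x fastest, then y, then z).
#'
#' @param values 3D numeric array of dose in Gy; must be finite and >= 0.
#' @param spacing Per-axis voxel size in mm (length 1 or 3), all > 0.
#' @param origin Physical position (mm) of the first voxel center (length 3).
#' @return An object of class `dose_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- dose_grid(array(1, c(4, 4, 4)), spacing = 2)
#' voxel_volume_cc(g)
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  origin <- rep(as.numeric(origin), length.out = 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be positive and finite on all axes.")
  }
  if (any(!is.finite(origin))) abort("`origin` must be finite.")
  values <- array(as.double(values), dim = dim(values)) # strip foreign attrs
  if (anyNA(values) || any(values < 0) || any(!is.finite(values))) {
    abort("Dose values must be finite and non-negative.")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
    d[1], d[2], d[3],
    paste(format(x$spacing, trim = TRUE), collapse = " x "),
    paste(format(x$origin, trim = TRUE), collapse = ", ")
  ))
  cat(sprintf("  dose range %.3f - %.3f Gy\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid A [dose_grid()] or [structure_mask()].
#' @return Volume of one voxel, in cm^3 for `voxel_volume_cc()` and mm^3 for
#'   `voxel_volume_mm3()`.
#' @export
voxel_volume_cc <- function(grid) voxel_volume_mm3(grid) / 1000

#' @rdname voxel_volume_cc
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Physical voxel-center coordinates along each axis
#'
#' @param grid A `dose_grid` or `structure_mask`.
#' @return List of numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  d <- grid_dim(grid)
  list(
    x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
    y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
    z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  )
}

grid_dim <- function(grid) {
  if (!is.null(grid$values)) dim(grid$values) else dim(grid$mask)
}

# TRUE when two grids share geometry to floating tolerance
same_geometry <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
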