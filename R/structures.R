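#' Construct a structure mask
#'
#' A structure is a named binary mask on a stated grid, with a clinical role:
#' `"target"` (tumor volumes such as PTV/GTV) or `"oar"` (organs at risk such
#' as brainstem or carotid). Its volume is the voxel count times the voxel
#' volume, in cm^3.
#'
#' @param mask 3D logical array; `TRUE` inside the structure.
#' @param spacing,origin Grid geometry, as in [dose_grid()].
#' @param name Structure label.
#' @param role `"target"` or `"oar"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(mask, spacing, origin = c(0, 0, 0),
                           name = "structure", role = c("target", "oar")) {
  role <- match.arg(role)
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3D array.")
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) abort("`mask` must not contain NA.")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) abort("`spacing` must be positive.")
  structure(
    list(
      mask = mask, spacing = spacing,
      origin = rep(as.numeric(origin), length.out = 3L),
      name = as.character(name), role = role
    ),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "<structure_mask> '%s' (%s): %d voxels, %.3f cm^3\n",
    x$name, x$role, sum(x$mask), structure_volume_cc(x)
  ))
  invisible(x)
}

#' Structure volume in cm^3
#'
#' Volume is the number of masked voxels times the voxel volume.
#'
#' @param structure A [structure_mask()].
#' @export
structure_volume_cc <- function(structure) {
  sum(structure$mask) * voxel_volume_cc(structure)
}

#' Rasterize planar contours into a structure mask
#'
#' Converts per-slice closed polygons (mm, patient coordinates) into a binary
#' mask on the geometry of `grid`. A voxel belongs to the structure iff its
#' center is inside the polygon(s) of its slice under the even-odd rule, so
#' holes are supported by supplying inner loops. Contour vertices on a slice
#' are matched to the nearest grid slice; slices falling outside the grid are
#' clipped with a warning.
#'
#' @param contours Data frame with columns `x`, `y`, `z` (mm) and `loop`
#'   (identifier of the closed polygon; loops sharing a z belong to the same
#'   slice and are combined by even-odd parity).
#' @param grid A [dose_grid()] (or anything with `spacing`/`origin`/values
#'   dimensions) defining the output geometry.
#' @param name,role Passed to [structure_mask()].
#' @return A [structure_mask()] on the grid geometry.
#' @examples
#' g <- dose_grid(array(0, c(30, 30, 12)), spacing = 1)
#' sq <- expand.grid(x = c(5, 25, 25, 5), z = 1:10)
#' sq$y <- rep(c(5, 5, 25, 25), 10)
#' sq$loop <- sq$z
#' s <- rasterize_structure(sq, g, name = "square")
#' structure_volume_cc(s)
#' @export
rasterize_structure <- function(contours, grid, name = "structure",
                                role = c("target", "oar")) {
  role <- match.arg(role)
  contours <- as.data.frame(contours)
  need <- c("x", "y", "z", "loop")
  if (!all(need %in% names(contours))) {
    abort("`contours` needs columns x, y, z, loop.")
  }
  d <- grid_dim(grid)
  ax <- grid_axes(grid)
  mask <- array(FALSE, dim = d)
  clipped <- FALSE
  loops <- split(contours, contours$loop)
  # slice index for each loop from its (constant) z
  for (lp in loops) {
    z <- lp$z[1]
    if (length(unique(lp$z)) > 1L) {
      abort("Each contour loop must lie in a single z slice.")
    }
    k <- round((z - grid$origin[3]) / grid$spacing[3]) + 1
    if (k < 1 || k > d[3] || abs(ax$z[max(1, min(k, d[3]))] - z) >
        grid$spacing[3] / 2 + 1e-6) {
      clipped <- TRUE
      next
    }
    vx <- lp$x
    vy <- lp$y
    # restrict the point-in-polygon test to the loop's bounding box
    irange <- which(ax$x >= min(vx) - 1e-9 & ax$x <= max(vx) + 1e-9)
    jrange <- which(ax$y >= min(vy) - 1e-9 & ax$y <= max(vy) + 1e-9)
    if (!length(irange) || !length(jrange)) {
      clipped <- clipped || (min(vx) > max(ax$x) || max(vx) < min(ax$x) ||
                               min(vy) > max(ax$y) || max(vy) < min(ax$y))
      next
    }
    pts <- expand.grid(px = ax$x[irange], py = ax$y[jrange])
    inside <- point_in_polygon(pts$px, pts$py, vx, vy)
    sl <- mask[, , k]
    sub <- matrix(inside, nrow = length(irange))
    sl[irange, jrange] <- xor(sl[irange, jrange], sub)
    mask[, , k] <- sl
  }
  if (clipped) {
    warn(sprintf("Contours of '%s' extend outside the grid; clipped.", name))
  }
  if (!any(mask)) {
    abort(sprintf("Rasterizing '%s' produced an empty mask.", name))
  }
  structure_mask(mask, grid$spacing, grid$origin, name = name, role = role)
}

# Even-odd (crossing number) point-in-polygon, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  # drop an explicitly repeated closing vertex
  if (n > 1 && vx[1] == vx[n] && vy[1] == vy[n]) {
    vx <- vx[-n]
    vy <- vy[-n]
    n <- n - 1
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}
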