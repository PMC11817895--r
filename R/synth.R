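#' Specify a synthetic plan with analytic ground truth
#'
#' Builds the specification of a phenomenological dose distribution around a
#' convex target: a plateau (or hot core) inside the target and a monotone
#' falloff outside, parameterized by distance to the target surface so that
#' the falloff in %Rx/mm is uniform over the border and every gradient
#' metric has a closed-form ground truth ([ground_truth()]). The profile
#' families emulate the falloff regimes of the clinical delivery systems:
#'
#' * `linear(g)`: plateau at Rx inside the target, falloff of `g` %Rx per mm
#'   outside, clipped at 0. Prescription sits at the plateau edge; SBG is
#'   `g` at every level.
#' * `logistic(prescription_isodose, scale)`: sigmoid of the signed distance
#'   with maximum dose `Rx * 100 / prescription_isodose`. With
#'   `prescription_isodose = 50` the prescription isodose sits at the
#'   steepest point of the profile and a hot core of about twice Rx forms
#'   inside the target (the radiosurgery normalization); `90` prescribes at
#'   the shoulder, pushing the steepest gradient below the prescription
#'   level (the arc/proton normalization).
#' * `piecewise(knots)`: monotone linear interpolation of
#'   `(distance_mm, pct_rx)` knots outside the target, plateau inside.
#'
#' An optional anisotropy emulates a beam-stopping sector (proton-like zero
#' exit dose): outside distances in the half-space `direction . x > 0`
#' (relative to the target center) are multiplied by `factor` before the
#' profile is evaluated, so `factor = Inf` gives zero exit dose.
#'
#' @param target List: `type` ("sphere" or "ellipsoid"), `radius` (mm) or
#'   `semi_axes` (mm, length 3), optional `center` (mm) and `name`.
#' @param rx_dose,n_fractions Prescription; defaults 24 Gy in 3 fractions
#'   (the 3-fraction reirradiation regime).
#' @param profile List with `family` and its parameters, see above.
#' @param anisotropy `NULL` or list(`direction`, `factor`).
#' @param oars List of lists: `name`, `radius` (mm), `gap` (mm from the
#'   target surface), `direction` (unit vector from target center).
#' @param grid List: `spacing` (mm, default 0.5) and `extent` (mm cube edge,
#'   default 80), centered on the target center.
#' @param noise_sd_pct Additive Gaussian noise, sd in %Rx (default 0: the
#'   metrics are defined on the noiseless field).
#' @param seed RNG seed used when noise is on.
#' @return An object of class `synthetic_plan_spec`.
#' @export
synthetic_plan_spec <- function(target = list(type = "sphere", radius = 10),
                                rx_dose = 24, n_fractions = 3,
                                profile = list(family = "linear", g = 5),
                                anisotropy = NULL,
                                oars = list(),
                                grid = list(spacing = 0.5, extent = 80),
                                noise_sd_pct = 0, seed = 1L) {
  target <- modifyList(list(type = "sphere", center = c(0, 0, 0), name = "PTV"),
                       target)
  if (target$type == "sphere" && is.null(target$radius)) {
    abort("Sphere targets need `radius`.")
  }
  if (target$type == "ellipsoid" && is.null(target$semi_axes)) {
    abort("Ellipsoid targets need `semi_axes`.")
  }
  grid <- modifyList(list(spacing = 0.5, extent = 80), grid)
  if (grid$spacing <= 0 || grid$extent <= 0) abort("Grid spacing/extent must be > 0.")
  rmax <- if (target$type == "sphere") target$radius else max(target$semi_axes)
  if (2 * rmax >= grid$extent) abort("Target does not fit inside the grid.")
  frac <- profile_fraction(profile)
  dd <- seq(0, grid$extent, length.out = 200)
  if (any(diff(frac(dd)) > 1e-9)) {
    abort("Profile must be monotone non-increasing with distance.")
  }
  if (!is.null(anisotropy)) {
    anisotropy <- modifyList(list(direction = c(1, 0, 0), factor = Inf), anisotropy)
    anisotropy$direction <- anisotropy$direction / sqrt(sum(anisotropy$direction^2))
    if (anisotropy$factor < 1) abort("Anisotropy factor must be >= 1.")
  }
  structure(
    list(
      target = target, rx_dose = rx_dose, n_fractions = as.integer(n_fractions),
      profile = profile, anisotropy = anisotropy, oars = oars, grid = grid,
      noise_sd_pct = noise_sd_pct, seed = as.integer(seed)
    ),
    class = "synthetic_plan_spec"
  )
}

# fraction-of-Rx as a function of signed distance (mm) to the target surface
profile_fraction <- function(profile) {
  switch(
    profile$family,
    linear = {
      g <- profile$g
      function(d) pmin(1, pmax(0, 1 - g * pmax(d, 0) / 100))
    },
    logistic = {
      p <- profile$prescription_isodose
      s <- profile$scale
      dmax_frac <- 100 / p # maximum dose as a fraction of Rx
      d0 <- s * stats::qlogis(p / 100)
      function(d) dmax_frac * stats::plogis(-(d - d0) / s)
    },
    piecewise = {
      kn <- profile$knots
      if (abs(kn$pct_rx[1] - 100) > 1e-9 || kn$d_mm[1] != 0) {
        abort("Piecewise knots must start at (0 mm, 100 %Rx).")
      }
      function(d) {
        out <- approx(kn$d_mm, kn$pct_rx / 100, xout = pmax(d, 0),
                      rule = 2, ties = "ordered")$y
        out[d <= 0] <- 1
        out
      }
    },
    abort(sprintf("Unknown profile family '%s'.", profile$family))
  )
}

# inverse of the outside profile: distance (mm, signed) at which the dose is
# x %Rx; closed form where available, else 1D root finding (flagged)
profile_offset <- function(profile, x) {
  switch(
    profile$family,
    linear = (100 - x) / profile$g,
    logistic = {
      p <- profile$prescription_isodose
      s <- profile$scale
      s * stats::qlogis(p / 100) - s * stats::qlogis(x * p / 1e4)
    },
    {
      frac <- profile_fraction(profile)
      vapply(x, function(xx) {
        if (xx >= 100) return(0)
        lo <- 0
        hi <- 1
        while (frac(hi) > xx / 100 && hi < 1e6) hi <- hi * 2
        uniroot(function(d) frac(d) - xx / 100, c(lo, hi), tol = 1e-10)$root
      }, numeric(1))
    }
  )
}

#' Generate a plan from a synthetic specification
#'
#' Evaluates the analytic profile of signed distance-to-target-surface at
#' every voxel center, rasterizes the target and OAR geometries on the same
#' grid, and assembles an [rt_plan()]. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_plan_spec()].
#' @return An [rt_plan()].
#' @examples
#' spec <- synthetic_plan_spec(grid = list(spacing = 1, extent = 50))
#' plan <- generate_plan(spec)
#' glance(plan)
#' @export
generate_plan <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plan_spec"))
  g <- spec$grid
  n <- max(2L, round(g$extent / g$spacing))
  coord <- (seq_len(n) - (n + 1) / 2) * g$spacing
  origin <- spec$target$center + coord[1]
  ax <- list(x = coord + spec$target$center[1],
             y = coord + spec$target$center[2],
             z = coord + spec$target$center[3])
  dx <- ax$x - spec$target$center[1]
  dy <- ax$y - spec$target$center[2]
  dz <- ax$z - spec$target$center[3]
  sd <- signed_distance_field(spec$target, dx, dy, dz)
  d_eff <- sd
  if (!is.null(spec$anisotropy)) {
    u <- spec$anisotropy$direction
    proj <- array(rep(dx * u[1], times = n * n), c(n, n, n))
    proj <- proj + array(rep(rep(dy * u[2], each = n), times = n), c(n, n, n))
    proj <- proj + array(rep(dz * u[3], each = n * n), c(n, n, n))
    sector <- proj > 0 & sd > 0
    if (is.finite(spec$anisotropy$factor)) {
      d_eff[sector] <- sd[sector] * spec$anisotropy$factor
    } else {
      d_eff[sector] <- Inf
    }
  }
  frac <- profile_fraction(spec$profile)
  dose_vals <- spec$rx_dose * frac(d_eff)
  dose_vals[!is.finite(dose_vals)] <- 0
  dose_vals[d_eff == Inf] <- 0
  if (spec$noise_sd_pct > 0) {
    set.seed(spec$seed)
    dose_vals <- dose_vals +
      stats::rnorm(length(dose_vals), 0, spec$noise_sd_pct / 100 * spec$rx_dose)
    dose_vals <- pmax(dose_vals, 0)
  }
  dose <- dose_grid(array(dose_vals, c(n, n, n)), g$spacing, origin)
  target_mask <- structure_mask(sd <= 0, g$spacing, origin,
                                name = spec$target$name, role = "target")
  structures <- list(target_mask)
  for (o in spec$oars) {
    o <- modifyList(list(radius = 5, gap = 2, direction = c(1, 0, 0)), o)
    u <- o$direction / sqrt(sum(o$direction^2))
    surf_r <- if (spec$target$type == "sphere") spec$target$radius else
      1 / sqrt(sum((u / spec$target$semi_axes)^2))
    ctr <- spec$target$center + u * (surf_r + o$gap + o$radius)
    r2 <- outer(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, `+`),
                (ax$z - ctr[3])^2, `+`)
    m <- r2 <= o$radius^2
    if (!any(m)) abort(sprintf("OAR '%s' falls outside the grid.", o$name))
    structures <- c(structures, list(
      structure_mask(m, g$spacing, origin, name = o$name, role = "oar")
    ))
  }
  rt_plan(dose, structures, spec$rx_dose, spec$n_fractions,
          primary_target = spec$target$name)
}

# signed distance (mm) to the target surface at all grid nodes (<0 inside)
signed_distance_field <- function(target, dx, dy, dz) {
  n <- c(length(dx), length(dy), length(dz))
  if (target$type == "sphere") {
    r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    return(sqrt(r2) - target$radius)
  }
  pts <- as.matrix(expand.grid(x = dx, y = dy, z = dz))
  array(ellipsoid_signed_distance(pts, target$semi_axes), dim = n)
}

#' Exact signed distance to an ellipsoid surface
#'
#' Vectorized Newton iteration on the standard Lagrange parameter: for a
#' query point q the foot point is `y_i = a_i^2 q_i / (a_i^2 + t)` with t the
#' root of `sum (a_i q_i / (a_i^2 + t))^2 = 1`. Negative inside.
#'
#' @param pts n x 3 matrix of points (ellipsoid-centered coordinates, mm).
#' @param semi_axes Length-3 positive semi-axes (mm).
#' @return Signed distances (mm).
#' @export
ellipsoid_signed_distance <- function(pts, semi_axes) {
  a <- rep(as.numeric(semi_axes), length.out = 3)
  q <- abs(as.matrix(pts))
  inside <- (q[, 1] / a[1])^2 + (q[, 2] / a[2])^2 + (q[, 3] / a[3])^2 < 1
  a2 <- a^2
  degenerate <- rowSums(q) < 1e-12
  # f(t) = sum (a_i q_i / (a2_i + t))^2 - 1 is convex decreasing on
  # (-min a^2, Inf) with a flat right tail, so plain Newton can diverge;
  # use a guaranteed bracket and fall back to bisection when a Newton step
  # leaves it. Bracket: f(aj|qj| - aj^2) >= 0 for the dominant term j and
  # f(|diag(a) q| - min a^2) <= 0 by Cauchy-Schwarz.
  aq <- cbind(a[1] * q[, 1], a[2] * q[, 2], a[3] * q[, 3])
  jmax <- max.col(aq, ties.method = "first")
  lo_min <- -min(a2) + 1e-12 * max(a2)
  t_lo <- pmax(aq[cbind(seq_len(nrow(q)), jmax)] - a2[jmax], lo_min)
  t_hi <- pmax(sqrt(rowSums(aq^2)) - min(a2), t_lo + 1e-12)
  t <- (t_lo + t_hi) / 2
  for (it in 1:100) {
    den1 <- a2[1] + t
    den2 <- a2[2] + t
    den3 <- a2[3] + t
    f <- (aq[, 1] / den1)^2 + (aq[, 2] / den2)^2 + (aq[, 3] / den3)^2 - 1
    pos <- f >= 0
    t_lo <- ifelse(pos, t, t_lo)
    t_hi <- ifelse(pos, t_hi, t)
    fp <- -2 * (aq[, 1]^2 / den1^3 + aq[, 2]^2 / den2^3 + aq[, 3]^2 / den3^3)
    tn <- t - f / fp
    use <- is.finite(tn) & tn > t_lo & tn < t_hi
    t <- ifelse(use, tn, (t_lo + t_hi) / 2)
  }
  y1 <- a2[1] * q[, 1] / (a2[1] + t)
  y2 <- a2[2] * q[, 2] / (a2[2] + t)
  y3 <- a2[3] * q[, 3] / (a2[3] + t)
  d <- sqrt((q[, 1] - y1)^2 + (q[, 2] - y2)^2 + (q[, 3] - y3)^2)
  d[degenerate] <- min(a)
  ifelse(inside, -d, d)
}

#' Closed-form expected metrics for a synthetic specification
#'
#' Computes the analytic (grid-free) values every engine metric should
#' converge to for a [synthetic_plan_spec()]: level radii/offsets, shortest
#' border distances, SBG, isodose volumes, VG, gradient index, conformity
#' indices, homogeneity index, coverage and maximum dose. For convex targets
#' the x%Rx surface is the outward parallel surface of the target at the
#' profile offset, so `d_min(x)` is exact for spheres and ellipsoids alike;
#' volumes use the sphere closed form or the Steiner parallel-body formula
#' with numerically integrated surface area and mean-curvature integral.
#' Hot-core interior quantities (HI, Dx, Dmax) use the sphere closed form
#' and are `NA` for ellipsoids. Profiles without a closed-form inverse are
#' inverted by 1D root finding (`numeric_inverse = TRUE` in the result).
#'
#' @param spec A [synthetic_plan_spec()].
#' @param sbg_levels,vg_levels Levels (%Rx) at which to tabulate.
#' @return A list with `levels` (tibble: `level_pct`, `offset_mm`,
#'   `d_min_mm`, `sbg_pct_per_mm`, `vol_cc`, `vg`) and scalars `tv_cc`,
#'   `paddick_ci`, `rtog_ci`, `gradient_index`, `homogeneity_index`,
#'   `coverage_pct`, `dmax_gy`, `numeric_inverse`.
#' @export
ground_truth <- function(spec, sbg_levels = seq(50, 90, by = 10),
                         vg_levels = seq(20, 100, by = 10)) {
  stopifnot(inherits(spec, "synthetic_plan_spec"))
  levels <- sort(unique(c(sbg_levels, vg_levels, 50, 100)), decreasing = TRUE)
  off <- profile_offset(spec$profile, levels)
  off100 <- profile_offset(spec$profile, 100)
  numeric_inverse <- !spec$profile$family %in% c("linear", "logistic")
  tv <- target_volume_mm3(spec$target) / 1000
  vol <- vapply(off, function(o) parallel_volume_mm3(spec, o), numeric(1)) / 1000
  # closed-form border distances hold for isotropic falloff only: with a
  # sharper sector the level surfaces pinch together near the sector boundary
  iso <- is.null(spec$anisotropy)
  lev <- tibble::tibble(
    level_pct = levels,
    offset_mm = off,
    d_min_mm = if (iso) off - off100 else NA_real_,
    sbg_pct_per_mm = ifelse(rep(iso, length(levels)) & levels < 100,
                            (100 - levels) / (off - off100), NA_real_),
    vol_cc = vol,
    vg = vol / tv
  )
  vg50 <- lev$vg[lev$level_pct == 50]
  vg100 <- lev$vg[lev$level_pct == 100]
  sphere <- spec$target$type == "sphere"
  frac <- profile_fraction(spec$profile)
  hi <- NA_real_
  dmax <- NA_real_
  if (sphere) {
    R <- spec$target$radius
    dx_at <- function(x) spec$rx_dose * frac(R * ((x / 100)^(1 / 3) - 1))
    hi <- (dx_at(2) - dx_at(98)) / dx_at(50)
    dmax <- spec$rx_dose * frac(-R)
  }
  list(
    levels = dplyr::filter(lev, .data$level_pct %in% c(sbg_levels, vg_levels)),
    tv_cc = tv,
    paddick_ci = 1, # the x=100 offset is 0: PIV coincides with the target
    rtog_ci = 1,
    gradient_index = vg50 / vg100,
    homogeneity_index = hi,
    coverage_pct = 100,
    dmax_gy = dmax,
    numeric_inverse = numeric_inverse
  )
}

target_volume_mm3 <- function(target) {
  if (target$type == "sphere") {
    4 / 3 * pi * target$radius^3
  } else {
    4 / 3 * pi * prod(target$semi_axes)
  }
}

# volume of {dose >= level}: the outward parallel body of the target at
# offset o (mm); inner offsets (hot core) use the sphere closed form
parallel_volume_mm3 <- function(spec, o) {
  tgt <- spec$target
  iso_vol <- function(off) {
    if (tgt$type == "sphere") {
      r <- max(tgt$radius + off, 0)
      4 / 3 * pi * r^3
    } else {
      if (off < 0) return(NA_real_)
      sm <- ellipsoid_surface_integrals(tgt$semi_axes)
      target_volume_mm3(tgt) + sm$area * off + sm$mean_curv * off^2 +
        4 / 3 * pi * off^3
    }
  }
  if (is.null(spec$anisotropy)) return(iso_vol(o))
  if (o <= 0) return(iso_vol(o))
  f <- spec$anisotropy$factor
  o2 <- if (is.finite(f)) o / f else 0
  (iso_vol(o) + iso_vol(o2)) / 2 # half-space split through the center
}

# surface area and integral of mean curvature of an ellipsoid (numeric)
ellipsoid_surface_integrals <- function(semi_axes, n_theta = 400, n_phi = 400) {
  a <- semi_axes[1]; b <- semi_axes[2]; c3 <- semi_axes[3]
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  TH <- matrix(th, n_theta, n_phi)
  PH <- matrix(ph, n_theta, n_phi, byrow = TRUE)
  x <- a * sin(TH) * cos(PH)
  y <- b * sin(TH) * sin(PH)
  z <- c3 * cos(TH)
  # |r_theta x r_phi|
  rt <- cbind(as.vector(a * cos(TH) * cos(PH)), as.vector(b * cos(TH) * sin(PH)),
              as.vector(-c3 * sin(TH)))
  rp <- cbind(as.vector(-a * sin(TH) * sin(PH)), as.vector(b * sin(TH) * cos(PH)),
              0)
  cr <- cbind(rt[, 2] * rp[, 3] - rt[, 3] * rp[, 2],
              rt[, 3] * rp[, 1] - rt[, 1] * rp[, 3],
              rt[, 1] * rp[, 2] - rt[, 2] * rp[, 1])
  dA <- sqrt(rowSums(cr^2)) * (pi / n_theta) * (2 * pi / n_phi)
  # mean curvature from the implicit form sum x_i^2/a_i^2 = 1
  nx <- as.vector(x) / a^2
  ny <- as.vector(y) / b^2
  nz <- as.vector(z) / c3^2
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  tr <- 1 / a^2 + 1 / b^2 + 1 / c3^2
  quad <- nx^2 / a^2 + ny^2 / b^2 + nz^2 / c3^2
  H <- (tr / nn - quad / nn^3) / 2
  list(area = sum(dA), mean_curv = sum(H * dA))
}
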