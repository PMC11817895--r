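# Shared fixture builders. Everything is generated in code at test time;
# grids are kept small so the default run stays fast.

# plan with an explicit dose array and a single all-TRUE target mask
plan_from_values <- function(values, spacing = 1, rx = NULL, n_fx = 3,
                             mask = NULL, name = "PTV") {
  g <- dose_grid(values, spacing)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  s <- structure_mask(mask, spacing, g$origin, name = name, role = "target")
  if (is.null(rx)) rx <- max(values)
  rt_plan(g, list(s), rx_dose = rx, n_fractions = n_fx)
}

# uniform-dose plan: `n` voxels at `dose` Gy, voxel volume `vox_cc` cm^3
uniform_plan <- function(dose = 45, n = 10, vox_cc = 1) {
  sp <- (vox_cc * 1000)^(1 / 3)
  plan_from_values(array(dose, c(n, 1, 1)), spacing = sp, rx = dose)
}

# plan whose target voxels carry the given doses, one voxel each
voxel_list_plan <- function(doses, vox_cc = 0.005, rx = max(doses)) {
  sp <- (vox_cc * 1000)^(1 / 3)
  plan_from_values(array(doses, c(length(doses), 1, 1)), spacing = sp, rx = rx)
}

# the reference linear-falloff spherical plan (plateau prescribed at edge)
linear_sphere_spec <- function(spacing = 0.5, extent = 46, radius = 10,
                               g = 5, rx = 24) {
  synthetic_plan_spec(
    target = list(type = "sphere", radius = radius), rx_dose = rx,
    profile = list(family = "linear", g = g),
    grid = list(spacing = spacing, extent = extent)
  )
}

logistic_sphere_spec <- function(prescription_isodose, scale,
                                 spacing = 0.5, extent = 56) {
  synthetic_plan_spec(
    target = list(type = "sphere", radius = 10), rx_dose = 24,
    profile = list(
      family = "logistic",
      prescription_isodose = prescription_isodose, scale = scale
    ),
    grid = list(spacing = spacing, extent = extent)
  )
}

# independent brute-force DVH oracle: plain loop over sorted voxels
oracle_dose_at_volume <- function(doses, volumes, v_target_cc) {
  ord <- order(doses, decreasing = TRUE)
  d <- doses[ord]
  v <- volumes[ord]
  acc <- 0
  for (i in seq_along(d)) {
    prev <- acc
    acc <- acc + v[i]
    if (acc >= v_target_cc) {
      if (i == 1) return(d[1])
      # linear interpolation between adjacent sorted voxel doses
      f <- (v_target_cc - prev) / v[i]
      return(d[i - 1] + f * (d[i] - d[i - 1]))
    }
  }
  d[length(d)]
}

# all-pairs brute-force minimum distance between two point clouds (chunked)
oracle_min_distance <- function(a, b, chunk = 500) {
  best <- Inf
  for (i in seq(1, nrow(a), by = chunk)) {
    ia <- i:min(i + chunk - 1, nrow(a))
    d2 <- outer(rowSums(a[ia, , drop = FALSE]^2), rowSums(b^2), `+`) -
      2 * a[ia, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

# exhaustive signed-rank enumeration: two-sided p over all 2^n sign vectors
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# plan with a covered target plus a uniform-dose brainstem
goal_test_plan <- function(bs_dose, rx = 40, n_fx = 5L) {
  n <- 20
  sp <- 2
  cc <- (seq_len(n) - (n + 1) / 2) * sp
  r_t <- sqrt(outer(outer((cc + 10)^2, cc^2, `+`), cc^2, `+`))
  r_b <- sqrt(outer(outer((cc - 12)^2, cc^2, `+`), cc^2, `+`))
  vals <- array(0, c(n, n, n))
  vals[r_t <= 8] <- rx
  vals[r_b <= 6] <- bs_dose
  g <- dose_grid(vals, sp, origin = rep(cc[1], 3))
  tgt <- structure_mask(r_t <= 8, sp, rep(cc[1], 3), name = "PTV",
                        role = "target")
  bs <- structure_mask(r_b <= 6, sp, rep(cc[1], 3), name = "Brainstem",
                       role = "oar")
  rt_plan(g, list(tgt, bs), rx_dose = rx, n_fractions = n_fx)
}

circle_contour <- function(r, center = c(0, 0), z, n = 360, loop = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(
    x = center[1] + r * cos(th),
    y = center[2] + r * sin(th),
    z = z, loop = loop
  )
}
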