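test_that("specs validate geometry and profile monotonicity", {
  expect_error(synthetic_plan_spec(target = list(type = "sphere")), "radius")
  expect_error(
    synthetic_plan_spec(target = list(type = "sphere", radius = 50),
                        grid = list(spacing = 1, extent = 60)),
    "fit inside"
  )
  bad_knots <- tibble::tibble(d_mm = c(0, 5, 10), pct_rx = c(100, 40, 70))
  expect_error(
    synthetic_plan_spec(profile = list(family = "piecewise", knots = bad_knots)),
    "monotone"
  )
  expect_error(
    synthetic_plan_spec(profile = list(family = "gaussian")),
    "Unknown profile family"
  )
})

test_that("generation is deterministic given the seed", {
  spec <- synthetic_plan_spec(grid = list(spacing = 1, extent = 40),
                              noise_sd_pct = 2, seed = 99)
  p1 <- generate_plan(spec)
  p2 <- generate_plan(spec)
  expect_identical(p1$dose$values, p2$dose$values)
  spec2 <- synthetic_plan_spec(grid = list(spacing = 1, extent = 40),
                               noise_sd_pct = 2, seed = 100)
  expect_false(identical(generate_plan(spec2)$dose$values, p1$dose$values))
})

test_that("plateau plans realize their analytic limits", {
  spec <- linear_sphere_spec(spacing = 1, extent = 40)
  plan <- generate_plan(spec)
  expect_equal(homogeneity_index(plan), 0)
  expect_equal(coverage(plan), 100)
  expect_equal(paddick_ci(plan), 1)
  expect_equal(max(plan$dose$values), plan$rx_dose)
})

test_that("hot-core normalization doubles the maximum dose at 50% prescription", {
  spec <- logistic_sphere_spec(50, 2.4, spacing = 1, extent = 40)
  plan <- generate_plan(spec)
  # the logistic tail leaves the center a hair under the asymptotic 2 x Rx
  expect_equal(max(plan$dose$values) / plan$rx_dose, 2, tolerance = 0.05)
  gt <- ground_truth(spec)
  expect_equal(gt$dmax_gy / spec$rx_dose, 2, tolerance = 0.05)
})

test_that("ground truth tabulates the linear sphere in closed form", {
  spec <- linear_sphere_spec()
  gt <- ground_truth(spec, sbg_levels = c(50, 90), vg_levels = c(50, 90, 100))
  lev <- gt$levels
  expect_equal(lev$offset_mm[lev$level_pct == 90], 2)
  expect_equal(lev$offset_mm[lev$level_pct == 50], 10)
  expect_equal(lev$vg[lev$level_pct == 100], 1)
  expect_equal(lev$vg[lev$level_pct == 90], 1.728)
  expect_equal(lev$vg[lev$level_pct == 50], 8)
  expect_true(all(lev$sbg_pct_per_mm[lev$level_pct < 100] == 5))
  expect_equal(gt$gradient_index, 8)
  expect_equal(gt$homogeneity_index, 0)
  expect_equal(gt$tv_cc, 4 / 3 * pi, tolerance = 1e-12)
})

test_that("piecewise profiles invert numerically and are flagged", {
  kn <- tibble::tibble(d_mm = c(0, 2, 10, 20), pct_rx = c(100, 80, 30, 0))
  spec <- synthetic_plan_spec(profile = list(family = "piecewise", knots = kn),
                              grid = list(spacing = 1, extent = 60))
  gt <- ground_truth(spec, sbg_levels = c(50, 80), vg_levels = 100)
  expect_true(gt$numeric_inverse)
  expect_equal(gt$levels$offset_mm[gt$levels$level_pct == 80], 2)
  # 50%Rx from interpolating 80 -> 30 over 2 -> 10 mm: 2 + 8 * 30/50 = 6.8
  expect_equal(gt$levels$offset_mm[gt$levels$level_pct == 50], 6.8,
               tolerance = 1e-6)
  plan <- generate_plan(spec)
  prof <- sbg_profile(plan, c(50, 80))
  expect_equal(prof$d_min_mm[prof$level_pct == 80], 2, tolerance = 0.1)
  expect_equal(prof$d_min_mm[prof$level_pct == 50], 6.8, tolerance = 0.15)
})

test_that("ellipsoid distances are exact against sphere and brute force", {
  pts <- matrix(rnorm(300, sd = 15), ncol = 3)
  sphere_d <- ellipsoid_signed_distance(pts, c(10, 10, 10))
  expect_equal(sphere_d, sqrt(rowSums(pts^2)) - 10, tolerance = 1e-9)
  semi <- c(12, 8, 5)
  d <- ellipsoid_signed_distance(pts, semi)
  # brute force: minimize distance over the parameterized surface
  for (i in 1:8) {
    q <- pts[i, ]
    obj <- function(p) {
      s <- c(semi[1] * sin(p[1]) * cos(p[2]), semi[2] * sin(p[1]) * sin(p[2]),
             semi[3] * cos(p[1]))
      sum((q - s)^2)
    }
    best <- min(vapply(1:20, function(k) {
      set.seed(k)
      optim(c(runif(1, 0, pi), runif(1, -pi, pi)), obj,
            method = "Nelder-Mead")$value
    }, numeric(1)))
    expect_equal(abs(d[i]), sqrt(best), tolerance = 1e-4)
  }
})

test_that("ellipsoid parallel-body volumes follow the Steiner formula", {
  # sphere as a degenerate ellipsoid: integrals have closed forms
  sm <- sbgrad:::ellipsoid_surface_integrals(c(10, 10, 10))
  expect_equal(sm$area, 4 * pi * 100, tolerance = 1e-4)
  expect_equal(sm$mean_curv, 4 * pi * 10, tolerance = 1e-4)
  spec <- synthetic_plan_spec(
    target = list(type = "ellipsoid", semi_axes = c(12, 8, 6)),
    profile = list(family = "linear", g = 5),
    grid = list(spacing = 0.5, extent = 56)
  )
  gt <- ground_truth(spec, vg_levels = c(80, 100))
  plan <- generate_plan(spec)
  vg <- vg_profile(plan, c(80, 100))
  expect_equal(vg$vg[vg$level_pct == 80],
               gt$levels$vg[gt$levels$level_pct == 80], tolerance = 0.03)
  expect_equal(vg$vg[vg$level_pct == 100], 1, tolerance = 0.03)
})

test_that("engine metrics converge to ground truth as the grid refines", {
  spec_of <- function(sp) linear_sphere_spec(spacing = sp, extent = 46)
  err <- vapply(c(2, 1, 0.5), function(sp) {
    plan <- generate_plan(spec_of(sp))
    vg <- vg_profile(plan, c(50, 90, 100))
    gt <- ground_truth(spec_of(sp), vg_levels = c(50, 90, 100))
    m <- merge(as.data.frame(vg), as.data.frame(gt$levels), by = "level_pct")
    max(abs(m$vg.x - m$vg.y) / m$vg.y)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.03)
})

test_that("OAR geometries land at the requested gap from the target", {
  spec <- synthetic_plan_spec(
    grid = list(spacing = 1, extent = 50),
    oars = list(list(name = "Brainstem", radius = 5, gap = 2,
                     direction = c(1, 0, 0)))
  )
  plan <- generate_plan(spec)
  expect_true("Brainstem" %in% names(plan$structures))
  bs <- plan$structures$Brainstem
  expect_equal(bs$role, "oar")
  expect_equal(structure_volume_cc(bs), 4 / 3 * pi * 125 / 1000,
               tolerance = 0.08)
  # nearest brainstem voxel sits about the gap away from the target surface
  sub <- which(bs$mask, arr.ind = TRUE)
  ax <- grid_axes(bs)
  pts <- cbind(ax$x[sub[, 1]], ax$y[sub[, 2]], ax$z[sub[, 3]])
  expect_equal(min(sqrt(rowSums(pts^2))) - 10, 2, tolerance = 1)
})
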