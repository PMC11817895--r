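test_that("dose grid enforces its invariants", {
  expect_error(dose_grid(matrix(1, 2, 2), 1), "3D")
  expect_error(dose_grid(array(1, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(dose_grid(array(-1, c(2, 2, 2)), 1), "non-negative")
  expect_error(dose_grid(array(NA_real_, c(2, 2, 2)), 1), "finite")
  g <- dose_grid(array(1, c(3, 4, 5)), c(1, 2, 2.5), origin = c(-1, 0, 3))
  expect_equal(voxel_volume_mm3(g), 5)
  expect_equal(voxel_volume_cc(g), 0.005)
  expect_equal(grid_axes(g)$z, c(3, 5.5, 8, 10.5, 13))
})

test_that("plans validate prescription and structure geometry", {
  g <- dose_grid(array(10, c(4, 4, 4)), 1)
  s <- structure_mask(array(TRUE, c(4, 4, 4)), 1, name = "PTV", role = "target")
  expect_error(rt_plan(g, list(s), rx_dose = 0), "rx_dose")
  expect_error(rt_plan(g, list(s), rx_dose = 10, n_fractions = 0), "fractions")
  s2 <- structure_mask(array(TRUE, c(4, 4, 4)), 2, name = "PTV", role = "target")
  expect_error(rt_plan(g, list(s2), rx_dose = 10), "not on the dose grid")
  oar <- structure_mask(array(TRUE, c(4, 4, 4)), 1, name = "BS", role = "oar")
  expect_error(rt_plan(g, list(oar), rx_dose = 10), "target")
  p <- rt_plan(g, list(s, oar), rx_dose = 10)
  expect_identical(p$primary_target, "PTV")
})

test_that("square contours rasterize to exact voxel-center counts", {
  g <- dose_grid(array(0, c(30, 30, 12)), 1, origin = c(0.5, 0.5, 0.5))
  # 20 mm x 20 mm square spanning voxel centers 3.5..22.5 on 10 slices
  sq <- do.call(rbind, lapply(1:10, function(k) {
    tibble::tibble(
      x = c(3, 23, 23, 3), y = c(3, 3, 23, 23),
      z = k + 0.5, loop = k
    )
  }))
  s <- rasterize_structure(sq, g, name = "square")
  expect_equal(sum(s$mask), 20 * 20 * 10)
  expect_equal(structure_volume_cc(s), 4.0)
})

test_that("circle rasterization approaches the analytic area and converges", {
  r <- 10
  errs <- sapply(c(1, 0.5, 0.25), function(sp) {
    n <- round(30 / sp)
    g <- dose_grid(array(0, c(n, n, 3)), sp,
                   origin = c(-15 + sp / 2, -15 + sp / 2, 0))
    ct <- circle_contour(r, center = c(0.13, 0.07), z = grid_axes(g)$z[2])
    s <- rasterize_structure(ct, g)
    area <- sum(s$mask) * sp^2 # one slice: area x slice thickness = volume
    abs(area - pi * r^2) / (pi * r^2)
  })
  expect_lt(errs[2], 0.015) # within 1.5% at 0.5 mm
  expect_true(all(diff(errs) < 0)) # monotone convergence with refinement
})

test_that("holes are honored by the even-odd rule", {
  g <- dose_grid(array(0, c(30, 30, 3)), 1, origin = c(-14.5, -14.5, 0))
  z <- grid_axes(g)$z[2]
  outer_loop <- tibble::tibble(x = c(-10, 10, 10, -10), y = c(-10, -10, 10, 10),
                               z = z, loop = 1)
  inner_loop <- tibble::tibble(x = c(-4, 4, 4, -4), y = c(-4, -4, 4, 4),
                               z = z, loop = 2)
  s <- rasterize_structure(rbind(outer_loop, inner_loop), g)
  expect_equal(sum(s$mask), 20 * 20 - 8 * 8)
})

test_that("contours outside the grid clip with a warning or error out", {
  g <- dose_grid(array(0, c(10, 10, 4)), 1)
  far <- tibble::tibble(x = c(100, 110, 110, 100), y = c(100, 100, 110, 110),
                        z = 1, loop = 1)
  expect_error(expect_warning(rasterize_structure(far, g), "outside"), "empty")
  half <- do.call(rbind, lapply(c(1, 50), function(z) {
    tibble::tibble(x = c(2, 7, 7, 2), y = c(2, 2, 7, 7), z = z, loop = z)
  }))
  expect_warning(s <- rasterize_structure(half, g), "clipped")
  expect_gt(sum(s$mask), 0)
})

test_that("dose resampling is exact for identical grids, constants and affine fields", {
  vals <- array(runif(6 * 5 * 4, 1, 10), c(6, 5, 4))
  g <- dose_grid(vals, c(1, 2, 3), origin = c(0, 0, 0))
  same <- align_dose_to_grid(g, g)
  expect_identical(same$values, g$values)
  const <- dose_grid(array(45, c(8, 8, 8)), 2)
  fine <- dose_grid(array(0, c(6, 6, 6)), 1, origin = c(2, 2, 2))
  expect_equal(unique(as.vector(align_dose_to_grid(const, fine)$values)), 45)
  # affine field: trilinear interpolation reproduces it exactly
  ax <- list(x = 0:7 * 2, y = 0:7 * 2, z = 0:7 * 2)
  aff <- function(x, y, z) 3 + 0.5 * x + 0.25 * y + 0.125 * z
  av <- array(0, c(8, 8, 8))
  for (k in 1:8) av[, , k] <- outer(ax$x, ax$y, function(x, y) aff(x, y, ax$z[k]))
  ag <- dose_grid(av, 2)
  half <- dose_grid(array(0, c(9, 9, 9)), 1, origin = c(2, 2, 2))
  res <- align_dose_to_grid(ag, half)
  axh <- grid_axes(half)
  expected <- array(0, c(9, 9, 9))
  for (k in 1:9) expected[, , k] <- outer(axh$x, axh$y, function(x, y) aff(x, y, axh$z[k]))
  expect_equal(res$values, expected, tolerance = 1e-12)
})

test_that("disjoint grids refuse to resample and outside voxels are flagged", {
  g <- dose_grid(array(1, c(4, 4, 4)), 1)
  far <- dose_grid(array(0, c(4, 4, 4)), 1, origin = c(100, 100, 100))
  expect_error(align_dose_to_grid(g, far), "disjoint")
  part <- dose_grid(array(0, c(4, 4, 4)), 1, origin = c(2, 0, 0))
  expect_warning(res <- align_dose_to_grid(g, part), "outside")
  expect_gt(attr(res, "n_outside"), 0)
})

test_that("fixture round-trip preserves values and metadata bit-exactly", {
  spec <- linear_sphere_spec(spacing = 2, extent = 30)
  plan <- generate_plan(spec)
  dir <- withr::local_tempdir()
  write_plan_fixture(plan, dir)
  back <- read_plan_fixture(dir)
  expect_identical(back$dose$values, plan$dose$values)
  expect_identical(back$dose$spacing, plan$dose$spacing)
  expect_identical(back$dose$origin, plan$dose$origin)
  expect_identical(back$rx_dose, plan$rx_dose)
  expect_identical(back$n_fractions, plan$n_fractions)
  expect_identical(
    back$structures[[plan$primary_target]]$mask,
    plan$structures[[plan$primary_target]]$mask
  )
})
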