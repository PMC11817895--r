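test_that("linear radial falloff yields a flat SBG profile at the falloff rate", {
  plan <- generate_plan(linear_sphere_spec(spacing = 0.5, extent = 46))
  prof <- sbg_profile(plan)
  expect_equal(prof$level_pct, c(50, 60, 70, 80, 90))
  expect_true(all(abs(prof$sbg_pct_per_mm - 5) / 5 < 0.05))
  expect_equal(prof$d_min_mm[prof$level_pct == 50], 10, tolerance = 0.05)
  expect_equal(prof$d_min_mm[prof$level_pct == 90], 2, tolerance = 0.05)
})

test_that("SBG converts distance to %Rx per mm", {
  # a 10% fall within 0.5 mm is 20 %/mm; within 1 mm it is 10 %/mm
  expect_equal((100 - 90) / 0.5, 20)
  prof <- tibble::tibble(level_pct = 90, d_min_mm = c(0.5, 1))
  sbg <- (100 - prof$level_pct) / prof$d_min_mm
  expect_equal(sbg, c(20, 10))
})

test_that("VG matches the analytic volume ratios of the linear sphere", {
  plan <- generate_plan(linear_sphere_spec(spacing = 0.5, extent = 46))
  vg <- vg_profile(plan, levels = c(50, 90, 100))
  expect_equal(vg$vg[vg$level_pct == 100], 1.0, tolerance = 0.03)
  expect_equal(vg$vg[vg$level_pct == 90], 1.728, tolerance = 0.03)
  expect_equal(vg$vg[vg$level_pct == 50], 8.0, tolerance = 0.03)
  expect_true(all(diff(vg$vg[order(vg$level_pct)]) < 0)) # non-increasing in level
})

test_that("gradient index is definitionally VG(50)/VG(100)", {
  plan <- generate_plan(linear_sphere_spec(spacing = 1, extent = 46))
  vg <- vg_profile(plan, levels = c(50, 100))
  gi <- gradient_index(plan)
  expect_equal(gi, vg$vg[vg$level_pct == 50] / vg$vg[vg$level_pct == 100],
               tolerance = 1e-12)
  expect_equal(gi, 8, tolerance = 0.03)
})

test_that("a 2^(1/3) radius ratio between the 50% and 100% shells gives GI = 2", {
  n <- 80
  cc <- (seq_len(n) - (n + 1) / 2) * 0.5
  r <- sqrt(outer(outer(cc^2, cc^2, `+`), cc^2, `+`))
  r100 <- 10
  r50 <- 2^(1 / 3) * r100
  # piecewise-linear radial dose hitting 100%Rx at r100 and 50%Rx at r50
  frac <- approx(c(0, r100, r50, 20), c(1.2, 1, 0.5, 0), xout = r, rule = 2)$y
  g <- dose_grid(array(24 * frac, dim(r)), 0.5, origin = rep(cc[1], 3))
  s <- structure_mask(r <= r100, 0.5, rep(cc[1], 3), name = "PTV", role = "target")
  plan <- rt_plan(g, list(s), rx_dose = 24)
  expect_equal(gradient_index(plan), 2, tolerance = 0.03)
})

test_that("Paddick and RTOG conformity behave as defined", {
  plan <- generate_plan(linear_sphere_spec(spacing = 1, extent = 36))
  expect_equal(paddick_ci(plan), 1) # PIV coincides with the target: exact
  expect_equal(rtog_ci(plan), 1)
  # constructed counts: TV = 10, PIV = 10, TV_PIV = 5 -> PCI = 0.25
  vals <- array(0, c(20, 1, 1))
  vals[6:15] <- 45 # PIV voxels 6..15
  mask <- array(FALSE, c(20, 1, 1))
  mask[1:10] <- TRUE # target voxels 1..10; overlap 6..10 = 5 voxels
  g <- dose_grid(vals, spacing = 10)
  s <- structure_mask(mask, 10, name = "PTV", role = "target")
  p2 <- rt_plan(g, list(s), rx_dose = 45)
  expect_equal(paddick_ci(p2), 5^2 / (10 * 10))
  expect_equal(rtog_ci(p2), 1)
})

test_that("conformity identity RTOG CI == VG(100) holds exactly on any plan", {
  for (plan in list(
    generate_plan(linear_sphere_spec(spacing = 1, extent = 36)),
    generate_plan(logistic_sphere_spec(50, 2.4, spacing = 1, extent = 36)),
    generate_plan(synthetic_plan_spec(
      target = list(type = "ellipsoid", semi_axes = c(12, 8, 6)),
      profile = list(family = "linear", g = 5),
      grid = list(spacing = 1, extent = 40)
    ))
  )) {
    vg100 <- vg_profile(plan, 100)$vg
    expect_identical(rtog_ci(plan), vg100)
    prof <- sbg_profile(plan)
    expect_equal(prof$sbg_pct_per_mm * prof$d_min_mm, 100 - prof$level_pct,
                 tolerance = 1e-12)
  }
})

test_that("all gradient and conformity metrics are dose-scale equivariant", {
  spec <- linear_sphere_spec(spacing = 1, extent = 40)
  p1 <- generate_plan(spec)
  p2 <- p1
  p2$dose <- dose_grid(p1$dose$values * 3.7, p1$dose$spacing, p1$dose$origin)
  p2$rx_dose <- p1$rx_dose * 3.7
  expect_equal(sbg_profile(p2)$sbg_pct_per_mm, sbg_profile(p1)$sbg_pct_per_mm)
  expect_equal(vg_profile(p2)$vg, vg_profile(p1)$vg)
  expect_equal(paddick_ci(p2), paddick_ci(p1))
  expect_equal(homogeneity_index(p2), homogeneity_index(p1))
  expect_equal(gradient_index(p2), gradient_index(p1))
})

test_that("prescription isodose placement flips the SBG level trend", {
  gk <- generate_plan(logistic_sphere_spec(50, 2.4, spacing = 0.5))
  shoulder <- generate_plan(logistic_sphere_spec(90, 1.2, spacing = 0.5))
  pg <- sbg_profile(gk)
  ps <- sbg_profile(shoulder)
  sbg_at <- function(p, l) p$sbg_pct_per_mm[p$level_pct == l]
  expect_gt(sbg_at(pg, 90), sbg_at(pg, 50))
  expect_lt(sbg_at(ps, 90), sbg_at(ps, 50))
  # 1D fine-grid brute force on the radial profile reproduces the distances
  for (case in list(list(p = 50, s = 2.4, prof = pg),
                    list(p = 90, s = 1.2, prof = ps))) {
    dmax_frac <- 100 / case$p
    d0 <- case$s * qlogis(case$p / 100)
    rgrid <- seq(0, 20, by = 1e-4)
    dose1d <- dmax_frac * plogis(-(rgrid - d0) / case$s)
    for (lev in c(50, 90)) {
      d_bf <- rgrid[which(dose1d <= lev / 100)[1]] -
        rgrid[which(dose1d <= 1)[1]]
      expect_equal(case$prof$d_min_mm[case$prof$level_pct == lev], d_bf,
                   tolerance = 0.08)
    }
  }
})

test_that("a zero-exit sector shrinks low-isodose spill (VG at 20%)", {
  iso_spec <- linear_sphere_spec(spacing = 1, extent = 70)
  ani_spec <- synthetic_plan_spec(
    target = list(type = "sphere", radius = 10), rx_dose = 24,
    profile = list(family = "linear", g = 5),
    anisotropy = list(direction = c(1, 0, 0), factor = Inf),
    grid = list(spacing = 1, extent = 70)
  )
  vg_iso <- vg_profile(generate_plan(iso_spec), 20)$vg
  vg_ani <- vg_profile(generate_plan(ani_spec), 20)$vg
  expect_lt(vg_ani, vg_iso)
  gt <- ground_truth(ani_spec, vg_levels = 20)
  expect_equal(vg_ani, gt$levels$vg[gt$levels$level_pct == 20], tolerance = 0.03)
})

test_that("gradient report joins both profiles on the level grid", {
  plan <- generate_plan(linear_sphere_spec(spacing = 1, extent = 46))
  rep <- gradient_report(plan)
  expect_setequal(rep$level_pct, seq(20, 100, 10))
  expect_equal(sum(!is.na(rep$sbg_pct_per_mm)), 5)
  expect_equal(sum(!is.na(rep$vg)), 9)
})
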