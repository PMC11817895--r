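goal_table_path <- system.file("extdata", "goals_skullbase_reirradiation.yaml",
                               package = "sbgrad")

test_that("goal expressions parse into the constraint grammar", {
  g <- parse_goal("Dmax < 10 Gy", "Brainstem", fractions = 3)
  expect_equal(g$metric, "Dmax")
  expect_equal(g$comparator, "<")
  expect_equal(g$threshold, 10)
  expect_equal(g$unit, "Gy")
  expect_equal(g$fractions, 3L)
  expect_equal(parse_goal("V100% > 95%", "PTV")$metric, "Vx%")
  expect_equal(parse_goal("V12 Gy < 3 cm3", "Temporal lobe")$metric_arg, 12)
  expect_equal(parse_goal("Dmax < 120%", "PTV")$unit, "%")
  expect_equal(parse_goal("D50% < 20 Gy", "Cord")$metric_arg, 50)
  expect_error(parse_goal("Dfoo < 10 Gy", "X"), "Cannot parse")
  expect_error(parse_goal("V12 Gy < 3 %", "X"), "not valid")
  expect_error(parse_goal("Dmax < 0 Gy", "X"), "> 0")
})

test_that("the shipped reirradiation constraint table transcribes in full", {
  goals <- read_goal_table(goal_table_path)
  expect_gte(nrow(goals), 17)
  expect_setequal(
    unique(goals$structure),
    c("PTV", "Brainstem", "Spinal cord", "Optic apparatus", "Carotids",
      "Cochlea", "Temporal lobe")
  )
  bs3 <- dplyr::filter(goals, structure == "Brainstem", fractions == 3,
                       !advisory)
  expect_equal(bs3$threshold, 10)
  bs5 <- dplyr::filter(goals, structure == "Brainstem", fractions == 5,
                       !advisory)
  expect_equal(bs5$threshold, 13)
  tl3 <- dplyr::filter(goals, structure == "Temporal lobe", fractions == 3)
  expect_setequal(tl3$text, c("Dmax < 18 Gy", "V12 Gy < 3 cm3"))
})

test_that("a malformed goal table names the offending entry", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("goals:", "  - structure: X", "    goal: 'Dq < 1 Gy'"), f)
  expect_error(read_goal_table(f), "entry 1 \\(X\\)")
})

test_that("goal evaluation computes achieved values, margins and pass flags", {
  goals <- read_goal_table(goal_table_path)
  pass_plan <- goal_test_plan(bs_dose = 9.5, rx = 27, n_fx = 3L)
  rep <- evaluate_goals(pass_plan, goals)
  bs <- dplyr::filter(rep, structure == "Brainstem", !advisory)
  expect_equal(bs$achieved, 9.5)
  expect_true(bs$passed)
  expect_equal(bs$margin, -0.5)
  ptv <- dplyr::filter(rep, structure == "PTV")
  expect_equal(ptv$achieved[ptv$metric == "Vx%"], 100)
  expect_true(all(ptv$passed))
  # absent structures are reported, not failed
  expect_true(all(is.na(dplyr::filter(rep, structure == "Cochlea")$passed)))
  # advisory rows never pass/fail
  expect_true(all(is.na(dplyr::filter(rep, advisory)$passed)))
})

test_that("failing goals are detected for each metric family", {
  goals <- dplyr::bind_rows(
    parse_goal("V100% > 95%", "PTV"),
    parse_goal("Dmax < 120%", "PTV")
  )
  # half-covered target fails V100%; 125% hot spot fails the Dmax% goal
  vals <- array(c(rep(40, 500), rep(39, 500)), c(10, 10, 10))
  vals[1] <- 50 # 125% of 40 Gy
  p <- plan_from_values(vals, spacing = 4, rx = 40)
  rep <- evaluate_goals(p, goals)
  expect_false(rep$passed[rep$metric == "Vx%"]) # 50% < 95%
  expect_false(rep$passed[rep$metric == "Dmax"]) # 125% > 120%
  expect_equal(rep$achieved[rep$metric == "Vx%"], 50, tolerance = 0.2)
})

test_that("goal reports are byte-stable for identical inputs", {
  goals <- read_goal_table(goal_table_path)
  plan <- goal_test_plan(bs_dose = 9, rx = 27, n_fx = 3L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_goal_report(evaluate_goals(plan, goals), f1)
  write_goal_report(evaluate_goals(plan, goals), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("Dmax goals can fall back to the single hottest voxel", {
  goals <- parse_goal("Dmax < 13 Gy", "Brainstem", fractions = 5)
  plan <- goal_test_plan(bs_dose = 11)
  hot <- plan
  hot$dose$values[which(plan$structures$Brainstem$mask)[1]] <- 13.5
  # one hot voxel (0.008 cm^3) does not move D0.01cc above 13 Gy by itself
  r1 <- evaluate_goals(hot, goals, dmax_mode = "d001cc")
  r2 <- evaluate_goals(hot, goals, dmax_mode = "voxel")
  expect_true(r1$passed)
  expect_false(r2$passed)
  expect_equal(r2$achieved, 13.5)
})
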