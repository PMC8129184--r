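phi <- (sqrt(5) - 1) / 2

test_that("golden search finds known maxima and shrinks by phi per iteration", {
  gs <- golden_search(function(x) -(x - 5)^2, 2, 10, tol = 1e-4)
  expect_equal(gs$argmax, 5, tolerance = 1e-4)
  # the interval shrinks by exactly phi each iteration
  widths <- gs$trace$b - gs$trace$a
  expect_equal(widths[-1] / widths[-length(widths)],
               rep(phi, length(widths) - 1), tolerance = 1e-12)
  expect_equal(widths, 8 * phi^(seq_along(widths) - 1), tolerance = 1e-9)
  # asymmetric and flat-topped objectives still converge inside the bracket
  gs2 <- golden_search(function(x) dnorm(x, 3.3, 0.7), 0, 10, tol = 1e-3)
  expect_equal(gs2$argmax, 3.3, tolerance = 1e-3)
})

test_that("iteration count matches the closed-form golden bound", {
  cases <- list(c(2, 10, 0.2), c(0.7, 1.6, 0.1), c(0, 1, 1e-3), c(-4, 3, 0.37))
  for (cs in cases) {
    W <- cs[2] - cs[1]
    expected_iters <- ceiling(log(cs[3] / W) / log(phi))
    for (f in list(function(x) -(x - mean(cs[1:2]))^2, function(x) sin(x / 10))) {
      gs <- golden_search(f, cs[1], cs[2], tol = cs[3])
      expect_equal(gs$iterations, expected_iters)
      expect_equal(gs$n_evaluations, expected_iters + 1)
      expect_lt(gs$interval[2] - gs$interval[1], cs[3])
    }
  }
})

test_that("grid bracketing returns the neighbors of the argmax", {
  br <- bracket_from_grid(function(x) -(x - 6.5)^2, c(2, 6, 10))
  expect_equal(c(br$a, br$b), c(2, 10))
  expect_equal(br$argmax, 6)
  g1 <- c(0.25, 0.7, 1.15, 1.6, 2.05, 2.6)
  br2 <- bracket_from_grid(function(x) -(x - 1.13)^2, g1)
  expect_equal(c(br2$a, br2$b), c(0.7, 1.6))
  expect_error(bracket_from_grid(function(x) -x, g1), "boundary")
  expect_error(bracket_from_grid(function(x) x, g1), "boundary")
  expect_error(bracket_from_grid(function(x) x, c(2, 6)), "length")
})

test_that("bracketing plus refinement reproduces the published evaluation budget", {
  # alpha stage: grid (2, 6, 10), tolerance 0.2 -> 8 iterations, 12 evaluations
  st <- braincalib:::search_stage(function(x) -(x - 6.3)^2, c(2, 6, 10), 0.2)
  expect_equal(st$iterations, 8)
  expect_equal(st$n_evaluations, 12)
  expect_equal(st$n_evaluations - nrow(st$bracket$evaluations), 9)
  expect_equal(st$argmax, 6.3, tolerance = 0.2)
  # ledger bookkeeping: reused rows point at already-evaluated parameters
  reused <- st$ledger[st$ledger$reused, ]
  fresh <- st$ledger[!st$ledger$reused, ]
  expect_true(all(round(reused$param, 9) %in% round(fresh$param, 9)))
})

test_that("non-finite objectives abort the search", {
  expect_error(golden_search(function(x) ifelse(x > 5, NaN, x), 2, 10, 0.5),
               "non-finite")
})

test_that("configuration defaults encode the staged design", {
  cfg <- calibration_config()
  expect_equal(cfg$stage1_grid, c(0.25, 0.7, 1.15, 1.6, 2.05, 2.6))
  expect_equal(cfg$stage1_tol, 0.1)
  expect_equal(cfg$stage2_grid, c(2, 6, 10))
  expect_equal(cfg$stage2_tol, 0.2)
  expect_equal(cfg$duration_ms, 200)
  expect_equal(cfg$stage1_case, "z-20-60")
  expect_equal(cfg$stage2_case, "x-40-30")
  expect_error(calibration_config(stage1_grid = c(1, 1, 2)), "strictly")
  expect_error(calibration_config(stage1_tol = 0), "stage1_tol")
})

test_that("the joint objective at the true parameters is exact on a clean bundle", {
  bundle <- tiny_bundle()
  cfg <- tiny_config()
  truth <- braincalib:::joint_wccora(
    bundle, "z-20-60",
    function(ctr) build_material_cards(ctr, 1.125, 6.67, bundle$prony), cfg)
  expect_equal(truth, 1, tolerance = 1e-9)
  off <- braincalib:::joint_wccora(
    bundle, "z-20-60",
    function(ctr) build_material_cards(ctr, 2.25, 6.67, bundle$prony), cfg)
  expect_lt(off, truth)
})

test_that("stage 1 recovers the modulus on a clean bundle and logs its search", {
  bundle <- tiny_bundle()
  cfg <- tiny_config()
  s1 <- calibrate_stage1(bundle, cfg)
  expect_lt(abs(s1$mu0_med - 1.125), cfg$stage1_tol)
  expect_equal(s1$search$iterations,
               ceiling(log(cfg$stage1_tol / 0.9) / log(phi)))
  # every stage-1 evaluation is a Neo-Hookean (alpha = 2) card set by design
  expect_equal(s1$stage, 1L)
  cfg_bad <- calibration_config(stage1_case = "y-40-60", duration_ms = 120)
  expect_error(calibrate_stage1(bundle, cfg_bad), "lacks")
})

test_that("stage 2 preserves the calibrated infinitesimal modulus at every step", {
  bundle <- tiny_bundle()
  cfg <- tiny_config()
  s2 <- calibrate_stage2(bundle, 1.125, cfg)
  expect_lt(abs(s2$alpha - 6.67), 2 * cfg$stage2_tol)
  # the mu0-preserving construction pins the median card at mu0_med for every
  # alpha the search visited
  for (a in s2$search$ledger$param) {
    cs <- build_material_cards(reference_gamma_centers(), 1.125, a, bundle$prony)
    expect_equal(infinitesimal_shear_modulus(cs$median_card$ogden), 1.125,
                 tolerance = 1e-9)
    expect_equal(vapply(cs$cards, function(cc) infinitesimal_shear_modulus(cc$ogden),
                        numeric(1)),
                 1.125 * reference_gamma_centers(), tolerance = 1e-9)
  }
})

test_that("the full staged run produces a coherent, reproducible report", {
  bundle <- make_dataset(cases = c("z-20-60", "x-40-30", "x-20-60"), seed = 33,
                         n_subjects = 2, n_nodes = 40, n_receivers = 6,
                         duration_ms = 120)
  cfg <- tiny_config()
  rep1 <- run_calibration(bundle, cfg)
  expect_s3_class(rep1, "calibration_report")
  # held-out low-severity verification precedes stage 2
  expect_equal(sort(unique(rep1$stage1_verification$case_id)), "x-20-60")
  expect_equal(nrow(rep1$verification), 2 * 3)
  # on a noise-free bundle the calibrated material reproduces the experiments
  expect_gt(rep1$summary$mean_wccora, 0.95)
  expect_true(all(c("mean_wccora", "sd_wccora", "min_wccora", "max_wccora")
                  %in% names(rep1$summary)))
  # determinism: the same bundle and config give a bit-identical report
  rep2 <- run_calibration(bundle, cfg)
  expect_identical(glance(rep1), glance(rep2))
  expect_identical(rep1$verification, rep2$verification)
  g <- glance(rep1)
  expect_equal(g$stage2_evaluations, 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(rep1, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$mu0_med_kpa, rep1$mu0_med)
  expect_equal(parsed$summary$mean_wccora, rep1$summary$mean_wccora)
})

test_that("tidiers expose the search trace and verification table", {
  gs <- golden_search(function(x) -(x - 5)^2, 2, 10, tol = 0.1)
  tr <- tidy(gs)
  expect_true(all(c("iteration", "a", "b", "x1", "x2", "f1", "f2") %in% names(tr)))
  gl <- glance(gs)
  expect_equal(gl$iterations, nrow(tr))
  expect_lt(gl$final_width, 0.1)
})
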