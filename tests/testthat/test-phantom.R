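test_that("half-sine pulses integrate to the closed-form total angle", {
  p <- make_pulse("x", 40, 30)
  expect_equal(p$theta_at(1e6), 2 * 40 * 0.030 / pi, tolerance = 1e-12)
  expect_equal(p$theta_at(200), 0.7639437, tolerance = 1e-6)
  expect_equal(p$omega_at(15), 40)                   # mid-pulse peak
  expect_equal(p$omega_at(c(-1, 31, 200)), c(0, 0, 0))
  expect_equal(p$theta_at(0), 0)
  z <- make_pulse("axial", 0, 60)
  expect_equal(z$axis, "z")
  expect_equal(z$omega_at(seq(0, 100, 5)), rep(0, 21))
  expect_equal(z$theta_at(seq(0, 100, 5)), rep(0, 21))
  m <- default_case_matrix()
  expect_equal(nrow(m), 12)
  expect_setequal(m$axis, c("x", "y", "z"))
  expect_true(all(c("x-40-30", "z-20-60") %in% m$case_id))
})

test_that("synthetic MRE volumes hit the target median and are seed-stable", {
  v <- generate_synthetic_mre(shape = c(48, 48, 48), seed = 5)
  med <- median(v$values, na.rm = TRUE)
  expect_lt(abs(med - 2.53) / 2.53, 0.01)
  v2 <- generate_synthetic_mre(shape = c(48, 48, 48), seed = 5)
  expect_identical(v$values, v2$values)
  v3 <- generate_synthetic_mre(shape = c(48, 48, 48), seed = 6)
  expect_false(identical(v$values, v3$values))
  flat <- generate_synthetic_mre(shape = c(16, 16, 16), sd_kpa = 0, seed = 5)
  inside <- flat$values[!is.na(flat$values)]
  expect_equal(max(inside) - min(inside), 0)
  expect_error(truncate_and_normalize(flat), "degenerate")
  expect_error(generate_synthetic_mre(shape = c(8, 8, 8)), "seed")
})

test_that("phantom construction is connected, labelled and reproducible", {
  ph <- tiny_phantom()
  expect_gt(ph$n_int, 20)
  expect_equal(length(ph$gamma_nodes), ph$n_int)
  expect_true(all(ph$gamma_nodes %in% ph$labels$centers))
  expect_true(all(ph$gamma_spring >= min(ph$labels$centers) &
                    ph$gamma_spring <= max(ph$labels$centers)))
  expect_equal(length(ph$receivers), 6)
  # every interior node reaches the shell through the spring graph
  reach <- braincalib:::connected_to_shell(ph$n_int, ph$springs)
  expect_true(all(reach))
  ph2 <- tiny_phantom()
  expect_identical(ph$nodes, ph2$nodes)
  expect_identical(ph$springs, ph2$springs)
})

test_that("simulation responds physically to load and stiffness", {
  ph <- tiny_phantom()
  cards <- tiny_cards(ph)
  still <- simulate_phantom(ph, make_pulse("x", 0, 30), cards, duration_ms = 60)
  expect_equal(max(abs(c(still$x_mm, still$y_mm, still$z_mm))), 0)
  s20 <- simulate_phantom(ph, make_pulse("x", 20, 30), cards, duration_ms = 120)
  s40 <- simulate_phantom(ph, make_pulse("x", 40, 30), cards, duration_ms = 120)
  peak <- function(s) max(sqrt(s$x_mm^2 + s$y_mm^2 + s$z_mm^2))
  expect_gt(peak(s40), peak(s20))
  stiff <- simulate_phantom(ph, make_pulse("x", 40, 30),
                            tiny_cards(ph, mu0 = 11.25), duration_ms = 120)
  expect_lt(peak(stiff), peak(s40))
  # toward the rigid limit the relative displacement collapses monotonically
  # (the rotational coupling through radial anchor springs is second-order
  # geometric, so convergence is slow but steady over stiffness decades)
  pk <- c()
  for (m in c(112.5, 1125, 11250)) {
    r <- simulate_phantom(ph, make_pulse("x", 40, 30), tiny_cards(ph, mu0 = m),
                          duration_ms = 120, dt_ms = if (m > 2000) 0.004 else 0.01)
    pk <- c(pk, peak(r))
  }
  expect_true(all(diff(pk) < 0))
  expect_lt(pk[1], 0.5 * peak(s40))
  expect_lt(pk[3], 0.1 * peak(s40))
  # determinism of the integrator
  again <- simulate_phantom(ph, make_pulse("x", 40, 30), cards, duration_ms = 120)
  expect_identical(s40, again)
})

test_that("kinetic energy dissipates after the pulse ends", {
  ph <- tiny_phantom()
  sim <- simulate_phantom(ph, make_pulse("y", 40, 30), tiny_cards(ph),
                          duration_ms = 200)
  ke <- attr(sim, "kinetic_j")
  during <- max(ke$kinetic_j[ke$time_ms <= 60])
  late <- max(ke$kinetic_j[ke$time_ms >= 160])
  expect_lt(late, 0.05 * during)
})

test_that("unstable time steps are rejected with the stability limit named", {
  ph <- tiny_phantom()
  expect_error(simulate_phantom(ph, make_pulse("x", 20, 30),
                                tiny_cards(ph, mu0 = 5000), duration_ms = 60),
               "stability")
  expect_error(simulate_phantom(ph, make_pulse("x", 20, 30),
                                build_material_cards(c(0.9, 1.1), 1.125, 6.67,
                                                     brain_prony())),
               "cover")
})

test_that("synthetic bundles carry provenance and regenerate bit-identically", {
  b1 <- tiny_bundle(seed = 44)
  b2 <- make_dataset(cases = b1$provenance$case_ids, seed = b1$provenance$seed,
                     n_subjects = b1$provenance$n_subjects,
                     n_nodes = b1$provenance$n_nodes,
                     n_receivers = b1$provenance$n_receivers,
                     duration_ms = b1$provenance$duration_ms)
  expect_identical(b1$records, b2$records)
  expect_equal(b1$provenance$true_mu0_med, 1.125)
  expect_equal(b1$provenance$true_alpha, 6.67)
  # records cover 200 * duration grid at uniform dt for every receiver
  rec <- b1$records[[1]][["z-20-60"]][[1]]
  expect_equal(rec$time_ms, seq(0, 120, by = 0.1))
  # noise changes records but not provenance-driven structure
  bn <- tiny_bundle(seed = 44, noise = 0.05)
  expect_false(identical(bn$records, b1$records))
  expect_equal(names(bn$records), names(b1$records))
})

test_that("the noise-free objective peaks at the true parameters along transects", {
  bundle <- tiny_bundle(seed = 51)
  cfg <- tiny_config()
  mu_grid <- c(0.5, 0.75, 1, 1.125, 1.3, 1.7, 2.2)
  f_mu <- vapply(mu_grid, function(m) braincalib:::joint_wccora(
    bundle, "z-20-60",
    function(ctr) build_material_cards(ctr, m, 6.67, bundle$prony), cfg),
    numeric(1))
  expect_equal(mu_grid[which.max(f_mu)], 1.125)
  al_grid <- c(2, 3.5, 5, 6.67, 8, 9, 10)
  f_al <- vapply(al_grid, function(a) braincalib:::joint_wccora(
    bundle, "x-40-30",
    function(ctr) build_material_cards(ctr, 1.125, a, bundle$prony), cfg),
    numeric(1))
  expect_equal(al_grid[which.max(f_al)], 6.67)
  # with noise, the objective at truth still beats a 2x-stiff model
  bn <- tiny_bundle(seed = 51, noise = 0.05)
  at_truth <- braincalib:::joint_wccora(
    bn, "z-20-60",
    function(ctr) build_material_cards(ctr, 1.125, 6.67, bn$prony), cfg)
  at_double <- braincalib:::joint_wccora(
    bn, "z-20-60",
    function(ctr) build_material_cards(ctr, 2.25, 6.67, bn$prony), cfg)
  expect_gt(at_truth, at_double)
})

test_that("strain-truth fields partition the mask into three regions", {
  ph <- tiny_phantom()
  out <- make_strain_truth(ph, make_pulse("z", 40, 30), tiny_cards(ph),
                           grid_spacing_mm = 8, duration_ms = 80)
  expect_s3_class(out$field, "displacement_field")
  mask <- out$field$mask
  expect_gt(sum(mask), 100)
  regs <- out$regions
  expect_true(all(is.na(regs[!mask])))
  expect_setequal(unique(regs[mask]), 1:3)
  expect_true(out$time_ms > 0 && out$time_ms <= 80)
})
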