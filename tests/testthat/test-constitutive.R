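test_that("infinitesimal shear modulus and its inverse are consistent", {
  expect_equal(infinitesimal_shear_modulus(ogden_params(0.337, 6.67)), 1.123895,
               tolerance = 1e-6)
  expect_equal(infinitesimal_shear_modulus(ogden_params(1, 2)), 1)
  expect_equal(infinitesimal_shear_modulus(ogden_params(0.179, 6.67)), 0.597,
               tolerance = 1e-3)
  for (alpha in c(-4, 2, 6.67, 9)) {
    mu0 <- 1.31
    og <- ogden_params(abs(mu_from_mu0(mu0, alpha)), alpha)
    expect_equal(infinitesimal_shear_modulus(og), sign(alpha) * mu0)
  }
})

test_that("parameter containers enforce their invariants", {
  expect_error(ogden_params(-1, 2), "positive")
  expect_error(ogden_params(1, 0), "non-zero")
  expect_error(prony_series(c(0.5, 0.6), c(1, 0.1)), ">= 0")   # implied g_inf < 0
  expect_error(prony_series(c(0.5, 0.4), c(1, 0.1), g_inf = 0.2), "normalization")
  expect_error(prony_series(c(0.5, -0.1), c(1, 0.1), 0.6), ">= 0")
  expect_error(prony_series(0.5, -1, 0.5), "positive")
  pr <- prony_series(c(0.02, 0.9), c(0.1, 10))   # tau re-sorted decreasing
  expect_equal(pr$tau, c(10, 0.1))
  expect_equal(pr$g, c(0.9, 0.02))
  expect_error(material_card(ogden_params(1, 2), pr, poisson = 0.5), "0.5")
  expect_error(material_card(ogden_params(1, 2), pr, density = 0), "positive")
})

test_that("instantaneous stress matches Neo-Hookean closed forms at alpha = 2", {
  mu <- 0.85
  og <- ogden_params(mu, 2)
  lam <- seq(0.6, 1.8, by = 0.05)
  expect_equal(instantaneous_stress("tension", lam - 1, og),
               mu * (lam - lam^-2), tolerance = 1e-10)
  cstr <- seq(0.05, 0.4, by = 0.05)
  expect_equal(instantaneous_stress("compression", cstr, og),
               mu * ((1 - cstr) - (1 - cstr)^-2), tolerance = 1e-10)
  gam <- seq(-0.8, 0.8, by = 0.1)
  expect_equal(instantaneous_stress("simple_shear", gam, og), mu * gam,
               tolerance = 1e-10)
})

test_that("uniaxial stress equals the derivative of the strain energy", {
  # W(lambda) under incompressible uniaxial kinematics, differentiated centrally
  for (alpha in c(2, 4.5, 6.67)) {
    og <- ogden_params(0.4, alpha)
    W <- function(l) (og$mu / alpha) * (l^alpha + 2 * l^(-alpha / 2) - 3)
    h <- 1e-6
    for (lam in c(0.7, 1.1, 1.5)) {
      expect_equal(instantaneous_stress("tension", lam - 1, og),
                   (W(lam + h) - W(lam - h)) / (2 * h), tolerance = 1e-6)
    }
  }
  expect_equal(instantaneous_stress("tension", 0.5, ogden_params(1, 2)), 1.0556,
               tolerance = 1e-4)
})

test_that("stress is zero at zero strain and the shear slope is mu0", {
  for (alpha in c(2, 6.67, -3)) {
    og <- ogden_params(0.3, alpha)
    for (mode in c("tension", "compression", "simple_shear"))
      expect_equal(instantaneous_stress(mode, 0, og), 0)
    h <- 1e-7
    slope <- instantaneous_stress("simple_shear", h, og) / h
    expect_equal(slope, infinitesimal_shear_modulus(og), tolerance = 1e-5)
  }
  expect_error(instantaneous_stress("tension", -1, ogden_params(1, 2)), "domain")
})

test_that("reduced relaxation is normalized, bounded and monotone", {
  pr <- brain_prony()
  expect_equal(pr$g_inf, 0.0337, tolerance = 1e-9)
  expect_equal(reduced_relaxation(0, pr), 1)
  expect_equal(reduced_relaxation(1e9, pr), 0.0337, tolerance = 1e-6)
  t10 <- 0.0337 + sum(pr$g * exp(-10 / pr$tau))
  expect_equal(reduced_relaxation(10, pr), t10)
  tt <- seq(0, 100, by = 0.1)
  g <- reduced_relaxation(tt, pr)
  expect_true(all(diff(g) <= 1e-12))
  expect_true(all(g > 0 & g <= 1))
  expect_error(reduced_relaxation(-1, pr), "non-negative")
})

test_that("complex modulus has the right limits and scaling", {
  pr <- brain_prony()
  og <- ogden_params(0.337, 6.67)
  lowf <- complex_modulus(1e-9, og, pr)
  expect_equal(lowf$storage_kpa, infinitesimal_shear_modulus(og), tolerance = 1e-6)
  expect_equal(lowf$loss_kpa, 0, tolerance = 1e-6)
  # instantaneous reference: static limit is g_inf * mu0
  lowf_i <- complex_modulus(1e-9, og, pr, reference = "instantaneous")
  expect_equal(lowf_i$storage_kpa, pr$g_inf * infinitesimal_shear_modulus(og),
               tolerance = 1e-6)
  # scaling mu by c scales both components; tan(delta) unchanged
  freq <- 10^seq(-1, 2, length.out = 7)
  base <- complex_modulus(freq, og, pr)
  for (cc in c(0.2, 3, 10)) {
    sc <- complex_modulus(freq, ogden_params(og$mu * cc, og$alpha), pr)
    expect_equal(sc$storage_kpa, cc * base$storage_kpa)
    expect_equal(sc$loss_kpa, cc * base$loss_kpa)
    expect_equal(sc$tan_delta, base$tan_delta)
  }
  # single-term spectrum at omega * tau = 1
  p1 <- prony_series(0.7, 5)
  f1 <- 1 / (2 * pi * 5e-3)
  cm <- complex_modulus(f1, ogden_params(1, 2), p1, reference = "instantaneous")
  expect_equal(cm$storage_kpa, 0.3 + 0.7 / 2, tolerance = 1e-12)
  expect_equal(cm$loss_kpa, 0.7 / 2, tolerance = 1e-12)
  expect_error(complex_modulus(0, og, pr), "positive")
})

test_that("tan delta vanishes in both elastic limits and peaks where predicted", {
  p1 <- prony_series(0.6, 1)
  expect_lt(tan_delta(1e-8, p1), 1e-6)
  expect_lt(tan_delta(1e8, p1), 1e-6)
  # dense-grid oracle for the single-term maximum s* = sqrt(ginf/(ginf + g1))
  s_grid <- 10^seq(-3, 3, length.out = 20000)
  f_grid <- s_grid / (2 * pi * 1e-3)    # tau = 1 ms
  td <- tan_delta(f_grid, p1)
  s_star <- s_grid[which.max(td)]
  expect_equal(s_star, sqrt(0.4 / (0.4 + 0.6)), tolerance = 1e-3)
  # consistency with the complex-modulus ratio for the four-term spectrum
  pr <- brain_prony()
  cm <- complex_modulus(10, ogden_params(1, 2), pr)
  expect_equal(tan_delta(10, pr), cm$loss_kpa / cm$storage_kpa)
})

test_that("tan delta is invariant under stiffness scaling for random spectra", {
  set.seed(11)
  freq <- 10^seq(-1, 3, length.out = 9)
  for (k in 1:10) {
    g <- runif(3); g <- 0.9 * g / sum(g)
    pr <- prony_series(g, sort(10^runif(3, -2, 1), decreasing = TRUE))
    base <- tan_delta(freq, pr)
    for (cc in c(0.5, 2, 7)) {
      og <- ogden_params(cc, 4)
      cm <- complex_modulus(freq, og, pr)
      expect_equal(cm$tan_delta, base, tolerance = 1e-12)
    }
  }
})

test_that("fit_prony round-trips spectra from its own model class", {
  pr <- brain_prony()
  f <- 10^seq(-1, 3, length.out = 30)
  fit <- fit_prony(data.frame(freq_hz = f, tan_delta = tan_delta(f, pr)))
  expect_equal(fit$g, pr$g, tolerance = 1e-3)
  expect_equal(fit$g_inf, pr$g_inf, tolerance = 1e-3)
  expect_equal(fit$tau, pr$tau)
  # single-term synthetic spectrum, 1-term fit
  p1 <- prony_series(0.6, 1)
  fit1 <- fit_prony(data.frame(freq_hz = f, tan_delta = tan_delta(f, p1)),
                    n_terms = 1, tau_grid = 1)
  expect_equal(fit1$g, 0.6, tolerance = 1e-4)
  # identically zero data -> purely elastic
  fit0 <- fit_prony(data.frame(freq_hz = f, tan_delta = rep(0, length(f))))
  expect_equal(fit0$g, rep(0, 4))
  expect_equal(fit0$g_inf, 1)
  expect_error(fit_prony(data.frame(freq_hz = 1, tan_delta = 0.1)), "at least")
})

test_that("QLV reduces to the elastic law without Prony terms", {
  card <- material_card(ogden_params(1, 2), prony_series(numeric(0), numeric(0), 1))
  eps <- c(0, 0.1, 0.25, 0.4, 0.3)
  h <- qlv_stress_history(eps, "simple_shear", card, dt = 1)
  expect_equal(h$stress_kpa, instantaneous_stress("simple_shear", eps, card$ogden),
               tolerance = 1e-12)
})

test_that("QLV step strain relaxes by the reduced relaxation function", {
  pr <- brain_prony()
  card <- material_card(ogden_params(1, 2), pr, reference = "instantaneous")
  eps0 <- 0.2
  dt <- 0.004
  eps <- c(0, rep(eps0, 30000))   # 120 ms, ~12 tau_1 past the slowest term
  h <- qlv_stress_history(eps, "simple_shear", card, dt = dt)
  Te <- instantaneous_stress("simple_shear", eps0, card$ogden)
  # sigma(t) tracks g(t) * T^e after the one-step ramp
  for (tm in c(1, 5, 20, 60)) {
    i <- round(tm / dt) + 1L
    expect_equal(h$stress_kpa[i], reduced_relaxation(tm, pr) * Te, tolerance = 0.02)
  }
  expect_equal(h$stress_kpa[length(eps)] / h$stress_kpa[2], pr$g_inf,
               tolerance = 0.01)
})

test_that("QLV linear ramp matches a fine-grid convolution oracle", {
  pr <- prony_series(0.6, 4)
  card <- material_card(ogden_params(1, 2), pr, reference = "instantaneous")
  dur <- 20; dt <- 0.1
  tt <- seq(0, dur, by = dt)
  eps <- 0.3 * tt / dur
  got <- qlv_stress_history(eps, "simple_shear", card, dt = dt)
  # trapezoid-rule convolution of g(t - s) dT/ds on a 10x finer grid
  dtf <- dt / 10
  tf <- seq(0, dur, by = dtf)
  Te <- instantaneous_stress("simple_shear", 0.3 * tf / dur, card$ogden)
  dTe <- diff(Te)
  oracle <- vapply(seq_along(tf), function(i) {
    if (i == 1) return(0)
    g <- reduced_relaxation(tf[i] - (tf[-length(tf)][1:(i - 1)] + dtf / 2), pr)
    sum(g * dTe[1:(i - 1)])
  }, numeric(1))
  idx <- seq(1, length(tf), by = 10)
  expect_equal(got$stress_kpa, oracle[idx], tolerance = 5e-3)
})

test_that("QLV output converges under time-step refinement", {
  pr <- brain_prony()
  card <- material_card(ogden_params(0.337, 6.67), pr)
  dur <- 16
  for (dt in c(0.02, 0.01)) {
    tt <- seq(0, dur, by = dt)
    eps <- 0.5 * sin(pi * tt / dur / 2)^2
    coarse <- qlv_stress_history(eps, "simple_shear", card, dt = dt)
    tt2 <- seq(0, dur, by = dt / 2)
    fine <- qlv_stress_history(0.5 * sin(pi * tt2 / dur / 2)^2, "simple_shear",
                               card, dt = dt / 2)
    expect_equal(coarse$stress_kpa[-1],
                 fine$stress_kpa[seq(3, length(tt2), by = 2)],
                 tolerance = 5e-3)
  }
})

test_that("single-element curves respect rate ordering and stiffness scaling", {
  pr <- brain_prony()
  card <- material_card(ogden_params(0.337, 6.67), pr)
  for (mode in c("tension", "compression", "simple_shear")) {
    c30 <- single_element_curves(card, mode, 30)
    c5 <- single_element_curves(card, mode, 5)
    c05 <- single_element_curves(card, mode, 0.5)
    expect_gte(nrow(c30), 100)
    expect_true(all(abs(c30$stress_kpa) >= abs(c5$stress_kpa) - 1e-10))
    expect_true(all(abs(c5$stress_kpa) >= abs(c05$stress_kpa) - 1e-10))
  }
  # mu scaling is a pointwise factor
  card2 <- material_card(ogden_params(0.337 * 1.53, 6.67), pr)
  a <- single_element_curves(card, "simple_shear", 5)
  b <- single_element_curves(card2, "simple_shear", 5)
  expect_equal(b$stress_kpa, 1.53 * a$stress_kpa, tolerance = 1e-10)
  # quasi-static reference converges to the static Ogden curve at slow rates
  slow <- single_element_curves(card, "tension", 1e-4)
  static <- instantaneous_stress("tension", slow$strain, card$ogden)
  expect_equal(slow$stress_kpa[-1], static[-1], tolerance = 0.01)
})

test_that("material cards round-trip through JSON", {
  card <- material_card(ogden_params(0.337, 6.67), brain_prony())
  path <- withr::local_tempfile(fileext = ".json")
  write_material_card(card, path)
  back <- read_material_card(path)
  expect_equal(back$ogden$mu, card$ogden$mu)
  expect_equal(back$prony$g, card$prony$g)
  expect_equal(back$reference, "quasi_static")
})
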