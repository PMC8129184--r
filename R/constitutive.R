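#' Ogden hyperelastic parameters
#'
#' Container for the deviatoric elasticity of a one-term Ogden solid with
#' strain-energy density \eqn{W = (\mu/\alpha)(\lambda_1^\alpha +
#' \lambda_2^\alpha + \lambda_3^\alpha - 3)}.
#'
#' @param mu Shear-modulus coefficient, kPa. Must be positive.
#' @param alpha Dimensionless non-linearity coefficient. Must be non-zero;
#'   `alpha = 2` recovers an incompressible Neo-Hookean solid.
#' @return An object of class `ogden_params`.
#' @export
#' @examples
#' ogden_params(mu = 0.337, alpha = 6.67)
ogden_params <- function(mu, alpha) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  if (alpha == 0) stop("`alpha` must be non-zero", call. = FALSE)
  structure(list(mu = mu, alpha = alpha), class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("<ogden_params> mu = %.4g kPa, alpha = %.4g (mu0 = %.4g kPa)\n",
              x$mu, x$alpha, infinitesimal_shear_modulus(x)))
  invisible(x)
}

#' Prony-series reduced relaxation spectrum
#'
#' Normalized relaxation function \eqn{g(t) = g_\infty + \sum_i g_i
#' e^{-t/\tau_i}} with the constraint \eqn{g_\infty + \sum_i g_i = 1} so that
#' \eqn{g(0) = 1}.
#'
#' @param g Numeric vector of non-negative normalized coefficients.
#' @param tau Matching vector of time constants, ms; strictly positive.
#' @param g_inf Long-term normalized coefficient. Defaults to `1 - sum(g)`.
#' @return An object of class `prony_series`, with `tau` sorted in strictly
#'   decreasing order.
#' @export
#' @examples
#' # four-decade brain parenchyma spectrum
#' prony_series(g = c(0.8619, 0.0383, 0.0412, 0.0249), tau = c(10, 1, 0.1, 0.01))
prony_series <- function(g, tau, g_inf = 1 - sum(g)) {
  stopifnot(is.numeric(g), is.numeric(tau), length(g) == length(tau),
            is.numeric(g_inf), length(g_inf) == 1L)
  if (any(!is.finite(g)) || any(g < 0)) stop("all `g` must be finite and >= 0", call. = FALSE)
  if (g_inf < 0) stop("`g_inf` must be >= 0", call. = FALSE)
  if (any(tau <= 0)) stop("all `tau` must be strictly positive", call. = FALSE)
  if (anyDuplicated(tau)) stop("`tau` values must be distinct", call. = FALSE)
  if (abs(g_inf + sum(g) - 1) > 1e-9)
    stop("normalization violated: g_inf + sum(g) must equal 1", call. = FALSE)
  ord <- order(tau, decreasing = TRUE)
  structure(list(g = as.numeric(g[ord]), tau = as.numeric(tau[ord]),
                 g_inf = as.numeric(g_inf)),
            class = "prony_series")
}

#' @export
print.prony_series <- function(x, ...) {
  cat(sprintf("<prony_series> %d terms, g_inf = %.4g\n", length(x$g), x$g_inf))
  print(tibble::tibble(g = x$g, tau_ms = x$tau))
  invisible(x)
}

#' Ogden-QLV material card
#'
#' Bundles the deviatoric elasticity, the reduced relaxation spectrum and the
#' bulk constants used for a single material part.
#'
#' @param ogden An [ogden_params()] object.
#' @param prony A [prony_series()] object.
#' @param density Mass density, kg/mm^3. Default 1.123e-6 (brain parenchyma).
#' @param poisson Poisson's ratio, near-incompressible default 0.499999.
#' @param reference Modulus reference convention. `"quasi_static"` (default)
#'   treats `mu` as the long-term (equilibrium) modulus, so the relaxation
#'   function is rescaled by `1/g_inf`; `"instantaneous"` uses the textbook
#'   QLV form where `mu` scales the instantaneous elastic response.
#' @return An object of class `material_card`.
#' @export
material_card <- function(ogden, prony,
                          density = 1.123e-6, poisson = 0.499999,
                          reference = c("quasi_static", "instantaneous")) {
  stopifnot(inherits(ogden, "ogden_params"), inherits(prony, "prony_series"))
  reference <- match.arg(reference)
  if (density <= 0) stop("`density` must be positive", call. = FALSE)
  if (poisson <= 0 || poisson >= 0.5) stop("`poisson` must lie in (0, 0.5)", call. = FALSE)
  if (reference == "quasi_static" && prony$g_inf <= 0)
    stop("quasi_static reference requires g_inf > 0", call. = FALSE)
  structure(list(ogden = ogden, prony = prony, density = density,
                 poisson = poisson, reference = reference),
            class = "material_card")
}

#' @export
print.material_card <- function(x, ...) {
  cat(sprintf("<material_card> mu = %.4g kPa, alpha = %.4g, %d Prony terms, reference = %s\n",
              x$ogden$mu, x$ogden$alpha, length(x$prony$g), x$reference))
  invisible(x)
}

#' Infinitesimal shear modulus of a one-term Ogden solid
#'
#' The initial slope of the shear stress-strain curve, \eqn{\mu_0 =
#' \mu\alpha/2}.
#'
#' @param ogden An [ogden_params()] object.
#' @return Infinitesimal shear modulus, kPa.
#' @seealso [mu_from_mu0()] for the inverse map.
#' @export
#' @examples
#' infinitesimal_shear_modulus(ogden_params(0.337, 6.67)) # ~1.124 kPa
infinitesimal_shear_modulus <- function(ogden) {
  stopifnot(inherits(ogden, "ogden_params"))
  ogden$mu * ogden$alpha / 2
}

#' Ogden mu from a target infinitesimal shear modulus
#'
#' Inverts \eqn{\mu_0 = \mu\alpha/2}: returns \eqn{\mu = 2\mu_0/\alpha}.
#'
#' @param mu0 Infinitesimal shear modulus, kPa.
#' @param alpha Non-linearity coefficient (non-zero).
#' @return Shear-modulus coefficient `mu`, kPa.
#' @export
mu_from_mu0 <- function(mu0, alpha) {
  stopifnot(is.numeric(mu0), is.numeric(alpha))
  if (any(alpha == 0)) stop("`alpha` must be non-zero", call. = FALSE)
  2 * mu0 / alpha
}

# principal stretch in simple shear for shear amount gam (odd in gam)
shear_stretch <- function(gam) (gam + sqrt(gam^2 + 4)) / 2

#' Instantaneous (elastic) nominal stress of the Ogden solid
#'
#' Closed-form nominal stress under incompressible homogeneous deformation:
#' uniaxial tension/compression \eqn{T(\lambda) = \mu(\lambda^{\alpha-1} -
#' \lambda^{-\alpha/2-1})} with \eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}},
#' and simple shear \eqn{\tau(\gamma) = \mu(\lambda_1^\alpha -
#' \lambda_1^{-\alpha})/\sqrt{\gamma^2+4}} with \eqn{\lambda_1 = (\gamma +
#' \sqrt{\gamma^2+4})/2}.
#'
#' @param mode One of `"tension"`, `"compression"`, `"simple_shear"`.
#' @param strain Engineering strain (tension/compression; compression strain
#'   is interpreted as a magnitude, `lambda = 1 - |strain|`) or shear amount
#'   gamma (simple shear). Vectorized.
#' @param ogden An [ogden_params()] object.
#' @return Nominal stress, kPa (same length as `strain`).
#' @export
#' @examples
#' instantaneous_stress("tension", 0.5, ogden_params(1, 2)) # Neo-Hookean, 1.0556 kPa
instantaneous_stress <- function(mode = c("tension", "compression", "simple_shear"),
                                 strain, ogden) {
  mode <- match.arg(mode)
  stopifnot(inherits(ogden, "ogden_params"), is.numeric(strain))
  mu <- ogden$mu; alpha <- ogden$alpha
  if (mode == "simple_shear") {
    lam1 <- shear_stretch(strain)
    return(mu * (lam1^alpha - lam1^(-alpha)) / sqrt(strain^2 + 4))
  }
  lam <- if (mode == "tension") 1 + strain else 1 - abs(strain)
  if (any(lam <= 0)) stop("engineering strain <= -1 is outside the model domain", call. = FALSE)
  mu * (lam^(alpha - 1) - lam^(-alpha / 2 - 1))
}

#' Reduced relaxation function
#'
#' Evaluates \eqn{g(t) = g_\infty + \sum_i g_i e^{-t/\tau_i}}; `g(0) = 1` by
#' normalization, and the function decays monotonically to `g_inf`.
#'
#' @param t Time, ms (vectorized, non-negative).
#' @param prony A [prony_series()] object.
#' @return Dimensionless relaxation values in `(0, 1]`.
#' @export
reduced_relaxation <- function(t, prony) {
  stopifnot(inherits(prony, "prony_series"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (length(prony$g) == 0L) return(rep(prony$g_inf, length(t)))
  ex <- exp(-outer(t, 1 / prony$tau))          # length(t) x n terms
  prony$g_inf + as.numeric(ex %*% prony$g)
}

# normalized storage/loss sums of the spectrum at angular frequency omega (rad/ms)
prony_storage_loss <- function(freq_hz, prony) {
  s <- outer(2 * pi * freq_hz * 1e-3, prony$tau)   # omega * tau, dimensionless
  storage <- prony$g_inf + as.numeric((s^2 / (1 + s^2)) %*% prony$g)
  loss <- as.numeric((s / (1 + s^2)) %*% prony$g)
  list(storage = storage, loss = loss)
}

#' Complex shear modulus of the Ogden-QLV material
#'
#' Frequency-domain small-strain response. With \eqn{s_i = \omega\tau_i}, the
#' normalized storage modulus is \eqn{g_\infty + \sum g_i s_i^2/(1+s_i^2)} and
#' the loss modulus \eqn{\sum g_i s_i/(1+s_i^2)}; both are scaled by the
#' infinitesimal shear modulus \eqn{\mu_0} (instantaneous reference) or by
#' \eqn{\mu_0/g_\infty} (quasi-static reference, so that the long-term modulus
#' equals \eqn{\mu_0}).
#'
#' @param freq Frequency, Hz (vectorized, positive).
#' @param ogden An [ogden_params()] object.
#' @param prony A [prony_series()] object.
#' @param reference `"quasi_static"` (default) or `"instantaneous"`.
#' @return A tibble with columns `freq_hz`, `storage_kpa`, `loss_kpa`,
#'   `tan_delta`.
#' @export
complex_modulus <- function(freq, ogden, prony,
                            reference = c("quasi_static", "instantaneous")) {
  reference <- match.arg(reference)
  stopifnot(inherits(ogden, "ogden_params"), inherits(prony, "prony_series"))
  if (any(freq <= 0)) stop("`freq` must be positive", call. = FALSE)
  if (reference == "quasi_static" && prony$g_inf <= 0)
    stop("quasi_static reference requires g_inf > 0", call. = FALSE)
  mu0 <- infinitesimal_shear_modulus(ogden)
  scale <- if (reference == "quasi_static") mu0 / prony$g_inf else mu0
  sl <- prony_storage_loss(freq, prony)
  tibble::tibble(freq_hz = freq,
                 storage_kpa = scale * sl$storage,
                 loss_kpa = scale * sl$loss,
                 tan_delta = sl$loss / sl$storage)
}

#' Loss tangent of a relaxation spectrum
#'
#' tan(delta) = loss/storage of the normalized spectrum; a damping measure
#' independent of the absolute stiffness `mu`.
#'
#' @inheritParams complex_modulus
#' @return Dimensionless tan(delta) values (same length as `freq`).
#' @export
tan_delta <- function(freq, prony) {
  stopifnot(inherits(prony, "prony_series"))
  if (any(freq <= 0)) stop("`freq` must be positive", call. = FALSE)
  sl <- prony_storage_loss(freq, prony)
  sl$loss / sl$storage
}

#' Fit a Prony series to tan(delta) data
#'
#' Least-squares fit of the normalized coefficients `g` (and implied `g_inf`)
#' to measured loss-tangent data, with the time constants fixed on a grid.
#' The simplex constraints (`g >= 0`, `g_inf >= 0`, `g_inf + sum(g) = 1`) are
#' enforced exactly through a softmax reparameterization and the true
#' tan(delta) residual is minimized by quasi-Newton descent.
#'
#' @param data A data frame with columns `freq_hz` and `tan_delta`.
#' @param n_terms Number of Prony terms (default 4).
#' @param tau_grid Fixed time constants, ms. Default is the decade grid
#'   `c(10, 1, 0.1, 0.01)` (its first `n_terms` entries are used when
#'   `n_terms < 4`; longer grids must be supplied explicitly).
#' @return A [prony_series()] minimizing the squared tan(delta) residuals.
#' @export
#' @examples
#' pr <- prony_series(c(0.8619, 0.0383, 0.0412, 0.0249), c(10, 1, 0.1, 0.01))
#' f <- 10^seq(-1, 3, length.out = 30)
#' fit <- fit_prony(data.frame(freq_hz = f, tan_delta = tan_delta(f, pr)))
fit_prony <- function(data, n_terms = 4, tau_grid = c(10, 1, 0.1, 0.01)) {
  stopifnot(is.data.frame(data),
            all(c("freq_hz", "tan_delta") %in% names(data)))
  if (length(tau_grid) < n_terms)
    stop("`tau_grid` must supply at least `n_terms` time constants", call. = FALSE)
  tau <- sort(tau_grid, decreasing = TRUE)[seq_len(n_terms)]
  f <- as.numeric(data$freq_hz); y <- as.numeric(data$tan_delta)
  keep <- is.finite(f) & is.finite(y) & f > 0
  f <- f[keep]; y <- y[keep]
  if (length(f) < n_terms + 1)
    stop("need at least n_terms + 1 finite data points", call. = FALSE)
  if (all(y == 0)) return(prony_series(g = rep(0, n_terms), tau = tau, g_inf = 1))
  s <- outer(2 * pi * f * 1e-3, tau)               # omega * tau
  Sm <- s^2 / (1 + s^2); Lm <- s / (1 + s^2)
  # theta: softmax weights over (g_1..g_n, g_inf)
  obj <- function(theta) {
    w <- exp(theta - max(theta)); w <- w / sum(w)
    g <- w[seq_len(n_terms)]; ginf <- w[n_terms + 1]
    storage <- ginf + as.numeric(Sm %*% g)
    loss <- as.numeric(Lm %*% g)
    sum((loss / storage - y)^2)
  }
  starts <- list(rep(0, n_terms + 1),
                 c(rep(1, n_terms), -2),
                 c(2, rep(-1, n_terms - 1), -1))
  ctl <- list(iter.max = 5000, eval.max = 10000, rel.tol = 1e-14, abs.tol = 1e-20)
  fits <- lapply(starts, function(th0) {
    r <- stats::nlminb(th0, obj, control = ctl)
    # polish through a simplex pass to escape any flat softmax directions
    r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-15))
    stats::nlminb(r$par, obj, control = ctl)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  w <- exp(best$par - max(best$par)); w <- w / sum(w)
  g <- w[seq_len(n_terms)]; g[g < 1e-12] <- 0
  prony_series(g = g, tau = tau, g_inf = 1 - sum(g))
}

# effective relaxation coefficients under the card's reference convention:
# quasi_static rescales g(t) by 1/g_inf so the long-term factor is 1
effective_relaxation <- function(card) {
  pr <- card$prony
  if (card$reference == "quasi_static")
    list(g = pr$g / pr$g_inf, tau = pr$tau, g_inf = 1)
  else
    list(g = pr$g, tau = pr$tau, g_inf = pr$g_inf)
}

#' QLV stress history under a prescribed strain history
#'
#' Evaluates the quasi-linear viscoelastic hereditary integral
#' \eqn{\sigma(t) = \int_0^t \hat g(t-s)\, \mathrm{d}T^e/\mathrm{d}s\, ds}
#' using the unconditionally stable recursive exponential (internal-variable)
#' update with piecewise-linear elastic stress within each step. Under the
#' quasi-static reference the relaxation function is rescaled so that
#' \eqn{\hat g(\infty) = 1}; under the instantaneous reference
#' \eqn{\hat g(0) = 1}.
#'
#' @param strain Strain history sampled on a uniform grid, starting at 0.
#' @param mode Deformation mode, as in [instantaneous_stress()].
#' @param card A [material_card()].
#' @param dt Time step, ms (uniform, positive).
#' @return A tibble with columns `time_ms`, `strain`, `stress_kpa`.
#' @export
qlv_stress_history <- function(strain, mode = c("tension", "compression", "simple_shear"),
                               card, dt) {
  mode <- match.arg(mode)
  stopifnot(inherits(card, "material_card"), is.numeric(strain), length(strain) >= 1)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive time step (ms)", call. = FALSE)
  if (abs(strain[1]) > 1e-12) stop("strain history must start at 0", call. = FALSE)
  Te <- instantaneous_stress(mode, strain, card$ogden)
  gh <- effective_relaxation(card)
  n <- length(strain); K <- length(gh$g)
  sig <- numeric(n)
  sig[1] <- gh$g_inf * Te[1]
  if (K == 0L) {
    sig <- gh$g_inf * Te
  } else {
    e <- exp(-dt / gh$tau)
    a <- gh$g * (gh$tau / dt) * (1 - e)   # linear-ramp-in-step update weight
    h <- numeric(K)
    for (i in 2:n) {
      dT <- Te[i] - Te[i - 1]
      h <- e * h + a * dT
      sig[i] <- gh$g_inf * Te[i] + sum(h)
    }
  }
  tibble::tibble(time_ms = (seq_len(n) - 1) * dt, strain = strain, stress_kpa = sig)
}

#' Single-element constant-rate loading curves
#'
#' Virtual single-element experiment: constant engineering-strain-rate loading
#' to `max_strain` in the requested mode, evaluated through the QLV hereditary
#' integral.
#'
#' @param card A [material_card()].
#' @param mode Deformation mode, as in [instantaneous_stress()].
#' @param rate Engineering strain rate, 1/s (protocol rates are 0.5, 5, 30).
#' @param max_strain Final engineering strain (default 0.5).
#' @param n_points Number of output strain samples (at least 100).
#' @return A tibble with columns `strain`, `stress_kpa`, `time_ms`, `mode`,
#'   `rate_per_s`.
#' @export
single_element_curves <- function(card, mode = c("tension", "compression", "simple_shear"),
                                  rate, max_strain = 0.5, n_points = 120) {
  mode <- match.arg(mode)
  stopifnot(inherits(card, "material_card"))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive strain rate (1/s)", call. = FALSE)
  n_points <- max(100L, as.integer(n_points))
  duration_ms <- max_strain / (rate * 1e-3)
  # the recursive update is exact for piecewise-linear elastic stress, so the
  # step only needs to resolve the curvature of T^e along the ramp
  n <- max(1600L, 4L * (n_points - 1L)) + 1L
  dt <- duration_ms / (n - 1L)
  eps <- seq(0, max_strain, length.out = n)
  hist <- qlv_stress_history(eps, mode, card, dt)
  idx <- unique(round(seq(1, n, length.out = n_points)))
  dplyr::mutate(hist[idx, ], mode = mode, rate_per_s = rate)
}

#' Export a material card to JSON
#'
#' @param card A [material_card()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_material_card <- function(card, path) {
  stopifnot(inherits(card, "material_card"))
  jsonlite::write_json(
    list(mu_kpa = card$ogden$mu, alpha = card$ogden$alpha,
         g = card$prony$g, tau_ms = card$prony$tau, g_inf = card$prony$g_inf,
         density_kg_mm3 = card$density, poisson = card$poisson,
         reference = card$reference),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a material card from JSON
#'
#' @param path JSON file written by [write_material_card()].
#' @return A [material_card()].
#' @export
read_material_card <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  material_card(ogden_params(x$mu_kpa, x$alpha),
                prony_series(x$g, x$tau_ms, x$g_inf),
                density = x$density_kg_mm3, poisson = x$poisson,
                reference = x$reference)
}
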