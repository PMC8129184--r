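# shared fixtures: everything is generated in code, sized for fast unit tests

# the published 10-bin relative-stiffness ladder used for card arithmetic
reference_gamma_centers <- function() {
  c(0.53, 0.64, 0.75, 0.86, 0.97, 1.08, 1.20, 1.31, 1.42, 1.53)
}

# a smooth, decaying displacement-like test signal
wave_signal <- function(n = 241, dt = 0.5, freq = 0.02, amp = 3, phase = 0) {
  t <- (seq_len(n) - 1) * dt
  data.frame(time_ms = t, y = amp * sin(2 * pi * freq * t + phase) * exp(-t / 80))
}

# three-axis receiver reference with distinct per-axis content
xyz_signal <- function(n = 241, dt = 0.5, amp = c(3, 2, 1)) {
  t <- (seq_len(n) - 1) * dt
  data.frame(time_ms = t,
             x_mm = amp[1] * sin(2 * pi * 0.02 * t) * exp(-t / 90),
             y_mm = amp[2] * sin(2 * pi * 0.03 * t + 0.4) * exp(-t / 70),
             z_mm = amp[3] * sin(2 * pi * 0.015 * t + 1.1) * exp(-t / 110))
}

# small phantom for unit tests (fast; acceptance tests use the defaults)
tiny_phantom <- function(seed = 42, n_nodes = 40, n_receivers = 6, ...) {
  phantom_config(subject_id = "tiny", n_nodes = n_nodes,
                 n_receivers = n_receivers, seed = seed, ...)
}

tiny_cards <- function(phantom, mu0 = 1.125, alpha = 6.67) {
  build_material_cards(phantom$labels$centers, mu0, alpha, brain_prony())
}

tiny_bundle <- function(seed = 33, noise = NULL, cases = c("z-20-60", "x-40-30"),
                        n_subjects = 2) {
  make_dataset(cases = cases, seed = seed, n_subjects = n_subjects,
               n_nodes = 40, n_receivers = 6, duration_ms = 120,
               noise_frac_peak = noise)
}

tiny_config <- function() calibration_config(duration_ms = 120)

# displacement field u(x) = A x on a masked ball, plus constant offset
linear_displacement_field <- function(A, n = 13, spacing = 2, offset = c(0, 0, 0)) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  u <- grid %*% t(A) + matrix(offset, nrow(grid), 3, byrow = TRUE)
  mask <- array(sqrt(rowSums(grid^2)) <= max(ax) - spacing, rep(n, 3))
  arr <- array(NA_real_, c(n, n, n, 3))
  for (d in 1:3) {
    comp <- array(u[, d], rep(n, 3))
    comp[!mask] <- NA_real_
    arr[, , , d] <- comp
  }
  displacement_field(arr, spacing = rep(spacing, 3), mask = mask)
}

rotation_matrix_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
}

# hand-built normalized-stiffness container for binning unit tests
make_norm <- function(values, retained = !is.na(values),
                      lo = array(FALSE, dim(values)),
                      hi = array(FALSE, dim(values))) {
  structure(list(normalized = values, median_kpa = 1, excluded_low = lo,
                 excluded_high = hi, retained = retained & !lo & !hi,
                 truncation = c(15, 98)),
            class = "normalized_stiffness")
}

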