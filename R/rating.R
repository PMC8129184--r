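#' CORA rating parameters
#'
#' Configuration of the curve-rating method. The overall score is
#' `w_corr * (w_shape * R_shape + w_size * R_size + w_phase * R_phase) +
#' w_corridor * R_corridor`, with sub-rating weights normalized so any valid
#' configuration yields scores in `[0, 1]`.
#'
#' @param w_corr,w_corridor Top-level weights of the correlation and corridor
#'   groups (must sum to 1).
#' @param w_shape,w_size,w_phase Within-correlation weights (must sum to 1).
#' @param delta_max Maximum cross-correlation shift as a fraction of the
#'   evaluation interval (default 0.12).
#' @param a0,b0 Inner and outer corridor half-widths as fractions of the peak
#'   absolute reference value (defaults 0.05 and 0.5).
#' @param window_frac Evaluation window threshold: the window spans the first
#'   to the last sample where `|ref| >= window_frac * max(|ref|)` (default
#'   0.03).
#' @param axis_weighting How composite per-axis weights are computed from the
#'   reference signals: `"peak"` (default, peak absolute displacement) or
#'   `"rms"`.
#' @return A list of class `cora_params`.
#' @export
cora_params <- function(w_corr = 0.5, w_corridor = 0.5,
                        w_shape = 0.5, w_size = 0.25, w_phase = 0.25,
                        delta_max = 0.12, a0 = 0.05, b0 = 0.5,
                        window_frac = 0.03,
                        axis_weighting = c("peak", "rms")) {
  axis_weighting <- match.arg(axis_weighting)
  stopifnot(w_corr >= 0, w_corridor >= 0, abs(w_corr + w_corridor - 1) < 1e-9,
            w_shape >= 0, w_size >= 0, w_phase >= 0,
            abs(w_shape + w_size + w_phase - 1) < 1e-9,
            delta_max > 0, delta_max < 1, a0 >= 0, b0 > a0,
            window_frac >= 0, window_frac < 1)
  structure(list(w_corr = w_corr, w_corridor = w_corridor, w_shape = w_shape,
                 w_size = w_size, w_phase = w_phase, delta_max = delta_max,
                 a0 = a0, b0 = b0, window_frac = window_frac,
                 axis_weighting = axis_weighting),
            class = "cora_params")
}

as_signal <- function(x, what = "signal") {
  if (is.data.frame(x)) {
    cols <- intersect(c("time_ms", "y"), names(x))
    if (length(cols) != 2L)
      stop(what, " must have columns `time_ms` and `y`", call. = FALSE)
    t <- as.numeric(x$time_ms); y <- as.numeric(x$y)
  } else stop(what, " must be a data frame with `time_ms`, `y`", call. = FALSE)
  if (length(t) < 10L) stop(what, " must have at least 10 samples", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop(what, " contains non-finite values", call. = FALSE)
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6 * max(abs(dt[1]), 1e-12)))
    stop(what, " must be uniformly sampled", call. = FALSE)
  list(t = t, y = y, dt = dt[1])
}

#' Resample a reference/test signal pair onto a common uniform grid
#'
#' Linear interpolation of both signals onto a uniform grid covering the
#' overlap of their time ranges.
#'
#' @param ref,test Data frames with columns `time_ms`, `y`.
#' @param dt_target Target sampling interval, ms. Defaults to the finer of the
#'   two input intervals.
#' @return A list with resampled `ref` and `test` tibbles sharing one grid.
#' @export
resample_pair <- function(ref, test, dt_target = NULL) {
  r <- as_signal(ref, "ref"); s <- as_signal(test, "test")
  t0 <- max(min(r$t), min(s$t)); t1 <- min(max(r$t), max(s$t))
  if (t1 <= t0) stop("signals have no overlapping time range", call. = FALSE)
  if (is.null(dt_target)) dt_target <- min(r$dt, s$dt)
  grid <- seq(t0, t1, by = dt_target)
  list(ref = tibble::tibble(time_ms = grid,
                            y = stats::approx(r$t, r$y, grid)$y),
       test = tibble::tibble(time_ms = grid,
                             y = stats::approx(s$t, s$y, grid)$y))
}

#' CORA score for one reference/test signal pair
#'
#' Rates the agreement of a model signal against a reference on `[0, 1]`:
#' a cross-correlation group (shape = clipped maximum normalized
#' cross-correlation over bounded time shifts; size = energy ratio
#' `min(A)/max(A)` with `A = integral of y^2 dt`; phase = 1 minus the
#' normalized optimal shift) plus a corridor group (per-sample score, 1 inside
#' the inner corridor, 0 outside the outer, quadratic in between, averaged
#' over the evaluation window).
#'
#' @param ref,test Data frames with columns `time_ms`, `y` on the same uniform
#'   grid (use [resample_pair()] first if needed).
#' @param params A [cora_params()] configuration.
#' @return A one-row tibble: `r_shape`, `r_size`, `r_phase`, `r_corridor`,
#'   `score`.
#' @export
#' @examples
#' t <- seq(0, 100, by = 0.5)
#' ref <- data.frame(time_ms = t, y = sin(t / 8) * exp(-t / 60))
#' cora_score(ref, ref)$score  # 1
cora_score <- function(ref, test, params = cora_params()) {
  r <- as_signal(ref, "ref"); s <- as_signal(test, "test")
  if (length(r$t) != length(s$t) || any(abs(r$t - s$t) > 1e-6))
    stop("ref and test must share one uniform time grid; see resample_pair()",
         call. = FALSE)
  peak <- max(abs(r$y))
  if (peak == 0) stop("zero-energy reference signal cannot be rated", call. = FALSE)
  # evaluation window
  on <- which(abs(r$y) >= params$window_frac * peak)
  idx <- seq(min(on), max(on))
  y <- r$y[idx]; z <- s$y[idx]; n <- length(idx)
  # corridor rating
  inner <- params$a0 * peak; outer <- params$b0 * peak
  dev <- abs(z - y)
  corr_score <- ifelse(dev <= inner, 1,
                       ifelse(dev >= outer, 0, ((outer - dev) / (outer - inner))^2))
  r_corridor <- mean(corr_score)
  # cross-correlation over bounded shifts, normalized on the overlap;
  # numerators via FFT, overlap energies via prefix sums
  D <- max(1L, floor(params$delta_max * n))
  shifts <- -D:D
  cc_full <- stats::convolve(y, z, conj = TRUE, type = "open")  # lag n - 1 .. -(n - 1)
  num <- cc_full[n - shifts]
  py <- cumsum(y^2); pz <- cumsum(z^2)
  ey <- ifelse(shifts >= 0, py[pmax(n - shifts, 1)], py[n] - c(0, py)[pmax(1 - shifts, 1)])
  ez <- ifelse(shifts >= 0, pz[n] - c(0, pz)[pmax(shifts + 1, 1)], pz[pmax(n + shifts, 1)])
  den <- sqrt(ey * ez)
  rho <- ifelse(den == 0, 0, pmin(pmax(num / den, -1), 1))
  best <- which(rho == max(rho))
  d_star <- shifts[best[which.min(abs(shifts[best]))]]
  r_shape <- max(0, max(rho))
  r_phase <- min(1, max(0, 1 - abs(d_star) / D))
  # size: energy ratio over the window
  a_ref <- sum(y^2) * r$dt; a_test <- sum(z^2) * r$dt
  r_size <- if (max(a_ref, a_test) == 0) 1 else min(a_ref, a_test) / max(a_ref, a_test)
  score <- params$w_corr * (params$w_shape * r_shape + params$w_size * r_size +
                              params$w_phase * r_phase) +
    params$w_corridor * r_corridor
  tibble::tibble(r_shape = r_shape, r_size = r_size, r_phase = r_phase,
                 r_corridor = r_corridor, score = score)
}

axis_cols <- c(x = "x_mm", y = "y_mm", z = "z_mm")

check_xyz <- function(df, what) {
  if (!is.data.frame(df) || !all(c("time_ms", axis_cols) %in% names(df)))
    stop(what, " must have columns time_ms, x_mm, y_mm, z_mm", call. = FALSE)
  df
}

#' A paired three-axis receiver record
#'
#' Bundles the reference (experimental) and test (model) displacement
#' histories of one receiver. The receiver weight beta is recomputed as the
#' maximum resultant reference displacement.
#'
#' @param id Receiver identifier.
#' @param ref,test Data frames with columns `time_ms`, `x_mm`, `y_mm`, `z_mm`
#'   on a shared uniform grid.
#' @return A list of class `receiver_record` with recomputed `beta` (mm).
#' @export
receiver_record <- function(id, ref, test) {
  check_xyz(ref, "ref"); check_xyz(test, "test")
  if (nrow(ref) != nrow(test) || any(abs(ref$time_ms - test$time_ms) > 1e-6))
    stop("ref and test must share one time grid", call. = FALSE)
  beta <- max(sqrt(ref$x_mm^2 + ref$y_mm^2 + ref$z_mm^2))
  structure(list(id = id, ref = tibble::as_tibble(ref),
                 test = tibble::as_tibble(test), beta = beta),
            class = "receiver_record")
}

#' Composite (magnitude-weighted) CORA score of a three-axis record
#'
#' Rates each axis with [cora_score()] and combines them with weights
#' proportional to the reference-signal magnitude of each axis (peak absolute
#' displacement by default). Axes whose reference is identically zero get
#' weight zero and are skipped.
#'
#' @param record A [receiver_record()].
#' @param params A [cora_params()].
#' @return A one-row tibble with the per-axis scores `score_x`, `score_y`,
#'   `score_z`, weights `weight_x/y/z`, the composite `ccora`, and `beta`.
#' @export
composite_cora <- function(record, params = cora_params()) {
  stopifnot(inherits(record, "receiver_record"))
  mags <- vapply(axis_cols, function(cl) {
    y <- record$ref[[cl]]
    if (params$axis_weighting == "peak") max(abs(y)) else sqrt(mean(y^2))
  }, numeric(1))
  if (all(mags == 0)) stop("all-zero reference record cannot be rated", call. = FALSE)
  scores <- vapply(axis_cols, function(cl) {
    if (max(abs(record$ref[[cl]])) == 0) return(NA_real_)
    cora_score(data.frame(time_ms = record$ref$time_ms, y = record$ref[[cl]]),
               data.frame(time_ms = record$test$time_ms, y = record$test[[cl]]),
               params)$score
  }, numeric(1))
  mags <- unname(mags); scores <- unname(scores)
  w <- mags / sum(mags)
  cc <- sum(w[mags > 0] * scores[mags > 0])
  tibble::tibble(score_x = scores[1], score_y = scores[2], score_z = scores[3],
                 weight_x = w[1], weight_y = w[2], weight_z = w[3],
                 ccora = cc, beta = record$beta)
}

#' Receiver-weighted overall rating (wcCORA)
#'
#' Weighted average of per-receiver composite scores, weighted by each
#' receiver's maximum resultant reference displacement:
#' `wcCORA = sum(alpha_i * cCORA_i)` with `alpha_i = beta_i / sum(beta)`.
#'
#' @param ratings Either a list of [receiver_record()] objects (rated here
#'   with `params`) or a data frame with columns `ccora` and `beta`.
#' @param params A [cora_params()], used when `ratings` are records.
#' @return A list of class `case_rating`: `wccora`, `weights`, and the
#'   per-receiver `ratings` tibble.
#' @export
weighted_overall <- function(ratings, params = cora_params()) {
  if (is.data.frame(ratings)) {
    stopifnot(all(c("ccora", "beta") %in% names(ratings)))
    tab <- tibble::as_tibble(ratings)
  } else {
    stopifnot(is.list(ratings), length(ratings) >= 1)
    tab <- dplyr::bind_rows(lapply(ratings, function(rec) {
      out <- composite_cora(rec, params)
      dplyr::mutate(out, receiver = rec$id, .before = 1)
    }))
  }
  if (nrow(tab) < 1L) stop("need at least one receiver", call. = FALSE)
  if (sum(tab$beta) <= 0) stop("all receiver weights (beta) are zero", call. = FALSE)
  alpha <- tab$beta / sum(tab$beta)
  structure(list(wccora = sum(alpha * tab$ccora),
                 weights = alpha, ratings = tab),
            class = "case_rating")
}

#' @export
print.case_rating <- function(x, ...) {
  cat(sprintf("<case_rating> wcCORA = %.4f over %d receivers\n",
              x$wccora, nrow(x$ratings)))
  invisible(x)
}

#' Joint multi-subject calibration objective
#'
#' Arithmetic mean of per-subject wcCORA scores; the quantity maximized by
#' the inverse calibration.
#'
#' @param wccora_by_subject Numeric vector of per-subject wcCORA values.
#' @return Mean score.
#' @export
joint_objective <- function(wccora_by_subject) {
  x <- as.numeric(wccora_by_subject)
  if (length(x) == 0L) stop("need at least one subject score", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite subject score", call. = FALSE)
  mean(x)
}
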