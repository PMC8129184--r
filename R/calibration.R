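#' Calibration configuration
#'
#' Grids, termination tolerances and simulation settings for the two-stage
#' inverse calibration. The defaults are the literature-informed first
#' iteration grids and termination criteria: stage 1 scans the median shear
#' modulus over `c(0.25, 0.7, 1.15, 1.6, 2.05, 2.6)` kPa and terminates when
#' the bracket is narrower than 0.1 kPa; stage 2 scans the non-linearity
#' coefficient over `c(2, 6, 10)` with tolerance 0.2.
#'
#' @param stage1_grid,stage1_tol Stage-1 (mu0_med, kPa) grid and tolerance.
#' @param stage2_grid,stage2_tol Stage-2 (alpha) grid and tolerance.
#' @param duration_ms Simulated record length, ms (default 200).
#' @param dt_ms Integrator time step, ms.
#' @param out_dt_ms Output sampling interval of receiver histories, ms.
#' @param stage1_case,stage2_case Case ids of the calibration cases: a
#'   low-severity axial rotation (`"z-20-60"`: axial, 20 rad/s, 60 ms) for the
#'   modulus and a higher-severity coronal rotation (`"x-40-30"`) for the
#'   non-linearity.
#' @param seed Base seed recorded with reports.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(stage1_grid = c(0.25, 0.7, 1.15, 1.6, 2.05, 2.6),
                               stage1_tol = 0.1,
                               stage2_grid = c(2, 6, 10),
                               stage2_tol = 0.2,
                               duration_ms = 200, dt_ms = 0.05, out_dt_ms = 0.1,
                               stage1_case = "z-20-60", stage2_case = "x-40-30",
                               seed = 1L) {
  stopifnot(length(stage1_grid) >= 3, !is.unsorted(stage1_grid, strictly = TRUE),
            length(stage2_grid) >= 3, !is.unsorted(stage2_grid, strictly = TRUE),
            stage1_tol > 0, stage2_tol > 0, duration_ms > 0, dt_ms > 0,
            out_dt_ms >= dt_ms)
  structure(list(stage1_grid = stage1_grid, stage1_tol = stage1_tol,
                 stage2_grid = stage2_grid, stage2_tol = stage2_tol,
                 duration_ms = duration_ms, dt_ms = dt_ms, out_dt_ms = out_dt_ms,
                 stage1_case = stage1_case, stage2_case = stage2_case,
                 seed = as.integer(seed)),
            class = "calibration_config")
}

# memoising evaluation ledger shared by bracketing and golden iterations;
# keys are parameter values rounded to 1e-9
new_eval_ledger <- function(objective) {
  env <- new.env(parent = emptyenv())
  env$tab <- tibble::tibble(param = numeric(), value = numeric(), reused = logical())
  env$f <- function(x) {
    key <- sprintf("%.9f", round(x, 9))
    hit <- which(sprintf("%.9f", round(env$tab$param, 9)) == key)
    if (length(hit)) {
      env$tab <- dplyr::bind_rows(env$tab,
        tibble::tibble(param = x, value = env$tab$value[hit[1]], reused = TRUE))
      return(env$tab$value[hit[1]])
    }
    val <- objective(x)
    if (!is.finite(val)) stop("non-finite objective value at ", format(x), call. = FALSE)
    env$tab <- dplyr::bind_rows(env$tab,
      tibble::tibble(param = x, value = val, reused = FALSE))
    val
  }
  env
}

#' Bracket the maximum of an objective from a scan grid
#'
#' Evaluates the objective at every grid point and returns the interval
#' formed by the two neighbors of the grid argmax. An argmax on the grid
#' boundary means no interior bracket exists and is an error.
#'
#' @param objective Function of one numeric parameter returning a score.
#' @param grid Strictly increasing numeric grid (length >= 3).
#' @param ledger Optional evaluation ledger (internal); one is created if
#'   missing.
#' @return A list with `a`, `b` (the bracket), `argmax`, `value`, and the
#'   grid `evaluations` tibble.
#' @export
#' @examples
#' bracket_from_grid(function(x) -(x - 6.5)^2, c(2, 6, 10))[c("a", "b")]
bracket_from_grid <- function(objective, grid, ledger = NULL) {
  stopifnot(is.numeric(grid), length(grid) >= 3,
            !is.unsorted(grid, strictly = TRUE))
  if (is.null(ledger)) ledger <- new_eval_ledger(objective)
  vals <- vapply(grid, ledger$f, numeric(1))
  k <- which.max(vals)
  if (k == 1L || k == length(grid))
    stop("bracket not found: objective maximum at grid boundary (", grid[k],
         "); extend the scan grid", call. = FALSE)
  list(a = grid[k - 1], b = grid[k + 1], argmax = grid[k], value = vals[k],
       evaluations = tibble::tibble(param = grid, value = vals))
}

GOLDEN_PHI <- (sqrt(5) - 1) / 2

#' Golden-section maximization with evaluation accounting
#'
#' Maximizes a unimodal objective on `[a, b]` by golden-section search with
#' interval-shrink factor `phi = (sqrt(5) - 1)/2`: interior points
#' `x1 = a + (1 - phi)(b - a)` and `x2 = a + phi(b - a)`; if `f(x1) >= f(x2)`
#' the interval becomes `[a, x2]`, otherwise `[x1, b]`. One interior point is
#' reused each iteration, so after the two initial evaluations every
#' iteration costs exactly one new objective evaluation. The search stops
#' once `b - a < tol` and returns the best evaluated parameter.
#'
#' @param objective Function of one numeric parameter.
#' @param a,b Interval bounds, `a < b`.
#' @param tol Termination width (same units as the parameter).
#' @param ledger Optional shared evaluation ledger from [bracket_from_grid()]
#'   so that repeat parameter values are reused, not re-evaluated.
#' @return An object of class `golden_search`: `argmax`, `value`,
#'   `iterations`, `n_evaluations` (unique objective evaluations including any
#'   ledger history), `trace` (per-iteration tibble) and `ledger` (evaluation
#'   tibble with reuse flags).
#' @export
#' @examples
#' gs <- golden_search(function(x) -(x - 5)^2, 2, 10, tol = 1e-4)
#' gs$argmax
golden_search <- function(objective, a, b, tol, ledger = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), a < b, is.numeric(tol), tol > 0)
  if (is.null(ledger)) ledger <- new_eval_ledger(objective)
  phi <- GOLDEN_PHI
  trace <- list()
  x1 <- a + (1 - phi) * (b - a); x2 <- a + phi * (b - a)
  f1 <- ledger$f(x1); f2 <- ledger$f(x2)
  iter <- 0L
  while (b - a >= tol) {
    iter <- iter + 1L
    # the carried-over interior point is already evaluated; the fresh one is
    # only evaluated if another iteration is needed, so n evaluations = n + 1
    if (is.na(f1)) f1 <- ledger$f(x1)
    if (is.na(f2)) f2 <- ledger$f(x2)
    trace[[iter]] <- tibble::tibble(iteration = iter, a = a, b = b,
                                    x1 = x1, x2 = x2, f1 = f1, f2 = f2)
    if (f1 >= f2) {           # ties follow the f(x1) > f(x2) branch
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- a + (1 - phi) * (b - a); f1 <- NA_real_
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- NA_real_
    }
  }
  tab <- ledger$tab
  best <- which.max(tab$value)
  structure(list(argmax = tab$param[best], value = tab$value[best],
                 iterations = iter, n_evaluations = sum(!tab$reused),
                 interval = c(a, b),
                 trace = dplyr::bind_rows(trace), ledger = tab),
            class = "golden_search")
}

#' @export
print.golden_search <- function(x, ...) {
  cat(sprintf("<golden_search> argmax = %.6g (objective %.6g), %d iterations, %d evaluations\n",
              x$argmax, x$value, x$iterations, x$n_evaluations))
  invisible(x)
}

#' @export
tidy.golden_search <- function(x, ...) x$trace

#' @export
glance.golden_search <- function(x, ...) {
  tibble::tibble(argmax = x$argmax, value = x$value, iterations = x$iterations,
                 n_evaluations = x$n_evaluations,
                 final_width = x$interval[2] - x$interval[1])
}

# one search stage = grid bracketing + golden refinement on a shared ledger
search_stage <- function(objective, grid, tol) {
  ledger <- new_eval_ledger(objective)
  br <- bracket_from_grid(objective, grid, ledger)
  gs <- golden_search(objective, br$a, br$b, tol, ledger)
  gs$bracket <- br
  gs
}

# evaluate the joint objective (mean wcCORA over subjects) for a card builder,
# simulating one case per subject and rating against the bundle reference
joint_wccora <- function(bundle, case_id, make_cards, config, params = cora_params()) {
  scores <- vapply(names(bundle$subjects), function(sid) {
    ph <- bundle$subjects[[sid]]
    cards <- make_cards(ph$labels$centers)
    case <- bundle$cases[bundle$cases$case_id == case_id, ]
    pulse <- make_pulse(case$axis, case$peak_rad_s, case$duration_ms)
    pred <- simulate_phantom(ph, pulse, cards, duration_ms = config$duration_ms,
                             dt_ms = config$dt_ms, out_dt_ms = config$out_dt_ms)
    refs <- bundle$records[[sid]][[case_id]]
    recs <- lapply(names(refs), function(rid)
      receiver_record(rid, refs[[rid]],
                      pred[pred$receiver == rid, c("time_ms", "x_mm", "y_mm", "z_mm")]))
    weighted_overall(recs, params)$wccora
  }, numeric(1))
  joint_objective(scores)
}

#' Stage 1: calibrate the median infinitesimal shear modulus
#'
#' Maximizes the joint wcCORA objective over the median quasi-static shear
#' modulus with the material constrained to a Neo-Hookean solid
#' (`alpha = 2`, so `mu_med = mu0_med` and part stiffnesses follow
#' `mu_i = gamma_i * mu_med`), simulating the low-severity axial calibration
#' case for each subject.
#'
#' @param bundle An [make_dataset()] experiment bundle.
#' @param config A [calibration_config()].
#' @param params A [cora_params()].
#' @return A list of class `calibration_stage`: `mu0_med`, `search`
#'   (a `golden_search`), `stage = 1`.
#' @export
calibrate_stage1 <- function(bundle, config = calibration_config(),
                             params = cora_params()) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  if (!config$stage1_case %in% bundle$cases$case_id)
    stop("bundle lacks the stage-1 calibration case ", config$stage1_case, call. = FALSE)
  prony <- bundle$prony
  objective <- function(mu0) joint_wccora(
    bundle, config$stage1_case,
    function(centers) build_material_cards(centers, mu0, 2, prony),
    config, params)
  gs <- search_stage(objective, config$stage1_grid, config$stage1_tol)
  structure(list(stage = 1L, mu0_med = gs$argmax, search = gs),
            class = "calibration_stage")
}

#' Stage 2: calibrate the Ogden non-linearity coefficient
#'
#' Maximizes the joint wcCORA objective over `alpha` while preserving the
#' stage-1 infinitesimal shear modulus: every evaluation rebuilds the card
#' set through `mu_i = 2 * gamma_i * mu0_med / alpha`, simulating the
#' higher-severity coronal calibration case.
#'
#' @param bundle An [make_dataset()] experiment bundle.
#' @param mu0_med Calibrated median infinitesimal shear modulus, kPa.
#' @param config A [calibration_config()].
#' @param params A [cora_params()].
#' @return A list of class `calibration_stage`: `alpha`, `mu0_med`, `search`.
#' @export
calibrate_stage2 <- function(bundle, mu0_med, config = calibration_config(),
                             params = cora_params()) {
  stopifnot(inherits(bundle, "experiment_bundle"), mu0_med > 0)
  if (!config$stage2_case %in% bundle$cases$case_id)
    stop("bundle lacks the stage-2 calibration case ", config$stage2_case, call. = FALSE)
  prony <- bundle$prony
  objective <- function(alpha) joint_wccora(
    bundle, config$stage2_case,
    function(centers) build_material_cards(centers, mu0_med, alpha, prony),
    config, params)
  gs <- search_stage(objective, config$stage2_grid, config$stage2_tol)
  structure(list(stage = 2L, alpha = gs$argmax, mu0_med = mu0_med, search = gs),
            class = "calibration_stage")
}

#' @export
print.calibration_stage <- function(x, ...) {
  what <- if (x$stage == 1L) sprintf("mu0_med = %.4g kPa", x$mu0_med)
          else sprintf("alpha = %.4g (mu0_med fixed at %.4g kPa)", x$alpha, x$mu0_med)
  cat(sprintf("<calibration_stage %d> %s; %d iterations, %d evaluations\n",
              x$stage, what, x$search$iterations, x$search$n_evaluations))
  invisible(x)
}

# rate every bundle case against simulations at the given parameters
verification_ratings <- function(bundle, mu0_med, alpha, config,
                                 params = cora_params(), cases = NULL) {
  cases <- cases %||% bundle$cases$case_id
  grid <- tidyr::expand_grid(subject = names(bundle$subjects), case_id = cases)
  grid$wccora <- purrr::map2_dbl(grid$subject, grid$case_id, function(sid, cid) {
    joint_wccora_single(bundle, sid, cid, mu0_med, alpha, config, params)
  })
  grid
}

joint_wccora_single <- function(bundle, sid, cid, mu0_med, alpha, config, params) {
  ph <- bundle$subjects[[sid]]
  cards <- build_material_cards(ph$labels$centers, mu0_med, alpha, bundle$prony)
  case <- bundle$cases[bundle$cases$case_id == cid, ]
  pulse <- make_pulse(case$axis, case$peak_rad_s, case$duration_ms)
  pred <- simulate_phantom(ph, pulse, cards, duration_ms = config$duration_ms,
                           dt_ms = config$dt_ms, out_dt_ms = config$out_dt_ms)
  refs <- bundle$records[[sid]][[cid]]
  recs <- lapply(names(refs), function(rid)
    receiver_record(rid, refs[[rid]],
                    pred[pred$receiver == rid, c("time_ms", "x_mm", "y_mm", "z_mm")]))
  weighted_overall(recs, params)$wccora
}

#' Run the full two-stage calibration with verification
#'
#' Executes the staged procedure: (1) calibrate the median shear modulus on
#' the low-severity axial case, (2) verify it on the held-out low-severity
#' cases, (3) calibrate the non-linearity coefficient on the higher-severity
#' coronal case, (4) rate the calibrated material on the full case matrix.
#'
#' @param bundle An [make_dataset()] experiment bundle.
#' @param config A [calibration_config()].
#' @param params A [cora_params()].
#' @return An object of class `calibration_report`: calibrated parameters,
#'   stage objects, stage-1 verification and full verification tibbles, and a
#'   summary (mean, sd, range of verification wcCORA).
#' @export
run_calibration <- function(bundle, config = calibration_config(),
                            params = cora_params()) {
  s1 <- calibrate_stage1(bundle, config, params)
  low_cases <- bundle$cases$case_id[bundle$cases$peak_rad_s ==
    bundle$cases$peak_rad_s[bundle$cases$case_id == config$stage1_case]]
  low_held_out <- setdiff(low_cases, config$stage1_case)
  v1 <- if (length(low_held_out))
    verification_ratings(bundle, s1$mu0_med, 2, config, params, low_held_out)
  else NULL
  s2 <- calibrate_stage2(bundle, s1$mu0_med, config, params)
  v2 <- verification_ratings(bundle, s1$mu0_med, s2$alpha, config, params)
  structure(list(mu0_med = s1$mu0_med, alpha = s2$alpha,
                 stage1 = s1, stage2 = s2,
                 stage1_verification = v1, verification = v2,
                 summary = tibble::tibble(
                   mean_wccora = mean(v2$wccora), sd_wccora = stats::sd(v2$wccora),
                   min_wccora = min(v2$wccora), max_wccora = max(v2$wccora),
                   n_cases = nrow(v2)),
                 config = config,
                 provenance = bundle$provenance),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> mu0_med = %.4g kPa, alpha = %.4g\n",
              x$mu0_med, x$alpha))
  cat(sprintf("  verification wcCORA: %.3f +/- %.3f (range %.3f-%.3f, n = %d)\n",
              x$summary$mean_wccora, x$summary$sd_wccora,
              x$summary$min_wccora, x$summary$max_wccora, x$summary$n_cases))
  invisible(x)
}

#' @export
tidy.calibration_report <- function(x, ...) x$verification

#' @export
glance.calibration_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mu0_med = x$mu0_med, alpha = x$alpha,
                                  stage1_iterations = x$stage1$search$iterations,
                                  stage1_evaluations = x$stage1$search$n_evaluations,
                                  stage2_iterations = x$stage2$search$iterations,
                                  stage2_evaluations = x$stage2$search$n_evaluations),
                   x$summary)
}

#' Write a calibration report to JSON
#'
#' @param report A `calibration_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(report, path) {
  stopifnot(inherits(report, "calibration_report"))
  jsonlite::write_json(
    list(mu0_med_kpa = report$mu0_med, alpha = report$alpha,
         stage1 = list(trace = report$stage1$search$trace,
                       ledger = report$stage1$search$ledger,
                       iterations = report$stage1$search$iterations,
                       evaluations = report$stage1$search$n_evaluations),
         stage2 = list(trace = report$stage2$search$trace,
                       ledger = report$stage2$search$ledger,
                       iterations = report$stage2$search$iterations,
                       evaluations = report$stage2$search$n_evaluations),
         stage1_verification = report$stage1_verification,
         verification = report$verification,
         summary = report$summary,
         provenance = report$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
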