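#' MRE stiffness volume
#'
#' A 3D voxel array of shear stiffness (kPa) with voxel spacing and an
#' optional voxel-to-world affine. Voxels outside the brain are `NA`.
#'
#' @param values 3D numeric array, kPa; `NA` marks absent (non-brain) voxels.
#' @param spacing Voxel spacing per axis, mm (length 3, positive).
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return An object of class `stiffness_volume`.
#' @export
stiffness_volume <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  present <- !is.na(values)
  if (any(values[present] < 0)) stop("stiffness values must be >= 0", call. = FALSE)
  if (!is.null(affine)) stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(values = values, spacing = spacing, affine = affine),
            class = "stiffness_volume")
}

#' @export
print.stiffness_volume <- function(x, ...) {
  p <- !is.na(x$values)
  cat(sprintf("<stiffness_volume> %s voxels (%d present), spacing %s mm, median %.3g kPa\n",
              paste(dim(x$values), collapse = "x"), sum(p),
              paste(signif(x$spacing, 3), collapse = "x"),
              stats::median(x$values[p])))
  invisible(x)
}

#' Truncate and median-normalize a stiffness volume
#'
#' Removes voxels below the `low_pct` percentile (approximate CSF
#' contamination) and above the `high_pct` percentile (edge/inversion
#' artifacts) of the present-voxel stiffness distribution, computes the median
#' over the retained values, and divides every present voxel by that median.
#' Excluded voxels are reported as masks so they can be assigned to the
#' extreme relative-stiffness bins downstream.
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7); the retained set is the half-open interval
#' `(q_low, q_high]`.
#'
#' @param vol A [stiffness_volume()] (or a bare 3D array with `NA` outside the
#'   brain).
#' @param low_pct,high_pct Truncation percentiles, defaults 15 and 98.
#' @return A list of class `normalized_stiffness` with elements `normalized`
#'   (3D array of stiffness / median over all present voxels), `median_kpa`,
#'   `excluded_low`, `excluded_high` (logical arrays), `retained` (logical
#'   array), and `truncation = c(low_pct, high_pct)`.
#' @export
truncate_and_normalize <- function(vol, low_pct = 15, high_pct = 98) {
  if (inherits(vol, "stiffness_volume")) values <- vol$values
  else { stopifnot(is.array(vol), length(dim(vol)) == 3L); values <- vol }
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)
  present <- !is.na(values)
  if (sum(present) < 100L) stop("need at least 100 present voxels", call. = FALSE)
  v <- values[present]
  if (max(v) == min(v)) stop("degenerate (constant) stiffness volume", call. = FALSE)
  q <- stats::quantile(v, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  excluded_low <- present & values <= q[1]
  excluded_high <- present & values > q[2]
  retained <- present & !excluded_low & !excluded_high
  if (!any(retained)) stop("truncation retained no voxels", call. = FALSE)
  med <- stats::median(values[retained])
  structure(list(normalized = values / med, median_kpa = med,
                 excluded_low = excluded_low, excluded_high = excluded_high,
                 retained = retained, truncation = c(low_pct, high_pct)),
            class = "normalized_stiffness")
}

#' Bin normalized stiffness into relative-stiffness labels
#'
#' Splits the retained normalized-stiffness range into `n_bins` equal-width
#' bins; bin centers are the bin midpoints (the relative stiffnesses
#' \eqn{\gamma_i}). Voxels excluded by the low/high truncation are assigned to
#' bin 1 and bin `n_bins` respectively. Values exactly on an interior bin edge
#' go to the upper bin; the retained maximum goes to bin `n_bins`.
#'
#' @param norm A `normalized_stiffness` object from [truncate_and_normalize()].
#' @param n_bins Number of bins (default 10).
#' @return An object of class `relative_stiffness_labels` with fields `labels`
#'   (3D integer array, `NA` outside the brain), `centers` (gamma values,
#'   length `n_bins`), `truncation`, and `median_kpa`.
#' @export
bin_relative_stiffness <- function(norm, n_bins = 10) {
  stopifnot(inherits(norm, "normalized_stiffness"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be at least 2", call. = FALSE)
  v <- norm$normalized
  r <- range(v[norm$retained])
  width <- diff(r) / n_bins
  if (width <= 0) stop("retained values are constant; cannot bin", call. = FALSE)
  centers <- r[1] + width * (seq_len(n_bins) - 0.5)
  labels <- array(NA_integer_, dim(v))
  idx <- norm$retained
  labels[idx] <- pmin(n_bins, as.integer(floor((v[idx] - r[1]) / width)) + 1L)
  labels[norm$excluded_low] <- 1L
  labels[norm$excluded_high] <- n_bins
  relative_stiffness_labels(labels, centers, norm$truncation, norm$median_kpa)
}

#' Relative-stiffness label volume
#'
#' Constructor for a binned relative-stiffness labelling; usually produced by
#' [bin_relative_stiffness()], but can be built directly from a known set of
#' gamma centers (e.g. a published table) when only the material-card
#' arithmetic is needed.
#'
#' @param labels 3D integer array of bin indices in `1..length(centers)`
#'   (`NA` outside the brain), or `NULL` for a centers-only labelling.
#' @param centers Strictly increasing relative stiffness values (gamma).
#' @param truncation Percentile pair used for truncation.
#' @param median_kpa Median stiffness of the retained distribution, kPa.
#' @return An object of class `relative_stiffness_labels`.
#' @export
relative_stiffness_labels <- function(labels, centers, truncation = c(15, 98),
                                      median_kpa = NA_real_) {
  centers <- as.numeric(centers)
  if (length(centers) < 1L || is.unsorted(centers, strictly = TRUE))
    stop("`centers` must be strictly increasing", call. = FALSE)
  if (!is.null(labels)) {
    stopifnot(is.array(labels), length(dim(labels)) == 3L)
    lab <- labels[!is.na(labels)]
    if (length(lab) && (min(lab) < 1L || max(lab) > length(centers)))
      stop("labels out of range of `centers`", call. = FALSE)
  }
  structure(list(labels = labels, centers = centers,
                 truncation = as.numeric(truncation),
                 median_kpa = as.numeric(median_kpa)),
            class = "relative_stiffness_labels")
}

#' @export
print.relative_stiffness_labels <- function(x, ...) {
  cat(sprintf("<relative_stiffness_labels> %d bins, gamma in [%.3g, %.3g], median %.3g kPa\n",
              length(x$centers), min(x$centers), max(x$centers), x$median_kpa))
  invisible(x)
}

#' Build the heterogeneous material-card set
#'
#' Derives one Ogden-QLV card per relative-stiffness bin from the median
#' infinitesimal quasi-static shear modulus and the (shared) non-linearity
#' coefficient, using the mu0-preserving rule \eqn{\mu_i = 2\gamma_i
#' \mu_{0,med}/\alpha}. With `alpha = 2` this reduces to the linear stage-1
#' relation \eqn{\mu_i = \gamma_i \mu_{med}}. The infinitesimal shear modulus
#' of card *i* is exactly \eqn{\gamma_i \mu_{0,med}}, independent of `alpha`.
#'
#' @param labels A [relative_stiffness_labels()] object, or a bare numeric
#'   vector of gamma centers.
#' @param mu0_med Median infinitesimal quasi-static shear modulus, kPa.
#' @param alpha Ogden non-linearity coefficient (shared by all bins).
#' @param prony Shared [prony_series()].
#' @param ... Passed to [material_card()] (density, poisson, reference).
#' @return An object of class `material_card_set`: list with `cards` (one
#'   [material_card()] per center), `median_card` (the gamma = 1 card),
#'   `centers`, `mu0_med`, `alpha`, `prony`.
#' @export
#' @examples
#' pr <- prony_series(c(0.8619, 0.0383, 0.0412, 0.0249), c(10, 1, 0.1, 0.01))
#' cs <- build_material_cards(seq(0.53, 1.53, length.out = 10), 1.125, 6.67, pr)
#' tidy(cs)
build_material_cards <- function(labels, mu0_med, alpha, prony, ...) {
  centers <- if (inherits(labels, "relative_stiffness_labels")) labels$centers
             else as.numeric(labels)
  if (length(centers) == 0L) stop("empty set of gamma centers", call. = FALSE)
  stopifnot(is.numeric(mu0_med), mu0_med > 0, is.numeric(alpha), alpha != 0,
            inherits(prony, "prony_series"))
  mk <- function(gam) material_card(ogden_params(mu_from_mu0(gam * mu0_med, alpha), alpha),
                                    prony, ...)
  structure(list(cards = lapply(centers, mk), median_card = mk(1),
                 centers = centers, mu0_med = mu0_med, alpha = alpha,
                 prony = prony),
            class = "material_card_set")
}

#' @export
print.material_card_set <- function(x, ...) {
  cat(sprintf("<material_card_set> %d parts, mu0_med = %.4g kPa, alpha = %.4g\n",
              length(x$cards), x$mu0_med, x$alpha))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a material-card set into a per-part parameter table
#'
#' @param x A `material_card_set`.
#' @param ... Unused.
#' @return A tibble with one row per relative-stiffness part: `gamma`,
#'   `mu_kpa`, `alpha`, `mu0_kpa`.
#' @export
tidy.material_card_set <- function(x, ...) {
  tibble::tibble(
    gamma = x$centers,
    mu_kpa = vapply(x$cards, function(cc) cc$ogden$mu, numeric(1)),
    alpha = x$alpha,
    mu0_kpa = vapply(x$cards, function(cc) infinitesimal_shear_modulus(cc$ogden), numeric(1)))
}

#' Export a material-card set to JSON
#'
#' @param cards A `material_card_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_material_card_set <- function(cards, path) {
  stopifnot(inherits(cards, "material_card_set"))
  jsonlite::write_json(
    list(mu0_med_kpa = cards$mu0_med, alpha = cards$alpha,
         gamma = cards$centers,
         mu_kpa = vapply(cards$cards, function(cc) cc$ogden$mu, numeric(1)),
         g = cards$prony$g, tau_ms = cards$prony$tau, g_inf = cards$prony$g_inf,
         density_kg_mm3 = cards$cards[[1]]$density,
         poisson = cards$cards[[1]]$poisson,
         reference = cards$cards[[1]]$reference),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stiffness volume from NIfTI
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param absent How absent (non-brain) voxels are encoded in the file:
#'   `"nan"` (default) or `"zero"`.
#' @return A [stiffness_volume()].
#' @export
read_stiffness_volume <- function(path, absent = c("nan", "zero")) {
  absent <- match.arg(absent)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("malformed NIfTI file: ", conditionMessage(e),
                                           call. = FALSE))
  values <- array(as.numeric(img), dim(img)[1:3])
  if (absent == "zero") values[values == 0] <- NA_real_
  values[is.nan(values)] <- NA_real_
  stiffness_volume(values, spacing = RNifti::pixdim(img)[1:3],
                   affine = unclass(RNifti::xform(img)))
}

#' Write a stiffness volume to NIfTI
#'
#' @param vol A [stiffness_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param absent Encoding for absent voxels: `"nan"` (default) or `"zero"`.
#' @return `path`, invisibly.
#' @export
write_stiffness_volume <- function(vol, path, absent = c("nan", "zero")) {
  stopifnot(inherits(vol, "stiffness_volume"))
  absent <- match.arg(absent)
  values <- vol$values
  values[is.na(values)] <- if (absent == "nan") NaN else 0
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- vol$spacing
  if (!is.null(vol$affine))
    img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a relative-stiffness label volume to NIfTI
#'
#' Labels are stored as integers with 0 outside the brain; the gamma centers,
#' truncation percentiles and median stiffness are written to a JSON sidecar
#' `<path>.json`.
#'
#' @param labels A [relative_stiffness_labels()] with a label array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labels_volume <- function(labels, path) {
  stopifnot(inherits(labels, "relative_stiffness_labels"))
  if (is.null(labels$labels)) stop("labelling has no label array", call. = FALSE)
  arr <- labels$labels
  arr[is.na(arr)] <- 0L
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  jsonlite::write_json(list(centers = labels$centers,
                            truncation = labels$truncation,
                            median_kpa = labels$median_kpa),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a relative-stiffness label volume written by [write_labels_volume()]
#'
#' @param path NIfTI path with its JSON sidecar alongside.
#' @return A [relative_stiffness_labels()].
#' @export
read_labels_volume <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(as.integer(img), dim(img)[1:3])
  arr[arr == 0L] <- NA_integer_
  relative_stiffness_labels(arr, meta$centers, meta$truncation, meta$median_kpa)
}
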