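#' Voxel displacement field
#'
#' A 3D grid of displacement vectors (mm) with a brain mask.
#'
#' @param u 4D numeric array `(nx, ny, nz, 3)` of displacement components, mm.
#' @param spacing Voxel spacing, mm (length 3, positive).
#' @param mask Logical 3D array marking brain voxels; defaults to voxels with
#'   finite displacements.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing = c(1, 1, 1), mask = NULL) {
  stopifnot(is.array(u), length(dim(u)) == 4L, dim(u)[4] == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  if (is.null(mask)) mask <- apply(is.finite(u), 1:3, all)
  stopifnot(is.array(mask), identical(dim(mask), dim(u)[1:3]))
  if (any(!is.finite(u[, , , 1][mask]) | !is.finite(u[, , , 2][mask]) |
            !is.finite(u[, , , 3][mask])))
    stop("non-finite displacements inside the mask", call. = FALSE)
  structure(list(u = u, spacing = spacing, mask = mask),
            class = "displacement_field")
}

#' Strain field
#'
#' Voxelwise maximum principal strain with its mask and the strain
#' definition used.
#'
#' @param values 3D array of strain values (`NA` outside the valid mask).
#' @param mask Logical 3D array of valid voxels.
#' @param definition Strain definition used (provenance).
#' @return An object of class `strain_field`.
#' @export
strain_field <- function(values, mask, definition = "green_lagrange") {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            identical(dim(values), dim(mask)))
  v <- values[mask]
  if (any(!is.finite(v)) || any(v < -0.5))
    stop("strain values must be finite and >= -0.5 within the mask", call. = FALSE)
  structure(list(values = values, mask = mask, definition = definition),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<strain_field> %d voxels (%s), MPS median %.4g, 95th pct %.4g\n",
              length(v), x$definition, stats::median(v),
              stats::quantile(v, 0.95, names = FALSE)))
  invisible(x)
}

# gradient of a 3D scalar array along one axis: central differences in the
# interior of the mask, one-sided at mask edges; NA where no neighbour exists
masked_gradient <- function(a, mask, axis, h) {
  dims <- dim(a)
  shift <- function(arr, by) {
    idx <- lapply(dims, seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), dims[axis])
    array(do.call(`[`, c(list(arr), idx)), dims)
  }
  inbounds <- function(by) {
    along <- seq_len(dims[axis]) + by
    ok <- along >= 1L & along <= dims[axis]
    flag <- array(TRUE, dims)
    if (any(!ok)) {
      idx <- lapply(dims, seq_len)
      idx[[axis]] <- which(!ok)
      flag <- do.call(`[<-`, c(list(flag), idx, list(FALSE)))
    }
    flag
  }
  fwd <- shift(a, 1L); bwd <- shift(a, -1L)
  has_f <- inbounds(1L) & shift(mask, 1L)
  has_b <- inbounds(-1L) & shift(mask, -1L)
  g <- array(NA_real_, dims)
  both <- mask & has_f & has_b
  g[both] <- (fwd[both] - bwd[both]) / (2 * h)
  fonly <- mask & has_f & !has_b
  g[fonly] <- (fwd[fonly] - a[fonly]) / h
  bonly <- mask & !has_f & has_b
  g[bonly] <- (a[bonly] - bwd[bonly]) / h
  g
}

# largest eigenvalue of symmetric 3x3 matrices, vectorized (trigonometric
# closed form); inputs are the six distinct components as vectors
sym3_max_eigen <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- pmax(a11, a22, a33)      # diagonal case (p == 0)
  nz <- p > 1e-300
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    out[nz] <- q[nz] + 2 * p[nz] * cos(acos(r) / 3)
  }
  out
}

#' Maximum principal strain from a displacement field
#'
#' Computes the displacement gradient by central differences (one-sided at
#' mask edges), forms the deformation gradient `F = I + grad(u)` and the
#' Green-Lagrange strain `E = (F'F - I)/2`, and returns the largest
#' eigenvalue of `E` per voxel (or, with `definition = "principal_stretch"`,
#' the largest principal stretch minus 1). Voxels without a full gradient
#' neighbourhood are excluded from the output mask.
#'
#' @param field A [displacement_field()].
#' @param definition `"green_lagrange"` (default) or `"principal_stretch"`.
#' @return A [strain_field()].
#' @export
strain_from_displacement <- function(field,
                                     definition = c("green_lagrange", "principal_stretch")) {
  stopifnot(inherits(field, "displacement_field"))
  definition <- match.arg(definition)
  mask <- field$mask
  if (any(dim(mask) < 3L) || sum(mask) == 0L)
    stop("mask must span at least 3 voxels in every direction", call. = FALSE)
  G <- vector("list", 9)
  for (i in 1:3) for (j in 1:3)
    G[[3 * (i - 1) + j]] <- masked_gradient(field$u[, , , i], mask, j,
                                            field$spacing[j])
  valid <- mask
  for (g in G) valid <- valid & !is.na(g)
  if (!any(valid)) stop("no voxel has a complete gradient neighbourhood", call. = FALSE)
  gv <- lapply(G, function(g) g[valid])
  # F = I + G; C = F'F ; E = (C - I)/2
  Fm <- list(gv[[1]] + 1, gv[[2]], gv[[3]],
             gv[[4]], gv[[5]] + 1, gv[[6]],
             gv[[7]], gv[[8]], gv[[9]] + 1)
  C11 <- Fm[[1]]^2 + Fm[[4]]^2 + Fm[[7]]^2
  C22 <- Fm[[2]]^2 + Fm[[5]]^2 + Fm[[8]]^2
  C33 <- Fm[[3]]^2 + Fm[[6]]^2 + Fm[[9]]^2
  C12 <- Fm[[1]] * Fm[[2]] + Fm[[4]] * Fm[[5]] + Fm[[7]] * Fm[[8]]
  C13 <- Fm[[1]] * Fm[[3]] + Fm[[4]] * Fm[[6]] + Fm[[7]] * Fm[[9]]
  C23 <- Fm[[2]] * Fm[[3]] + Fm[[5]] * Fm[[6]] + Fm[[8]] * Fm[[9]]
  cmax <- sym3_max_eigen(C11, C22, C33, C12, C13, C23)
  mps <- if (definition == "green_lagrange") (cmax - 1) / 2
         else sqrt(pmax(cmax, 0)) - 1
  values <- array(NA_real_, dim(mask))
  values[valid] <- mps
  strain_field(values, valid, definition)
}

#' 95th-percentile maximum principal strain
#'
#' @param strain A [strain_field()] (or bare numeric array).
#' @param mask Optional logical array restricting the summary.
#' @return MPS-95, dimensionless (95th percentile with linear interpolation).
#' @export
mps95 <- function(strain, mask = NULL) {
  v <- strain_values(strain, mask)
  if (length(v) < 20L) stop("need at least 20 voxels for MPS-95", call. = FALSE)
  stats::quantile(v, 0.95, names = FALSE, type = 7)
}

#' Volume fraction exceeding a strain threshold
#'
#' @param strain A [strain_field()] (or bare numeric array).
#' @param threshold Strain threshold (default 0.02, i.e. 2% strain).
#' @param mask Optional logical array restricting the summary.
#' @return Fraction of mask voxels with strain above the threshold.
#' @export
exceedance_fraction <- function(strain, threshold = 0.02, mask = NULL) {
  v <- strain_values(strain, mask)
  if (length(v) == 0L) stop("empty mask", call. = FALSE)
  mean(v > threshold)
}

strain_values <- function(strain, mask = NULL) {
  if (inherits(strain, "strain_field")) {
    m <- strain$mask
    if (!is.null(mask)) {
      stopifnot(identical(dim(mask), dim(m)))
      m <- m & mask
    }
    strain$values[m]
  } else {
    stopifnot(is.array(strain))
    if (is.null(mask)) mask <- !is.na(strain)
    stopifnot(identical(dim(mask), dim(strain)))
    strain[mask]
  }
}

#' Regional strain summary
#'
#' MPS-95 and threshold-exceedance volume fractions per labelled region plus
#' a global row.
#'
#' @param strain A [strain_field()].
#' @param labels Integer 3D array of region labels aligned with the strain
#'   grid (`NA` outside regions); optionally named via `region_names`.
#' @param threshold Exceedance threshold (default 0.02).
#' @param region_names Optional character vector naming the label values.
#' @return A tibble with columns `region`, `n_voxels`, `mps95`,
#'   `exceedance_fraction`.
#' @export
regional_summary <- function(strain, labels, threshold = 0.02,
                             region_names = NULL) {
  stopifnot(inherits(strain, "strain_field"), is.array(labels))
  if (!identical(dim(labels), dim(strain$values)))
    stop("label volume is not aligned with the strain grid", call. = FALSE)
  regs <- sort(unique(labels[!is.na(labels)]))
  rows <- lapply(regs, function(rg) {
    m <- !is.na(labels) & labels == rg & strain$mask
    nm <- if (!is.null(region_names) && rg <= length(region_names))
      region_names[rg] else as.character(rg)
    tibble::tibble(region = nm, n_voxels = sum(m),
                   mps95 = if (sum(m) >= 20) mps95(strain, m) else NA_real_,
                   exceedance_fraction = if (sum(m) > 0)
                     exceedance_fraction(strain, threshold, m) else NA_real_)
  })
  dplyr::bind_rows(
    tibble::tibble(region = "global", n_voxels = sum(strain$mask),
                   mps95 = mps95(strain),
                   exceedance_fraction = exceedance_fraction(strain, threshold)),
    dplyr::bind_rows(rows))
}
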