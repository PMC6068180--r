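#' Boundary specification for the undetermined boundary condition
#'
#' FFT-based convolution is circular, so modeling errors wrap around the
#' volume edges. Rather than apodizing or padding the measurement, the
#' reconstruction is carried out on a volume expanded by per-axis margins;
#' the data fidelity term is evaluated only on the measured region `C` (the
#' slab of reconstruction voxels mapping onto the observed focal stack), and
#' the margin voxels are left free to absorb wrap-around error.
#'
#' @param measured_shape Integer `(nz, ny, nx)` of the observed stack.
#' @param margins 3x2 integer matrix of `(low, high)` margin voxels per axis
#'   (rows: z, y, x), or a length-3 vector used for both sides.
#' @return An object of class `boundary_spec` with `recon_shape`,
#'   `measured_shape`, `margins`, and `index` ranges of `C` per axis.
#' @seealso [default_margins()]
#' @export
boundary_spec <- function(measured_shape, margins = 0L) {
  measured_shape <- as.integer(measured_shape)
  stopifnot(length(measured_shape) == 3L, all(measured_shape >= 1L))
  if (is.null(dim(margins))) {
    margins <- as.integer(margins)
    if (length(margins) == 1L) margins <- rep(margins, 3L)
    margins <- cbind(margins, margins)
  }
  margins <- matrix(as.integer(margins), 3L, 2L)
  if (any(margins < 0L)) stop("margins must be >= 0", call. = FALSE)
  recon <- measured_shape + margins[, 1L] + margins[, 2L]
  idx <- lapply(1:3, function(a) margins[a, 1L] + seq_len(measured_shape[a]))
  structure(list(measured_shape = measured_shape, margins = margins,
                 recon_shape = recon, index = idx),
            class = "boundary_spec")
}

#' Default reconstruction margins for a PSF
#'
#' Expands each axis by about half the PSF extent (split between the two
#' sides) so that wrap-around ghosts of the circular convolution fall in the
#' undetermined region, then grows the high-side margins so the expanded
#' dimensions are products of small primes (fast FFT sizes).
#'
#' @param measured_shape Integer `(nz, ny, nx)` of the observed stack.
#' @param psf_shape Integer `(nz, ny, nx)` of the PSF array.
#' @return A [boundary_spec()].
#' @export
default_margins <- function(measured_shape, psf_shape) {
  measured_shape <- as.integer(measured_shape)
  psf_shape <- as.integer(psf_shape)
  half <- pmin(psf_shape %/% 2L, measured_shape)  # total expansion per axis
  lo <- half %/% 2L
  hi <- half - lo
  target <- vapply(measured_shape + lo + hi, function(n) nextn(n, c(2L, 3L, 5L)),
                   integer(1L))
  hi <- hi + (target - (measured_shape + lo + hi))
  boundary_spec(measured_shape, cbind(lo, hi))
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat(sprintf("Boundary spec: measured %s -> reconstruction %s (margins z %d+%d, y %d+%d, x %d+%d)\n",
              paste(x$measured_shape, collapse = "x"),
              paste(x$recon_shape, collapse = "x"),
              x$margins[1L, 1L], x$margins[1L, 2L], x$margins[2L, 1L],
              x$margins[2L, 2L], x$margins[3L, 1L], x$margins[3L, 2L]))
  invisible(x)
}

# Extract the measured region C from a recon-grid array.
crop_region <- function(x, region) {
  x[region$index[[1L]], region$index[[2L]], region$index[[3L]], drop = FALSE]
}

# Logical mask of C on the recon grid.
region_mask <- function(region) {
  m <- array(FALSE, region$recon_shape)
  m[region$index[[1L]], region$index[[2L]], region$index[[3L]]] <- TRUE
  m
}

#' Shifted-Poisson negative log-likelihood
#'
#' The mixed Poisson-Gaussian measurement (in photoelectron units, with
#' normalized read noise `sigma_norm`) is approximated by a Poisson variable
#' shifted by `sigma_norm^2`, which matches its mean and variance. The
#' resulting negative log-likelihood of model intensities `v` given
#' measurements `y_norm`, up to constants, is
#' \deqn{\ell(v) = \sum_j v_j - (y_j + \tilde\sigma^2)\log(v_j + \tilde\sigma^2).}
#' Effective counts `y + sigma_norm^2` below zero (possible at dark voxels
#' because of read noise) are clamped to zero, as the surrogate Poisson count
#' cannot be negative.
#'
#' @param v Model intensities on the measured region (photoelectrons).
#' @param y_norm Measurements on the measured region (photoelectrons).
#' @param sigma_norm Normalized read-noise standard deviation (photoelectrons).
#' @return Scalar NLL; `+Inf` if any `v + sigma_norm^2 <= 0` where the
#'   effective count is positive.
#' @export
nll_shifted_poisson <- function(v, y_norm, sigma_norm = 0) {
  s <- sigma_norm^2
  cnt <- pmax(as.numeric(y_norm) + s, 0)
  vs <- as.numeric(v) + s
  if (any(vs <= 0 & cnt > 0)) return(Inf)
  lg <- ifelse(cnt > 0, log(vs), 0)
  sum(v) - sum(cnt * lg)
}

#' @rdname nll_shifted_poisson
#' @details `nll_poisson` is the `sigma_norm = 0` special case;
#'   `nll_gaussian` is `0.5 * sum((v - y)^2)`.
#' @export
nll_poisson <- function(v, y_norm) nll_shifted_poisson(v, y_norm, 0)

#' @rdname nll_shifted_poisson
#' @export
nll_gaussian <- function(v, y_norm) 0.5 * sum((as.numeric(v) - as.numeric(y_norm))^2)

# Closed-form scalar/vector prox of the shifted-Poisson NLL:
#   argmin_v  v - c log(v+s) + rho/2 (v-u)^2,  c = max(y+s, 0).
# Stationarity gives rho v^2 + (rho(s-u)+1) v + (s - rho s u - c) = 0; the
# minimizer is the larger root (the objective is convex on v > -s with
# derivative -> -Inf at the left edge when c > 0). Computed in a
# cancellation-free form: the larger root directly when b <= 0, else via the
# product of roots.
prox_sp_core <- function(u, y, s, rho) {
  cnt <- pmax(y + s, 0)
  b <- rho * (s - u) + 1
  cc <- s - rho * s * u - cnt
  disc <- b * b - 4 * rho * cc
  sq <- sqrt(pmax(disc, 0))
  pos <- b <= 0
  out <- numeric(length(u))
  out[pos] <- (-b[pos] + sq[pos]) / (2 * rho)
  np <- !pos
  denom <- b[np] + sq[np]
  out[np] <- ifelse(denom > 0, -2 * cc[np] / denom, 0)
  # c = 0 voxels: boundary solution max(u - 1/rho, -s) (no log term)
  zero <- cnt == 0
  if (any(zero)) out[zero] <- pmax(u[zero] - 1 / rho, -s)
  out
}

#' Proximal operator of the shifted-Poisson data fidelity
#'
#' Returns the unique minimizer of
#' `nll_shifted_poisson(v) + (rho/2) * (v - u)^2`, elementwise, in closed
#' form (the positive root of a voxelwise quadratic, evaluated in a
#' numerically stable way). When a [boundary_spec()] is supplied, `u` is a
#' reconstruction-grid array, the fidelity acts only on the measured region
#' `C` (where `y_norm` lives), and voxels outside `C` are returned unchanged
#' (the undetermined boundary).
#'
#' @param u Input array (recon grid if `region` is given, else the measured
#'   region).
#' @param y_norm Measured stack in photoelectrons (measured-region shape).
#' @param sigma_norm Normalized read-noise standard deviation.
#' @param rho ADMM penalty (> 0).
#' @param region Optional [boundary_spec()].
#' @return Array of the same shape as `u`.
#' @export
prox_shifted_poisson <- function(u, y_norm, sigma_norm = 0, rho, region = NULL) {
  check_scalar(rho, "rho", 0, Inf, strict = TRUE)
  s <- sigma_norm^2
  if (is.null(region)) {
    out <- prox_sp_core(as.numeric(u), as.numeric(y_norm), s, rho)
    dim(out) <- dim(u)
    return(out)
  }
  stopifnot(inherits(region, "boundary_spec"), all(dim(u) == region$recon_shape))
  uc <- crop_region(u, region)
  vc <- prox_sp_core(as.numeric(uc), as.numeric(y_norm), s, rho)
  out <- u
  out[region$index[[1L]], region$index[[2L]], region$index[[3L]]] <- vc
  out
}

#' @rdname prox_shifted_poisson
#' @details `prox_poisson` is the `sigma_norm = 0` special case.
#' @export
prox_poisson <- function(u, y_norm, rho, region = NULL)
  prox_shifted_poisson(u, y_norm, 0, rho, region)

#' @rdname prox_shifted_poisson
#' @details `prox_gaussian` is `(rho * u + y) / (rho + 1)` on the measured
#'   region.
#' @export
prox_gaussian <- function(u, y_norm, rho, region = NULL) {
  check_scalar(rho, "rho", 0, Inf, strict = TRUE)
  if (is.null(region)) {
    out <- (rho * as.numeric(u) + as.numeric(y_norm)) / (rho + 1)
    dim(out) <- dim(u)
    return(out)
  }
  stopifnot(inherits(region, "boundary_spec"), all(dim(u) == region$recon_shape))
  uc <- crop_region(u, region)
  out <- u
  out[region$index[[1L]], region$index[[2L]], region$index[[3L]]] <-
    (rho * uc + as.numeric(y_norm)) / (rho + 1)
  out
}

# Dispatch tables used by the solver.
fidelity_nll <- function(fidelity) {
  switch(fidelity,
         gaussian = function(v, y, s) nll_gaussian(v, y),
         poisson = function(v, y, s) nll_poisson(v, y),
         shifted_poisson = function(v, y, s) nll_shifted_poisson(v, y, s),
         stop("unknown fidelity: ", fidelity, call. = FALSE))
}

fidelity_prox <- function(fidelity) {
  switch(fidelity,
         gaussian = function(u, y, s, rho, region) prox_gaussian(u, y, rho, region),
         poisson = function(u, y, s, rho, region) prox_poisson(u, y, rho, region),
         shifted_poisson = prox_shifted_poisson,
         stop("unknown fidelity: ", fidelity, call. = FALSE))
}
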