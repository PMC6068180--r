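#' Reconstruction signal-to-noise ratio against ground truth
#'
#' `10 * log10(sum(x_true^2) / mean((x_hat - x_true)^2))`: the squared
#' 2-norm of the reference over the mean squared error. (Numerator is a sum
#' and denominator a mean, so the value carries a `10 log10 n` offset
#' relative to a pure power ratio; both conventions order methods
#' identically and this one follows the definition used with the simulation
#' study this package reproduces.)
#'
#' @param x_hat Reconstructed volume.
#' @param x_true Ground-truth volume of the same shape.
#' @return SNR in dB; `+Inf` for an exact match.
#' @export
snr_db <- function(x_hat, x_true) {
  x_hat <- as_volume(x_hat, "x_hat"); x_true <- as_volume(x_true, "x_true")
  if (!all(dim(x_hat) == dim(x_true))) stop("shapes differ", call. = FALSE)
  mse <- mean((x_hat - x_true)^2)
  if (mse == 0) return(Inf)
  10 * log10(sum(x_true^2) / mse)
}

#' Normalized mean squared error after affine intensity matching
#'
#' Different deconvolution methods report intensities on different scales,
#' so before comparing a reconstruction to a reference the best affine map
#' `a * x_hat + b` is fitted by a derivative-free Nelder-Mead simplex search
#' (initialized at the closed-form least-squares solution), and the residual
#' sum of squares is divided by the squared 2-norm of the reference.
#'
#' @param x_hat Image or volume to evaluate.
#' @param reference Reference image of the same shape; must not be constant.
#' @return List with `nmse`, `scale` (a) and `offset` (b).
#' @export
nmse_affine <- function(x_hat, reference) {
  h <- as.numeric(x_hat); r <- as.numeric(reference)
  if (length(h) != length(r)) stop("shapes differ", call. = FALSE)
  if (sd(r) == 0) stop("constant reference; NMSE normalization undefined", call. = FALSE)
  denom <- sum(r^2)
  # closed-form least squares start
  vh <- var(h)
  a0 <- if (vh > 0) stats::cov(h, r) / vh else 0
  b0 <- mean(r) - a0 * mean(h)
  f <- function(p) sum((p[1L] * h + p[2L] - r)^2)
  fit <- optim(c(a0, b0), f, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000L))
  list(nmse = fit$value / denom, scale = fit$par[1L], offset = fit$par[2L])
}

#' Extract a 1D intensity profile along an axis
#'
#' @param volume A [focal_stack()] or 3D array `(nz, ny, nx)`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param through Length-3 voxel index `(z, y, x)` the line passes through
#'   (1-based); defaults to the volume center.
#' @param normalize Divide by the profile maximum (default `FALSE`).
#' @return Numeric vector.
#' @export
line_profile <- function(volume, axis = c("x", "y", "z"), through = NULL,
                         normalize = FALSE) {
  axis <- match.arg(axis)
  v <- as_volume(volume, "volume")
  d <- dim(v)
  if (is.null(through)) through <- vapply(d, center_index, integer(1L))
  through <- as.integer(through)
  if (length(through) != 3L || any(through < 1L) || any(through > d))
    stop("'through' index out of bounds", call. = FALSE)
  p <- switch(axis,
              x = v[through[1L], through[2L], ],
              y = v[through[1L], , through[3L]],
              z = v[, through[2L], through[3L]])
  if (normalize) {
    m <- max(p)
    if (m <= 0) stop("cannot normalize an all-zero profile", call. = FALSE)
    p <- p / m
  }
  p
}

#' Peak-to-peak distance of a two-peaked profile
#'
#' Finds the maximum in each half of the profile (e.g. the two shell
#' crossings of a line through a hollow sphere) and returns the distance
#' between them in sample units.
#'
#' @param profile Numeric vector.
#' @return List with `distance` (samples), `left` and `right` peak indices.
#' @export
peak_to_peak <- function(profile) {
  n <- length(profile)
  mid <- n %/% 2L
  left <- which.max(profile[seq_len(mid)])
  right <- mid + which.max(profile[(mid + 1L):n])
  list(distance = right - left, left = left, right = right)
}

#' Golden-section search for the regularization weight
#'
#' Minimizes (or maximizes) a unimodal scalar objective of the
#' regularization weight `nu` by golden-section bracketing, by default over
#' `log10(nu)` (regularization weights act multiplicatively). The search
#' stops when the bracket gap is below `tol` in `nu` units.
#'
#' @param objective Function of `nu` returning a scalar (e.g. NMSE, or
#'   negative SNR).
#' @param bracket Length-2 positive numeric: initial bracket for `nu`.
#' @param tol Bracket-gap termination threshold (default `1e-5`).
#' @param log_scale Search over `log10(nu)` (default `TRUE`).
#' @param maximize Maximize instead of minimize (default `FALSE`).
#' @return List with `nu`, `objective`, `evaluations`, `gap`.
#' @export
tune_nu_golden <- function(objective, bracket, tol = 1e-5, log_scale = TRUE,
                           maximize = FALSE) {
  stopifnot(length(bracket) == 2L, all(bracket > 0), bracket[1L] < bracket[2L])
  sgn <- if (maximize) -1 else 1
  to_t <- if (log_scale) log10 else identity
  from_t <- if (log_scale) function(t) 10^t else identity
  a <- to_t(bracket[1L]); b <- to_t(bracket[2L])
  gr <- (sqrt(5) - 1) / 2
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- sgn * objective(from_t(c1)); fd <- sgn * objective(from_t(d1))
  nev <- 2L
  while (from_t(b) - from_t(a) >= tol) {
    if (!is.finite(fc) || !is.finite(fd))
      stop("non-finite objective value in golden-section search", call. = FALSE)
    if (fc <= fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a)
      fc <- sgn * objective(from_t(c1)); nev <- nev + 1L
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a)
      fd <- sgn * objective(from_t(d1)); nev <- nev + 1L
    }
  }
  best_t <- if (fc <= fd) c1 else d1
  best_f <- min(fc, fd)
  list(nu = from_t(best_t), objective = sgn * best_f, evaluations = nev,
       gap = from_t(b) - from_t(a))
}
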