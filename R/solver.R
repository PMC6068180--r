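#' Solver configuration
#'
#' @param nu Regularization weight (>= 0).
#' @param rho ADMM penalty parameter shared by all splits, in photoelectron
#'   units; fixed across iterations (no adaptive schedule) so runs are
#'   deterministic. The default `NULL` scales the penalty to the data as
#'   `0.2 / mean(pmax(y, 0) + sigma_norm^2)`, matching the curvature of the
#'   Poisson-family likelihoods (about `1/counts`); a fixed dimensionless
#'   penalty that ignores the photon scale slows convergence by orders of
#'   magnitude at high counts.
#' @param max_iter Iteration cap (default 150).
#' @param tol Relative-change stopping tolerance (default `1e-3`): iterations
#'   stop once `||x_k+1 - x_k||_2 / ||x_k||_2 < tol`.
#' @param margins `NULL` for PSF-derived default margins (see
#'   [default_margins()]), a scalar/length-3 vector, or a 3x2 matrix of
#'   per-axis `(low, high)` voxel margins.
#' @param fidelity `"shifted_poisson"` (default), `"poisson"` or
#'   `"gaussian"`.
#' @param regularizer `"fh"` (default), `"tv"`, `"l1"`, `"laplacian"`,
#'   `"l2"` or `"none"`.
#' @param nonneg Enforce the non-negativity constraint (default `TRUE`).
#' @param log_every Print objective/relative change every this many
#'   iterations (0 = silent).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(nu = 0.05, rho = NULL, max_iter = 150L, tol = 1e-3,
                          margins = NULL,
                          fidelity = c("shifted_poisson", "poisson", "gaussian"),
                          regularizer = c("fh", "tv", "l1", "laplacian", "l2", "none"),
                          nonneg = TRUE, log_every = 0L) {
  fidelity <- match.arg(fidelity)
  regularizer <- match.arg(regularizer)
  check_scalar(nu, "nu", 0, Inf)
  if (!is.null(rho)) check_scalar(rho, "rho", 0, Inf, strict = TRUE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("'max_iter' must be >= 1", call. = FALSE)
  check_scalar(tol, "tol", 0, Inf, strict = TRUE)
  structure(list(nu = nu, rho = rho, max_iter = max_iter, tol = tol,
                 margins = margins, fidelity = fidelity,
                 regularizer = regularizer, nonneg = isTRUE(nonneg),
                 log_every = as.integer(log_every)),
            class = "solver_config")
}

# Optical transfer function of a PSF on a given grid: the PSF is embedded
# centered (cropped if larger), circular-shifted so its center sits at
# [1,1,1], and Fourier transformed.
psf_otf <- function(psf, shape) {
  v <- if (inherits(psf, "psf_stack")) psf$values else as_volume(psf, "psf")
  v <- embed_center(v, shape)
  fft3(ifftshift3(v))
}

#' Convolve a volume with a PSF (circular, FFT-based)
#'
#' Applies the linear image-formation operator `A`: 3D circular convolution
#' with the (slice-normalized) PSF, computed in the Fourier domain. The PSF
#' is zero-embedded or cropped to the volume shape and center-shifted to the
#' origin, so a centered delta maps to the centered PSF.
#'
#' @param x 3D array (or [focal_stack()]).
#' @param psf A [psf_stack()] or 3D array.
#' @return 3D array of model intensities, same shape as `x`.
#' @export
convolve_psf <- function(x, psf) {
  x <- as_volume(x, "x")
  otf <- psf_otf(psf, dim(x))
  Re(ifft3(fft3(x) * otf))
}

#' Deconvolve a focal stack by ADMM
#'
#' Minimizes the convex objective
#' `nll(A x) + nu * R(x) + I_[0, Inf)(x)` over an expanded reconstruction
#' volume (undetermined boundary): the data-fidelity negative log-likelihood
#' acts on the measured region only, the regularizer acts on the whole grid,
#' and the margins absorb the wrap-around error of the circular convolution.
#' The problem is split three ways (fidelity on `A x`, regularizer on the
#' difference field, non-negativity on `x`); each split has a closed-form
#' proximal update and the x-update solves Fourier-diagonal normal
#' equations, so each iteration costs a fixed small number of 3D FFTs.
#' Iterations stop when the relative change of `x` drops below `cfg$tol` or
#' at `cfg$max_iter`.
#'
#' @param y Measured focal stack: a [focal_stack()] in DN (noise parameters
#'   are then required, or estimated on the fly) or in photoelectrons, or a
#'   3D array (treated as photoelectrons with `sigma_norm` from `noise`).
#' @param psf A [psf_stack()] (e.g. a measured PSF); normalized on entry if
#'   not already, and zero-embedded to the reconstruction grid. Omit it and
#'   pass `optics` instead to render the theoretical PSF directly on the
#'   expanded reconstruction grid, which avoids truncating the blur model at
#'   the measurement edges.
#' @param optics An [optical_params()] object used to simulate the PSF on
#'   the reconstruction grid when `psf` is not supplied.
#' @param noise A [noise_params()] object; if `NULL` and `y` is in DN, the
#'   parameters are estimated from `y` with [estimate_noise_params()].
#' @param cfg A [solver_config()].
#' @return An object of class `deconv_result` with elements `x` (full
#'   reconstruction grid, photoelectrons, non-negative), `x_cropped`
#'   (measured region), `iterations`, `converged`, `history` (data frame
#'   with per-iteration objective, primal/dual residual norms and relative
#'   change), `region`, `noise`, and `cfg`.
#' @export
admm_deconvolve <- function(y, psf = NULL, noise = NULL, cfg = solver_config(),
                            optics = NULL) {
  stopifnot(inherits(cfg, "solver_config"))
  if (is.null(psf) && is.null(optics))
    stop("supply either 'psf' or 'optics'", call. = FALSE)
  if (!is.null(psf)) {
    if (!inherits(psf, "psf_stack")) psf <- normalize_psf(psf)
    if (!psf$normalized) psf <- normalize_psf(psf)
  }

  # measurement units -> photoelectrons
  sigma_norm <- 0
  if (inherits(y, "focal_stack") && y$unit == "DN") {
    if (is.null(noise)) noise <- estimate_noise_params(y)
    nm <- normalize_measurement(y, noise)
    yv <- nm$stack$values
    sigma_norm <- nm$sigma_norm
  } else {
    yv <- as_volume(y, "y")
    if (!is.null(noise)) sigma_norm <- noise$read_sigma_norm
  }
  if (anyNA(yv)) stop("NaN/NA in the measurement", call. = FALSE)

  mshape <- dim(yv)
  region <- if (is.null(cfg$margins)) {
    default_margins(mshape, if (is.null(psf)) mshape else dim(psf$values))
  } else if (inherits(cfg$margins, "boundary_spec")) cfg$margins
    else boundary_spec(mshape, cfg$margins)
  stopifnot(all(region$measured_shape == mshape))
  rshape <- region$recon_shape
  N <- prod(rshape)
  if (is.null(psf)) psf <- simulate_psf(optics, rshape)

  if (all(yv == 0)) {
    warning("all-zero measurement; returning a zero volume")
    zero <- array(0, rshape)
    return(structure(list(x = zero, x_cropped = crop_region(zero, region),
                          iterations = 0L, converged = TRUE,
                          history = data.frame(), region = region,
                          noise = noise, cfg = cfg),
                     class = "deconv_result"))
  }

  otf <- psf_otf(psf$values, rshape)
  otf2 <- Re(otf * Conj(otf))
  rho <- if (is.null(cfg$rho)) 0.2 / mean(pmax(yv, 0) + sigma_norm^2) else cfg$rho
  nu <- cfg$nu
  reg <- cfg$regularizer
  use_prox_reg <- reg %in% c("fh", "tv", "l1") && nu > 0
  tau <- if (use_prox_reg) nu / rho else 0

  den <- otf2 + 1  # rho |A|^2 + rho I, with the shared rho divided out
  if (use_prox_reg) {
    den <- den + switch(reg, fh = hessian_transfer(rshape),
                        tv = grad_transfer(rshape), l1 = 1)
  } else if (nu > 0 && reg == "l2") {
    den <- den + 2 * nu / rho
  } else if (nu > 0 && reg == "laplacian") {
    den <- den + (2 * nu / rho) * laplacian_transfer_sq(rshape)
  }

  prox_fid <- fidelity_prox(cfg$fidelity)
  nll_fid <- fidelity_nll(cfg$fidelity)

  # operators of the regularizer split
  reg_apply <- switch(reg, fh = hessian_apply, tv = grad_apply,
                      l1 = function(x) list(v = x), function(x) NULL)
  reg_adjoint <- switch(reg, fh = hessian_adjoint, tv = grad_adjoint,
                        l1 = function(Y) Y$v, function(Y) NULL)
  # initialization: measured stack (clamped >= 0) replicate-padded, then
  # flux-matched so sum(A x0) over C equals the observed flux — a widefield
  # stack carries roughly nz times the specimen flux (every plane collects
  # the full emission), and starting that heavy wastes many iterations
  # burning mass off; the problem is convex, so this only affects speed
  x <- pad_replicate(pmax(yv, 0), region$margins)
  Xhat <- fft3(x)
  Ax <- Re(ifft3(otf * Xhat))
  flux_obs <- sum(pmax(yv, 0))
  flux_mod <- sum(crop_region(Ax, region))
  if (flux_mod > 0 && flux_obs > 0) {
    x <- x * (flux_obs / flux_mod)
    Xhat <- Xhat * (flux_obs / flux_mod)
    Ax <- Ax * (flux_obs / flux_mod)
  }
  z1 <- Ax; u1 <- array(0, rshape)
  if (use_prox_reg) {
    Z2 <- reg_apply(x)
    U2 <- lapply(Z2, function(a) array(0, dim(a)))
  }
  z3 <- x; u3 <- array(0, rshape)

  hist_obj <- hist_pri <- hist_dua <- hist_rel <- numeric(cfg$max_iter)
  iter <- 0L; converged <- FALSE
  for (k in seq_len(cfg$max_iter)) {
    iter <- k
    # x-update: (|A|^2 + T_reg + 1) x = A^T q1 + (reg^T q2 + q3) in Fourier
    q1 <- z1 - u1
    q23 <- z3 - u3
    if (use_prox_reg) q23 <- q23 + reg_adjoint(cpp_list_diff(Z2, U2))
    Xhat <- (Conj(otf) * fft3(q1) + fft3(q23)) / den
    xnew <- Re(ifft3(Xhat))

    rel <- sqrt(sum((xnew - x)^2) / max(sum(x^2), .Machine$double.xmin))
    x <- xnew

    # z-updates and duals
    Ax <- Re(ifft3(otf * Xhat))
    z1_old <- z1
    z1 <- prox_fid(Ax + u1, yv, sigma_norm, rho, region)
    u1 <- u1 + Ax - z1
    dz2 <- 0; pri2 <- 0; pen <- 0
    if (use_prox_reg) {
      Hx <- reg_apply(x)
      ru <- cpp_reg_update(unclass(Hx), U2, Z2, tau)
      Z2 <- ru$Z2; U2 <- ru$U2
      dz2 <- ru$dz2; pri2 <- ru$pri2; pen <- nu * ru$pen
    } else {
      pen <- penalty_value(x, reg, nu)
    }
    z3_old <- z3
    if (cfg$nonneg) {
      z3 <- pmax(x + u3, 0)
      u3 <- u3 + x - z3
    } else {
      z3 <- x + u3  # inactive constraint: identity prox
      u3 <- u3 + x - z3
    }

    # diagnostics
    obj <- nll_fid(crop_region(Ax, region), yv, sigma_norm) + pen
    pri <- sqrt(sum((Ax - z1)^2) + pri2 + sum((x - z3)^2))
    dua <- rho * sqrt(sum((z1 - z1_old)^2) + dz2 + sum((z3 - z3_old)^2))
    hist_obj[k] <- obj; hist_pri[k] <- pri; hist_dua[k] <- dua; hist_rel[k] <- rel
    if (cfg$log_every > 0L && (k %% cfg$log_every == 0L || k == 1L))
      message(sprintf("iter %3d  objective %.6g  rel change %.3g", k, obj, rel))
    # the initialization makes iteration 1 a fixed point of the x-update
    # (z = A x0, duals 0), so the relative change is only meaningful from
    # the second iteration on
    if (k > 1L && rel < cfg$tol) { converged <- TRUE; break }
  }

  x <- pmax(x, 0)  # guarantee the non-negativity invariant at output
  structure(list(x = x, x_cropped = crop_region(x, region),
                 iterations = iter, converged = converged,
                 history = data.frame(iteration = seq_len(iter),
                                      objective = hist_obj[seq_len(iter)],
                                      primal_residual = hist_pri[seq_len(iter)],
                                      dual_residual = hist_dua[seq_len(iter)],
                                      rel_change = hist_rel[seq_len(iter)]),
                 region = region, noise = noise, cfg = cfg),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("Deconvolution result: %s grid (measured %s), %d iteration(s), %s\n",
              paste(dim(x$x), collapse = "x"),
              paste(x$region$measured_shape, collapse = "x"),
              x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  if (nrow(x$history))
    cat(sprintf("  final objective %.6g, relative change %.3g\n",
                tail(x$history$objective, 1L), tail(x$history$rel_change, 1L)))
  invisible(x)
}
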