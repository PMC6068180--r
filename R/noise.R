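#' Camera noise parameters
#'
#' Mixed Poisson-Gaussian camera noise is described by the gain `gamma`
#' (digital units recorded per detected photoelectron) and the read-noise
#' standard deviation `sigma` (digital units). Dividing a measurement by the
#' gain gives photoelectron units with normalized read noise
#' `sigma_norm = sigma / gamma`.
#'
#' @param gain Camera gain, DN per photoelectron (> 0).
#' @param read_sigma Read-noise standard deviation, DN (>= 0).
#' @return An object of class `noise_params` with fields `gain`,
#'   `read_sigma`, `read_sigma_norm`.
#' @export
noise_params <- function(gain, read_sigma) {
  check_scalar(gain, "gain", 0, Inf, strict = TRUE)
  check_scalar(read_sigma, "read_sigma", 0, Inf)
  structure(list(gain = gain, read_sigma = read_sigma,
                 read_sigma_norm = read_sigma / gain),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("Noise parameters: gain %.4g DN/e-, read sigma %.4g DN (%.4g e-)\n",
              x$gain, x$read_sigma, x$read_sigma_norm))
  if (!is.null(attr(x, "flagged")) && isTRUE(attr(x, "flagged")))
    cat("  [flagged: intensity range too narrow to identify the gain reliably]\n")
  invisible(x)
}

#' Simulate a mixed Poisson-Gaussian camera measurement
#'
#' Draws each voxel independently as
#' `gain * Poisson(rate) + Normal(0, read_sigma^2)`,
#' where the rate is the expected photoelectron count (the blurred volume).
#'
#' @param clean_e Non-negative 3D array (or [focal_stack()]) of expected
#'   photoelectron counts per voxel.
#' @param noise A [noise_params()] object.
#' @param seed Optional integer seed; the draw is reproducible given the seed
#'   and the caller's RNG state is restored.
#' @param dxy_nm,dz_nm Voxel pitches recorded on the returned stack.
#' @return A [focal_stack()] in digital units (DN).
#' @export
simulate_measurement <- function(clean_e, noise, seed = NULL,
                                 dxy_nm = NULL, dz_nm = NULL) {
  stopifnot(inherits(noise, "noise_params"))
  if (inherits(clean_e, "focal_stack")) {
    if (is.null(dxy_nm)) dxy_nm <- clean_e$dxy_nm
    if (is.null(dz_nm)) dz_nm <- clean_e$dz_nm
  }
  x <- as_volume(clean_e, "clean_e")
  if (min(x) < 0) stop("'clean_e' must be non-negative", call. = FALSE)
  vals <- with_seed(seed, {
    noise$gain * rpois(length(x), as.numeric(x)) +
      rnorm(length(x), 0, noise$read_sigma)
  })
  dim(vals) <- dim(x)
  focal_stack(vals, unit = "DN", dxy_nm = dxy_nm, dz_nm = dz_nm)
}

#' Convert a raw measurement to normalized photoelectron units
#'
#' Divides the stack by the camera gain so the signal follows a
#' Poisson-Gaussian model in photoelectrons with normalized read noise
#' `sigma_norm = read_sigma / gain`.
#'
#' @param y A [focal_stack()] (or 3D array) in DN.
#' @param noise A [noise_params()] object with positive gain.
#' @return A list with `stack` (a `focal_stack` in photoelectrons) and
#'   `sigma_norm`.
#' @export
normalize_measurement <- function(y, noise) {
  stopifnot(inherits(noise, "noise_params"))
  if (noise$gain <= 0) stop("gain must be > 0", call. = FALSE)
  dxy <- NULL; dz <- NULL
  if (inherits(y, "focal_stack")) { dxy <- y$dxy_nm; dz <- y$dz_nm }
  v <- as_volume(y, "y")
  list(stack = focal_stack(v / noise$gain, unit = "photoelectrons",
                           dxy_nm = dxy, dz_nm = dz),
       sigma_norm = noise$read_sigma_norm)
}

#' Estimate camera gain and read noise from a focal stack
#'
#' Two-step mean-variance estimator in the spirit of local noise-fitting
#' methods: (1) collect local (mean, variance) pairs from non-overlapping
#' blocks of each slice, keeping only low-texture, unsaturated blocks; (2)
#' fit the affine variance law `Var(y) = gain * E(y) + read_sigma^2` implied
#' by the mixed Poisson-Gaussian model, by iteratively reweighted least
#' squares with weights inversely proportional to the squared predicted
#' variance (the sampling variance of a local variance estimate scales with
#' its square).
#'
#' Local noise variance is estimated, by default, from second-difference
#' pseudo-residuals within each block (`r = (y[i-1] - 2 y[i] + y[i+1]) /
#' sqrt(6)` along both lateral axes), which is unbiased when the underlying
#' signal is locally linear; the plain unbiased block variance
#' (`var_method = "moment"`) is also available but is inflated by smooth
#' signal ramps.
#'
#' @param y A [focal_stack()] or 3D array in DN.
#' @param block Block side length in pixels (default 8).
#' @param texture_quantile Blocks whose local gradient energy exceeds this
#'   quantile are discarded as textured (default 0.75).
#' @param sat_quantile Saturation ceiling as a quantile of the stack (default
#'   0.995); blocks containing values at or above the ceiling are discarded.
#' @param var_method `"difference"` (default) or `"moment"`; see Details.
#' @param irls_iter Number of reweighting iterations (default 6).
#' @return A [noise_params()] object with attributes `n_pairs` (number of
#'   mean-variance pairs used) and `flagged` (`TRUE` when the intensity range
#'   is too narrow to identify the slope reliably, with a warning).
#' @export
estimate_noise_params <- function(y, block = 8L, texture_quantile = 0.75,
                                  sat_quantile = 0.995,
                                  var_method = c("difference", "moment"),
                                  irls_iter = 6L) {
  var_method <- match.arg(var_method)
  v <- as_volume(y, "y")
  d <- dim(v)
  block <- as.integer(block)
  if (block < 4L) stop("'block' must be >= 4", call. = FALSE)
  ceiling_dn <- quantile(v, sat_quantile, names = FALSE)

  nby <- d[2L] %/% block; nbx <- d[3L] %/% block
  if (nby < 1L || nbx < 1L) stop("stack smaller than one block", call. = FALSE)
  means <- vars <- tex <- smax <- NULL
  for (iz in seq_len(d[1L])) {
    sl <- v[iz, seq_len(nby * block), seq_len(nbx * block)]
    dim(sl) <- c(nby * block, nbx * block)
    bi <- rep(seq_len(nby), each = block)
    bj <- rep(seq_len(nbx), each = block)
    g <- interaction(bi[row(sl)], bj[col(sl)], drop = FALSE)

    m <- tapply(sl, g, mean)
    mx <- tapply(sl, g, max)
    # texture proxy: gradient energy of a 3x3 box-smoothed slice, so the
    # score reflects signal structure rather than the block's own noise
    # realization (thresholding the raw gradient energy preferentially
    # discards blocks with large noise variance and biases the fit)
    sm <- box3(sl)
    gx <- sm[, -1L] - sm[, -ncol(sm)]
    gy <- sm[-1L, ] - sm[-nrow(sm), ]
    gx2 <- matrix(0, nrow(sl), ncol(sl)); gx2[, -ncol(sl)] <- gx^2
    gy2 <- matrix(0, nrow(sl), ncol(sl)); gy2[-nrow(sl), ] <- gy^2
    ge <- tapply(gx2 + gy2, g, mean)

    if (var_method == "moment") {
      s2 <- tapply(sl, g, var)
    } else {
      # second-difference pseudo-residuals along both lateral axes:
      # unbiased for the local noise variance under locally linear signal
      rx <- (sl[, -c(1L, ncol(sl))] * -2 + sl[, -c(ncol(sl) - 1L, ncol(sl))] +
               sl[, -c(1L, 2L)]) / sqrt(6)
      ry <- (sl[-c(1L, nrow(sl)), ] * -2 + sl[-c(nrow(sl) - 1L, nrow(sl)), ] +
               sl[-c(1L, 2L), ]) / sqrt(6)
      rx2 <- matrix(NA_real_, nrow(sl), ncol(sl)); rx2[, -c(1L, ncol(sl))] <- rx^2
      ry2 <- matrix(NA_real_, nrow(sl), ncol(sl)); ry2[-c(1L, nrow(sl)), ] <- ry^2
      s2x <- tapply(rx2, g, mean, na.rm = TRUE)
      s2y <- tapply(ry2, g, mean, na.rm = TRUE)
      s2 <- (s2x + s2y) / 2
    }
    means <- c(means, as.numeric(m))
    vars <- c(vars, as.numeric(s2))
    tex <- c(tex, as.numeric(ge))
    smax <- c(smax, as.numeric(mx))
  }

  keep <- is.finite(means) & is.finite(vars) & smax < ceiling_dn
  # texture threshold applied within intensity strata: a global threshold
  # would discard essentially every bright block (whose gradients scale with
  # brightness) and censor the top of the mean-variance cloud
  if (texture_quantile < 1 && any(keep)) {
    strata <- cut(rank(means[keep], ties.method = "first"),
                  breaks = 10L, labels = FALSE)
    thr <- tapply(tex[keep], strata, quantile, probs = texture_quantile,
                  names = FALSE)
    keep[keep] <- tex[keep] <= thr[strata]
  }
  m <- means[keep]; s2 <- vars[keep]
  if (length(m) < 10L) stop("too few usable blocks for noise estimation", call. = FALSE)

  # IRLS fit of s2 = gain * m + sigma^2
  w <- rep(1, length(m))
  gain <- NA_real_; sig2 <- NA_real_
  for (it in seq_len(max(1L, as.integer(irls_iter)))) {
    fit <- lm(s2 ~ m, weights = w)
    gain <- coef(fit)[[2L]]; sig2 <- coef(fit)[[1L]]
    pred <- pmax(gain * m + sig2, 1e-8 + 0.05 * mean(abs(s2)))
    w <- 1 / pred^2
  }
  flagged <- FALSE
  mrange <- diff(range(m))
  if (mrange^2 < 4 * mean(pmax(s2, 0)) || gain <= 0) {
    flagged <- TRUE
    warning("intensity range too narrow to identify the gain reliably")
    # slope and intercept are not separable on a narrow intensity range;
    # report a zero slope and take the noise variance directly
    gain <- 0
  }
  # recompute the intercept as the weighted mean residual (identical to the
  # fitted intercept whenever the slope is untouched)
  gain <- max(gain, 0)
  sig2 <- sum(w * (s2 - gain * m)) / sum(w)
  out <- noise_params(max(gain, 1e-12), sqrt(max(sig2, 0)))
  attr(out, "n_pairs") <- length(m)
  attr(out, "flagged") <- flagged
  out
}

# 3x3 box filter with replicate edges (texture pre-smoothing).
box3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  up <- m[c(1L, seq_len(n1 - 1L)), ]; dn <- m[c(seq_len(n1 - 1L) + 1L, n1), ]
  s <- m + up + dn
  lf <- s[, c(1L, seq_len(n2 - 1L))]; rt <- s[, c(seq_len(n2 - 1L) + 1L, n2)]
  (s + lf + rt) / 9
}

#' Calibration frames for dark- and flat-field correction
#'
#' @param dark 2D mean dark image (DN), lateral shape of the stack.
#' @param flat 2D flat-field image (dimensionless, global median ~ 1);
#'   must be strictly positive.
#' @return An object of class `calibration_frames`.
#' @export
calibration_frames <- function(dark, flat) {
  if (!is.matrix(dark) || !is.matrix(flat) || !all(dim(dark) == dim(flat)))
    stop("'dark' and 'flat' must be matrices of equal shape", call. = FALSE)
  if (min(flat) <= 0) stop("flat field must be strictly positive", call. = FALSE)
  structure(list(dark = dark, flat = flat), class = "calibration_frames")
}

#' Dark- and flat-field correct a raw focal stack
#'
#' Subtracts the dark (offset) image and divides by the flat-field image
#' pixel by pixel in every slice.
#'
#' @param raw A [focal_stack()] or 3D array in DN.
#' @param cal A [calibration_frames()] object whose lateral shape matches.
#' @return Corrected stack of the same class/shape as supplied.
#' @export
dark_flat_correct <- function(raw, cal) {
  stopifnot(inherits(cal, "calibration_frames"))
  is_fs <- inherits(raw, "focal_stack")
  v <- as_volume(raw, "raw")
  d <- dim(v)
  if (!all(dim(cal$dark) == d[2:3]))
    stop("calibration shape does not match the lateral stack shape", call. = FALSE)
  for (iz in seq_len(d[1L])) {
    sl <- v[iz, , ]
    dim(sl) <- d[2:3]
    v[iz, , ] <- (sl - cal$dark) / cal$flat
  }
  if (is_fs) { raw$values <- v; raw } else v
}

#' Build a flat-field image from autofluorescence slide images
#'
#' Computes the per-pixel median across repeated slide images, subtracts the
#' dark image, and divides by the global median of the result, producing a
#' dimensionless sensitivity map with global median one.
#'
#' @param slide_images List of >= 3 2D images (DN) of a uniform slide at
#'   different positions.
#' @param dark 2D mean dark image (DN).
#' @return 2D flat-field matrix (global median 1).
#' @export
build_flat_field <- function(slide_images, dark) {
  if (!is.list(slide_images) || length(slide_images) < 3L)
    stop("need at least 3 slide images", call. = FALSE)
  d <- dim(slide_images[[1L]])
  if (!all(vapply(slide_images, function(s) is.matrix(s) && all(dim(s) == d), TRUE)))
    stop("slide images must be matrices of identical shape", call. = FALSE)
  if (!is.matrix(dark) || !all(dim(dark) == d))
    stop("'dark' shape must match the slide images", call. = FALSE)
  arr <- array(unlist(slide_images), c(d, length(slide_images)))
  med <- apply(arr, c(1L, 2L), median) - dark
  flat <- med / median(med)
  if (min(flat) <= 0) {
    bad <- which(flat <= 0, arr.ind = TRUE)
    stop(sprintf("flat field non-positive at %d pixel(s), first at (%d, %d)",
                 nrow(bad), bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  flat
}
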