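#' Phantom specification
#'
#' Describes a synthetic ground-truth volume emulating the morphologies of
#' common fluorescence targets: a hollow spherical shell (membrane-stained
#' microsphere), random curvilinear filaments (actin-like), or smooth
#' ellipsoidal blobs (nucleus-like).
#'
#' @param kind `"hollow_shell"`, `"filaments"` or `"blobs"`.
#' @param shape Integer `(nz, ny, nx)`.
#' @param dxy_nm,dz_nm Voxel pitches (nm).
#' @param peak_photoelectrons Maximum expected photoelectron count of the
#'   volume (> 0).
#' @param shell_diameter_nm,shell_thickness_nm Hollow shell geometry
#'   (defaults 6000 and 300 nm; the thickness default makes the hollow core
#'   resolvable at typical pitches).
#' @param n_filaments,filament_sigma_nm Filament count and Gaussian tube
#'   radius.
#' @param n_blobs,blob_radius_nm Blob count and lateral semi-axis range (nm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("hollow_shell", "filaments", "blobs"),
                         shape, dxy_nm = 65, dz_nm = 150,
                         peak_photoelectrons = 100,
                         shell_diameter_nm = 6000, shell_thickness_nm = 300,
                         n_filaments = 10L, filament_sigma_nm = 120,
                         n_blobs = 6L, blob_radius_nm = c(800, 2500)) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  check_scalar(peak_photoelectrons, "peak_photoelectrons", 0, Inf, strict = TRUE)
  if (kind == "hollow_shell") {
    ext <- c(shape[1L] * dz_nm, shape[2L] * dxy_nm, shape[3L] * dxy_nm)
    if (shell_diameter_nm + shell_thickness_nm > min(ext[2:3]))
      stop("shell does not fit laterally inside the volume", call. = FALSE)
  }
  structure(list(kind = kind, shape = shape, dxy_nm = dxy_nm, dz_nm = dz_nm,
                 peak_photoelectrons = peak_photoelectrons,
                 shell_diameter_nm = shell_diameter_nm,
                 shell_thickness_nm = shell_thickness_nm,
                 n_filaments = as.integer(n_filaments),
                 filament_sigma_nm = filament_sigma_nm,
                 n_blobs = as.integer(n_blobs),
                 blob_radius_nm = blob_radius_nm),
            class = "phantom_spec")
}

# physical voxel-center coordinates (nm) relative to the volume center
phantom_coords <- function(spec) {
  list(z = (seq_len(spec$shape[1L]) - center_index(spec$shape[1L])) * spec$dz_nm,
       y = (seq_len(spec$shape[2L]) - center_index(spec$shape[2L])) * spec$dxy_nm,
       x = (seq_len(spec$shape[3L]) - center_index(spec$shape[3L])) * spec$dxy_nm)
}

#' Generate a synthetic ground-truth volume
#'
#' Deterministic given `seed`. The result is non-negative with maximum value
#' exactly `peak_photoelectrons`.
#'
#' Shapes: `hollow_shell` is the indicator of a spherical annulus of the
#' given diameter and thickness centered in the volume (interior exactly
#' zero); `filaments` are smoothed random curvilinear tubes grown with
#' slowly turning direction vectors; `blobs` are soft-edged random
#' ellipsoids.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (unused by the deterministic `hollow_shell`).
#' @return 3D array `(nz, ny, nx)` in photoelectrons.
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec)
  d <- spec$shape
  vol <- switch(spec$kind,
    hollow_shell = {
      r2 <- outer(outer(co$z^2, co$y^2, `+`), co$x^2, `+`)
      r <- sqrt(r2)
      r_mid <- spec$shell_diameter_nm / 2
      half <- spec$shell_thickness_nm / 2
      # raised-cosine radial cross-section: peaks exactly at the mid-radius,
      # falls smoothly to zero at +- thickness/2 (a stained membrane is not
      # a hard indicator), interior and exterior exactly zero
      v <- array(0, d)
      inside <- abs(r - r_mid) <= half
      v[inside] <- 0.5 * (1 + cos(pi * (r[inside] - r_mid) / half))
      v
    },
    filaments = with_seed(seed, {
      v <- array(0, d)
      ext <- c(range(co$z), range(co$y), range(co$x))
      step <- spec$dxy_nm
      n_steps <- ceiling(2.5 * max(d[2:3]) )
      for (f in seq_len(spec$n_filaments)) {
        p <- c(runif(1, ext[1L], ext[2L]) * 0.6,
               runif(1, ext[3L], ext[4L]) * 0.8,
               runif(1, ext[5L], ext[6L]) * 0.8)
        dir <- rnorm(3L); dir[1L] <- dir[1L] * 0.3  # mostly in-plane
        dir <- dir / sqrt(sum(dir^2))
        for (s in seq_len(n_steps)) {
          turn <- rnorm(3L, 0, 0.15); turn[1L] <- turn[1L] * 0.3
          dir <- dir + turn
          dir <- dir / sqrt(sum(dir^2))
          p <- p + dir * step
          iz <- round((p[1L] - co$z[1L]) / spec$dz_nm) + 1L
          iy <- round((p[2L] - co$y[1L]) / spec$dxy_nm) + 1L
          ix <- round((p[3L] - co$x[1L]) / spec$dxy_nm) + 1L
          if (iz >= 1L && iz <= d[1L] && iy >= 1L && iy <= d[2L] &&
              ix >= 1L && ix <= d[3L])
            v[iz, iy, ix] <- v[iz, iy, ix] + 1
        }
      }
      gaussian_smooth(v, spec$filament_sigma_nm, spec$dxy_nm, spec$dz_nm)
    }),
    blobs = with_seed(seed, {
      v <- array(0, d)
      for (b in seq_len(spec$n_blobs)) {
        ax_y <- runif(1, spec$blob_radius_nm[1L], spec$blob_radius_nm[2L])
        ax_x <- runif(1, spec$blob_radius_nm[1L], spec$blob_radius_nm[2L])
        ax_z <- runif(1, 0.5, 1) * min(ax_y, ax_x)
        cz <- runif(1, min(co$z), max(co$z)) * 0.5
        cy <- runif(1, min(co$y), max(co$y)) * 0.7
        cx <- runif(1, min(co$x), max(co$x)) * 0.7
        q <- outer(outer(((co$z - cz) / ax_z)^2, ((co$y - cy) / ax_y)^2, `+`),
                   ((co$x - cx) / ax_x)^2, `+`)
        amp <- runif(1, 0.5, 1)
        v <- v + amp * exp(-q^2)  # soft-edged superellipsoid profile
      }
      v
    }))
  mx <- max(vol)
  if (mx <= 0) stop("degenerate phantom (all zero)", call. = FALSE)
  vol * (spec$peak_photoelectrons / mx)
}

# separable FFT Gaussian smoothing (periodic; phantom content stays away
# from the boundary by construction)
gaussian_smooth <- function(v, sigma_nm, dxy_nm, dz_nm) {
  d <- dim(v)
  kern1 <- function(n, pitch) {
    pos <- (seq_len(n) - 1L) * pitch
    pos <- pmin(pos, n * pitch - pos)
    k <- exp(-0.5 * pos^2 / sigma_nm^2)
    k / sum(k)
  }
  kz <- kern1(d[1L], dz_nm); ky <- kern1(d[2L], dxy_nm); kx <- kern1(d[3L], dxy_nm)
  kern <- outer(outer(kz, ky), kx)
  Re(ifft3(fft3(v) * fft3(kern)))
}

#' Simulate a complete widefield focal-stack acquisition
#'
#' Blurs a ground-truth photoelectron volume with the simulated (or
#' supplied) PSF in the frequency domain, then applies mixed
#' Poisson-Gaussian camera noise, returning both stages for
#' ground-truth-aware evaluation.
#'
#' With `pad = 0` the blur is the plain circular convolution on the truth
#' grid. Nonzero `pad` emulates a real acquisition: the truth is
#' zero-embedded in an expanded volume, blurred there with a PSF rendered on
#' the expanded grid, and the measured region is cropped out, so
#' out-of-focus light genuinely leaves the field of view instead of
#' wrapping around. Use margins matching the solver's [boundary_spec()] when
#' testing the undetermined-boundary reconstruction.
#'
#' @param truth 3D array (photoelectrons), e.g. from [make_phantom()].
#' @param optics An [optical_params()] object (ignored when `psf` is given).
#' @param noise A [noise_params()] object.
#' @param seed Integer seed for the noise draw.
#' @param psf Optional [psf_stack()] to reuse across repeated simulations;
#'   must cover the padded grid when `pad` is nonzero.
#' @param pad Per-axis margins: 0 (default), a length-3 vector, a 3x2
#'   matrix, or a [boundary_spec()].
#' @return List with `clean_e` (noise-free blurred measurement,
#'   photoelectrons), `noisy` (a [focal_stack()] in DN), `psf` (on the
#'   padded grid when padding) and `region` (the [boundary_spec()] used).
#' @export
simulate_focal_stack <- function(truth, optics, noise, seed = NULL, psf = NULL,
                                 pad = 0L) {
  truth <- as_volume(truth, "truth")
  region <- if (inherits(pad, "boundary_spec")) pad
            else boundary_spec(dim(truth), pad)
  stopifnot(all(region$measured_shape == dim(truth)))
  big <- array(0, region$recon_shape)
  big[region$index[[1L]], region$index[[2L]], region$index[[3L]]] <- truth
  if (is.null(psf)) psf <- simulate_psf(optics, region$recon_shape)
  if (!all(dim(psf$values) == region$recon_shape) &&
      any(dim(psf$values) < region$recon_shape))
    warning("PSF smaller than the padded grid; blur model is truncated")
  clean_full <- pmax(convolve_psf(big, psf), 0)  # clip FFT rounding negatives
  clean <- crop_region(clean_full, region)
  noisy <- simulate_measurement(clean, noise, seed = seed,
                                dxy_nm = psf$dxy_nm, dz_nm = psf$dz_nm)
  list(clean_e = clean, noisy = noisy, psf = psf, region = region)
}
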