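#' Optical parameters of a widefield fluorescence microscope
#'
#' Bundles the quantities needed to simulate the depth-invariant intensity
#' point spread function (PSF) of a high-NA widefield objective: numerical
#' aperture, immersion refractive index, emission wavelength and the voxel
#' geometry of the focal stack. Magnification and objective focal length are
#' retained as metadata only: the constant amplitude prefactor they enter is
#' removed by the per-slice PSF normalization.
#'
#' @param na Numerical aperture of the objective (dimensionless);
#'   must satisfy `0 < na < n_immersion` so the aperture half-angle
#'   `alpha = asin(na / n_immersion)` is defined.
#' @param n_immersion Refractive index of the immersion medium.
#' @param wavelength_nm Emission wavelength in nm.
#' @param dxy_nm Lateral voxel pitch in nm (object-referred).
#' @param dz_nm Axial voxel pitch in nm.
#' @param oversample Integer lateral supersampling factor used when rendering
#'   the PSF; the field is evaluated on an `oversample`-times finer grid and
#'   block-averaged down to the sensor pitch to model pixel integration.
#' @param n_phi Number of composite-trapezoid nodes for the aperture-angle
#'   quadrature of the amplitude PSF integral.
#' @param magnification,f_obj_mm Informational system magnification and
#'   objective focal length (not used in computation).
#'
#' @return An object of class `optical_params`.
#' @examples
#' op <- optical_params(na = 1.4, n_immersion = 1.51, wavelength_nm = 525,
#'                      dxy_nm = 65, dz_nm = 150)
#' op$alpha  # aperture half-angle, radians
#' @export
optical_params <- function(na, n_immersion, wavelength_nm, dxy_nm, dz_nm,
                           oversample = 4L, n_phi = 256L,
                           magnification = NA_real_, f_obj_mm = NA_real_) {
  check_scalar(na, "na", 0, Inf, strict = TRUE)
  check_scalar(n_immersion, "n_immersion", 0, Inf, strict = TRUE)
  if (na >= n_immersion)
    stop("'na' must be < 'n_immersion' (asin(na/n) undefined otherwise)", call. = FALSE)
  check_scalar(wavelength_nm, "wavelength_nm", 0, Inf, strict = TRUE)
  check_scalar(dxy_nm, "dxy_nm", 0, Inf, strict = TRUE)
  check_scalar(dz_nm, "dz_nm", 0, Inf, strict = TRUE)
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("'oversample' must be >= 1", call. = FALSE)
  n_phi <- as.integer(n_phi)
  if (n_phi < 2L) stop("'n_phi' must be >= 2", call. = FALSE)
  structure(list(
    na = na, n_immersion = n_immersion, wavelength_nm = wavelength_nm,
    dxy_nm = dxy_nm, dz_nm = dz_nm, oversample = oversample, n_phi = n_phi,
    magnification = magnification, f_obj_mm = f_obj_mm,
    alpha = asin(na / n_immersion),      # aperture half-angle (rad)
    k = n_immersion / wavelength_nm      # wave number (cycles/nm)
  ), class = "optical_params")
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf("Optical parameters: NA %.3g / n %.4g / lambda %.4g nm\n",
              x$na, x$n_immersion, x$wavelength_nm))
  cat(sprintf("  voxel pitch %g x %g nm (xy x z), oversample %dx, %d quadrature nodes\n",
              x$dxy_nm, x$dxy_nm, x$dz_nm, x$oversample, x$n_phi))
  invisible(x)
}

#' Point spread function stack
#'
#' A 3D intensity PSF sampled on the focal-stack voxel grid, with the peak at
#' the center voxel `(nz %/% 2 + 1, ny %/% 2 + 1, nx %/% 2 + 1)`. When
#' `normalized` is `TRUE` every xy-slice sums to one, which expresses the
#' reconstructed volume in units of photoelectrons collected per exposure.
#'
#' @param values Non-negative 3D array, dim `(nz, ny, nx)`.
#' @param z_offsets_nm Axial position of each slice relative to focus (nm).
#' @param dxy_nm,dz_nm Voxel pitches (nm).
#' @param normalized Logical; whether per-slice normalization has been applied.
#' @return An object of class `psf_stack`.
#' @seealso [simulate_psf()], [normalize_psf()]
#' @export
psf_stack <- function(values, z_offsets_nm, dxy_nm, dz_nm, normalized = FALSE) {
  values <- as_volume(values, "values")
  if (min(values) < 0) stop("PSF values must be non-negative", call. = FALSE)
  if (length(z_offsets_nm) != dim(values)[1L])
    stop("length(z_offsets_nm) must equal nz", call. = FALSE)
  structure(list(values = values, z_offsets_nm = as.numeric(z_offsets_nm),
                 dxy_nm = dxy_nm, dz_nm = dz_nm, normalized = isTRUE(normalized)),
            class = "psf_stack")
}

#' @export
print.psf_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("PSF stack: %d x %d x %d (z,y,x), pitch %g/%g nm, %s\n",
              d[1L], d[2L], d[3L], x$dxy_nm, x$dz_nm,
              if (x$normalized) "slice-normalized" else "unnormalized"))
  invisible(x)
}

#' Normalize a PSF so each xy-slice sums to one
#'
#' Per-slice normalization defines the measurement scale: a point emitter of
#' one photoelectron contributes one photoelectron in total to every focal
#' plane, so the reconstructed intensities are photoelectrons per voxel.
#'
#' @param psf A [psf_stack()] or a 3D array.
#' @return A `psf_stack` with `normalized = TRUE` (arrays are wrapped with
#'   trivial geometry).
#' @export
normalize_psf <- function(psf) {
  if (!inherits(psf, "psf_stack")) {
    v <- as_volume(psf, "psf")
    psf <- psf_stack(v, z_offsets_nm = seq_len(dim(v)[1L]) - center_index(dim(v)[1L]),
                     dxy_nm = 1, dz_nm = 1)
  }
  v <- psf$values
  sums <- apply(v, 1L, sum)
  if (any(sums <= 0)) stop("PSF has an all-zero xy-slice; cannot normalize", call. = FALSE)
  psf$values <- v / array(sums, dim(v))  # recycles along z (first dim)
  psf$normalized <- TRUE
  psf
}

#' In-focus amplitude PSF (Debye diffraction integral)
#'
#' Evaluates the scalar Debye amplitude PSF of an Abbe-sine corrected
#' objective at the focal plane,
#' \deqn{h_A(r) = \int_0^\alpha \sqrt{\cos\varphi}\,
#'   J_0(2\pi k \sin\varphi\, r)\, \sin\varphi\, d\varphi,}
#' by composite trapezoid quadrature over the aperture angle. The constant
#' prefactor (magnification over focal length squared times wavelength
#' squared) is omitted; it is removed later by per-slice normalization.
#'
#' @param params An [optical_params()] object.
#' @param r_nm Radial coordinates (nm) at which to evaluate the field; any
#'   shape (vector or matrix, e.g. a centered lateral grid of radii).
#' @param n_phi Number of quadrature nodes (default from `params`).
#' @return Field amplitude with the same shape as `r_nm` (real-valued: the
#'   unaberrated Abbe-sine pupil is real, so the in-focus field is too).
#' @examples
#' op <- optical_params(1.4, 1.51, 525, 65, 150)
#' apsf_infocus(op, 0)   # = (2/3) (1 - cos(alpha)^1.5)
#' @export
apsf_infocus <- function(params, r_nm, n_phi = params$n_phi) {
  stopifnot(inherits(params, "optical_params"))
  n_phi <- as.integer(n_phi)
  if (is.na(n_phi) || n_phi < 2L) stop("'n_phi' must be >= 2", call. = FALSE)
  phi <- seq(0, params$alpha, length.out = n_phi)
  w <- rep(phi[2L] - phi[1L], n_phi); w[c(1L, n_phi)] <- w[1L] / 2  # trapezoid
  pupil <- sqrt(cos(phi)) * sin(phi) * w
  shp <- dim(r_nm)
  r <- abs(as.numeric(r_nm))  # radial coordinate; J0 is even
  # matrix of J0(2 pi k sin(phi) r): rows r, cols phi
  out <- besselJ(outer(r, 2 * pi * params$k * sin(phi)), 0) %*% pupil
  out <- as.numeric(out)
  if (!is.null(shp)) dim(out) <- shp
  out
}

#' Amplitude transfer function from an in-focus amplitude PSF
#'
#' Back-propagates the image-plane field to the aperture plane: the ATF is
#' the (inverse) Fourier transform of the amplitude PSF. The returned pupil
#' is sampled on the DFT frequency grid of the input field and is band
#' limited to the disk of radius NA/wavelength.
#'
#' @param apsf Real or complex matrix: the in-focus field sampled on a
#'   centered lateral grid with pitch `d_nm`.
#' @param d_nm Sample pitch of the field grid (nm).
#' @return A list with `values` (complex matrix in DFT layout, frequency
#'   origin at `[1,1]`), and `fu`, `fv` (frequency coordinates, cycles/nm,
#'   along the two axes).
#' @export
atf_from_apsf <- function(apsf, d_nm = 1) {
  if (!is.matrix(apsf)) stop("'apsf' must be a matrix", call. = FALSE)
  d <- dim(apsf)
  # move grid center to [1,1] so the DFT sees a field centered at the origin
  ap <- apsf[shift_order(d[1L]), shift_order(d[2L])]
  H <- stats::fft(ap, inverse = TRUE) / length(ap)
  list(values = H, fu = fft_freq(d[1L], d_nm), fv = fft_freq(d[2L], d_nm))
}

#' Non-paraxial defocus phase factor
#'
#' The defocus factor applied to the amplitude transfer function to shift
#' focus by `z_nm`:
#' \deqn{D(u,v,z) = \exp\{-i 2\pi z \sqrt{k^2 - (\mathrm{NA}/\lambda)^2 (u^2+v^2)}\},}
#' where \eqn{(u,v)} are pupil coordinates normalized so the aperture edge is
#' the unit circle (the physical frequency is \eqn{(\mathrm{NA}/\lambda) u}),
#' and \eqn{k = n/\lambda}. No paraxial approximation is made, so the factor
#' is valid for high-NA objectives. Outside the propagating passband
#' (negative radicand, evanescent waves) the factor is defined as 0.
#'
#' @param u,v Normalized pupil coordinates (aperture edge at `u^2+v^2 = 1`);
#'   vectors or arrays of equal shape.
#' @param z_nm Axial defocus (nm).
#' @param params An [optical_params()] object.
#' @return Complex values of unit modulus inside the passband, 0 outside.
#' @export
defocus_factor <- function(u, v, z_nm, params) {
  stopifnot(inherits(params, "optical_params"))
  check_scalar(z_nm, "z_nm")
  rad <- params$k^2 - (params$na / params$wavelength_nm)^2 * (u^2 + v^2)
  out <- exp(-1i * 2 * pi * z_nm * sqrt(pmax(rad, 0)))
  out[rad < 0] <- 0 + 0i
  out
}

#' Simulate a depth-invariant widefield intensity PSF
#'
#' Renders the 3D intensity PSF via the generalized-aperture route: the
#' in-focus amplitude PSF is computed by the Debye integral on a laterally
#' oversampled grid, Fourier transformed to the amplitude transfer function,
#' multiplied by the non-paraxial defocus factor for each z offset,
#' transformed back, and squared. Each fine-grid slice is block-averaged
#' (`oversample^2` sub-pixels per sensor pixel) to model pixel integration,
#' and finally every xy-slice is normalized to sum to one.
#'
#' @param params An [optical_params()] object.
#' @param shape Integer vector `(nz, ny, nx)`.
#' @param z_offsets_nm Axial slice positions (nm); default
#'   `(i - nz %/% 2) * dz_nm` for `i = 0, ..., nz-1` (centered focal plane).
#' @return A slice-normalized [psf_stack()].
#' @examples
#' op <- optical_params(1.4, 1.51, 525, 65, 150, oversample = 2)
#' psf <- simulate_psf(op, c(5, 32, 32))
#' apply(psf$values, 1, sum)  # all ~1
#' @export
simulate_psf <- function(params, shape, z_offsets_nm = NULL) {
  stopifnot(inherits(params, "optical_params"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three positive integers (nz, ny, nx)", call. = FALSE)
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  if (is.null(z_offsets_nm))
    z_offsets_nm <- (seq_len(nz) - 1L - nz %/% 2L) * params$dz_nm
  if (length(z_offsets_nm) != nz)
    stop("length(z_offsets_nm) must equal shape[1]", call. = FALSE)

  os <- params$oversample
  dfine <- params$dxy_nm / os
  nyf <- ny * os; nxf <- nx * os
  # the fine grid must resolve the pupil: Nyquist above the band limit NA/lambda
  if (1 / (2 * dfine) <= params$na / params$wavelength_nm)
    stop("lateral sampling too coarse for the pupil support; increase 'oversample'",
         call. = FALSE)
  if (min(nyf, nxf) < 4L)
    stop("'shape' too small to contain the oversampled pupil support", call. = FALSE)

  # fine-grid coordinates chosen so each sensor pixel averages `os` subsamples
  # centered on the pixel center (pixel-integration model)
  ccy <- (center_index(ny) - 1L) * os + (os + 1) / 2
  ccx <- (center_index(nx) - 1L) * os + (os + 1) / 2
  ycoord <- (seq_len(nyf) - ccy) * dfine
  xcoord <- (seq_len(nxf) - ccx) * dfine
  r <- sqrt(outer(ycoord^2, xcoord^2, `+`))

  # Debye integral evaluated on a dense radial table, then spline-interpolated
  # onto the 2D grid (the field is smooth on the scale lambda/NA >> table step).
  rmax <- max(r)
  step <- min(dfine / 2, params$wavelength_nm / (params$na * 16))
  rtab <- seq(0, rmax + step, by = step)
  ftab <- apsf_infocus(params, rtab)
  apsf <- matrix(stats::spline(rtab, ftab, xout = as.numeric(r))$y, nyf, nxf)

  atf <- atf_from_apsf(apsf, d_nm = dfine)
  scale_f <- params$wavelength_nm / params$na   # cycles/nm -> normalized pupil
  u <- atf$fu * scale_f
  v <- atf$fv * scale_f
  u2v2 <- outer(u^2, v^2, `+`)
  H <- atf$values
  H[u2v2 > 1] <- 0 + 0i                          # confine to the pupil disk

  vals <- array(0, c(nz, ny, nx))
  rad <- params$k^2 - (params$na / params$wavelength_nm)^2 * u2v2
  kz <- sqrt(pmax(rad, 0))
  kz[rad < 0] <- 0
  for (iz in seq_len(nz)) {
    D <- exp(-1i * 2 * pi * z_offsets_nm[iz] * kz)
    D[rad < 0] <- 0 + 0i
    field <- stats::fft(H * D)                   # back to the image plane
    inten <- Re(field * Conj(field))
    inten <- inten[unshift_order(nyf), unshift_order(nxf)]  # center the peak
    # bin os x os blocks by averaging down to the sensor pitch
    if (os > 1L) {
      dim(inten) <- c(os, ny, os, nx)
      s <- colSums(inten, dims = 1L)             # (ny, os, nx)
      inten <- colSums(aperm(s, c(2L, 1L, 3L)), dims = 1L) / os^2
    }
    vals[iz, , ] <- inten
  }
  normalize_psf(psf_stack(vals, z_offsets_nm, params$dxy_nm, params$dz_nm))
}
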