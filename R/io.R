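#' Focal stack container
#'
#' A 3D fluorescence intensity volume with a unit tag and voxel geometry.
#' Values are stored z-major: `dim(values) = c(nz, ny, nx)`, with
#' `values[k, , ]` the k-th focal plane.
#'
#' @param values Numeric 3D array `(nz, ny, nx)` (a matrix is treated as a
#'   single slice).
#' @param unit `"DN"` (raw camera digital units) or `"photoelectrons"`.
#' @param dxy_nm,dz_nm Optional voxel pitches (nm).
#' @return An object of class `focal_stack`.
#' @export
focal_stack <- function(values, unit = c("DN", "photoelectrons"),
                        dxy_nm = NULL, dz_nm = NULL) {
  unit <- match.arg(unit)
  values <- as_volume(values, "values")
  structure(list(values = values, unit = unit,
                 dxy_nm = if (is.null(dxy_nm)) NA_real_ else dxy_nm,
                 dz_nm = if (is.null(dz_nm)) NA_real_ else dz_nm),
            class = "focal_stack")
}

#' @export
print.focal_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Focal stack: %d x %d x %d (z,y,x) in %s", d[1L], d[2L], d[3L], x$unit))
  if (is.finite(x$dxy_nm)) cat(sprintf(", pitch %g/%g nm", x$dxy_nm, x$dz_nm))
  cat(sprintf(", range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.focal_stack <- function(x) dim(x$values)

sidecar_path <- function(path) paste0(path, ".json")

#' Write a focal stack (or PSF) as a multi-page 32-bit float TIFF
#'
#' One TIFF page per z-slice, plus a JSON sidecar (`<path>.json`) recording
#' voxel geometry, unit, and the intensity scale. TIFF float storage here is
#' restricted to `[0, 1]`, so values are divided by a recorded `scale` (the
#' maximum absolute value) before writing and multiplied back on read; the
#' round trip is exact to 32-bit float precision.
#'
#' @param stack A [focal_stack()] or [psf_stack()] (or 3D array).
#' @param path Output TIFF path.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = list()) {
  meta <- list(axes = "zyx")
  if (inherits(stack, "psf_stack")) {
    meta$kind <- "psf"; meta$normalized <- stack$normalized
    meta$dxy_nm <- stack$dxy_nm; meta$dz_nm <- stack$dz_nm
    meta$z_offsets_nm <- stack$z_offsets_nm
    v <- stack$values
  } else if (inherits(stack, "focal_stack")) {
    meta$kind <- "focal_stack"; meta$unit <- stack$unit
    meta$dxy_nm <- stack$dxy_nm; meta$dz_nm <- stack$dz_nm
    v <- stack$values
  } else {
    meta$kind <- "volume"
    v <- as_volume(stack, "stack")
  }
  lo <- min(v)
  if (lo < 0) { meta$offset <- lo; v <- v - lo } else meta$offset <- 0
  scale <- max(v, 1e-300)
  meta$scale <- scale
  pages <- lapply(seq_len(dim(v)[1L]), function(iz) {
    m <- v[iz, , ]
    dim(m) <- dim(v)[2:3]
    m / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF focal stack (or PSF) written by this package
#'
#' Reads a grayscale multi-page TIFF into a z-major volume, applying the
#' sidecar's intensity scale and metadata when present. TIFFs from other
#' sources are read as-is (values as stored) with unit `"DN"`.
#'
#' @param path TIFF path.
#' @param as `"auto"` (use the sidecar's kind), `"focal_stack"` or `"psf"`.
#' @return A [focal_stack()] or [psf_stack()].
#' @export
read_stack <- function(path, as = c("auto", "focal_stack", "psf")) {
  as <- match.arg(as)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L) stop("non-grayscale TIFF page", call. = FALSE)
      p <- p[, , 1L]
    }
    p
  })
  d0 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) all(dim(p) == d0), TRUE)))
    stop("inconsistent page shapes in TIFF", call. = FALSE)
  v <- array(0, c(length(pages), d0))
  for (iz in seq_along(pages)) v[iz, , ] <- pages[[iz]]

  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(meta$scale)) v <- v * meta$scale
  if (!is.null(meta$offset)) v <- v + meta$offset
  kind <- if (as == "auto") {
    if (identical(meta$kind, "psf")) "psf" else "focal_stack"
  } else as
  dxy <- if (is.null(meta$dxy_nm)) NULL else meta$dxy_nm
  dz <- if (is.null(meta$dz_nm)) NULL else meta$dz_nm
  if (kind == "psf") {
    zo <- if (is.null(meta$z_offsets_nm))
      (seq_len(dim(v)[1L]) - 1L - dim(v)[1L] %/% 2L) * (if (is.null(dz)) 1 else dz)
    else meta$z_offsets_nm
    psf <- psf_stack(v, zo, dxy_nm = if (is.null(dxy)) NA_real_ else dxy,
                     dz_nm = if (is.null(dz)) NA_real_ else dz,
                     normalized = isTRUE(meta$normalized))
    if (!psf$normalized) psf <- normalize_psf(psf)
    psf
  } else {
    unit <- if (identical(meta$unit, "photoelectrons")) "photoelectrons" else "DN"
    focal_stack(v, unit = unit, dxy_nm = dxy, dz_nm = dz)
  }
}

#' Export a volume as an 8-bit visualization TIFF
#'
#' Linearly rescales so that a fraction `saturate` of pixels clip, split
#' equally between black and white (0 and 255), then writes 8-bit pages.
#'
#' @param stack A [focal_stack()] or 3D array.
#' @param path Output path.
#' @param saturate Total clipped fraction (default 0.01, i.e. 0.5% at each end).
#' @return `path`, invisibly.
#' @export
write_stack_8bit <- function(stack, path, saturate = 0.01) {
  v <- as_volume(stack, "stack")
  qs <- quantile(v, c(saturate / 2, 1 - saturate / 2), names = FALSE)
  if (qs[2L] <= qs[1L]) qs[2L] <- qs[1L] + 1e-12
  v <- pmin(pmax((v - qs[1L]) / (qs[2L] - qs[1L]), 0), 1)
  pages <- lapply(seq_len(dim(v)[1L]), function(iz) {
    m <- v[iz, , ]; dim(m) <- dim(v)[2:3]; m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
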