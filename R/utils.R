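# Internal helpers shared across modules.
#
# Array convention: volumes are numeric arrays with dim = c(nz, ny, nx)
# (z-major), voxel indices are 1-based, and the "center" voxel of an axis of
# length n is at index n %/% 2 + 1 (so that an even axis centers on the upper
# of the two middle samples, matching FFT frequency-origin conventions).

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

fft3 <- function(x) stats::fft(x)

ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

center_index <- function(n) n %/% 2L + 1L

# Index order that moves the center voxel to position 1 (circular shift),
# i.e. an ifftshift along one axis.
shift_order <- function(n) {
  c0 <- center_index(n)
  c(c0:n, seq_len(c0 - 1L))
}

# Inverse of shift_order (fftshift).
unshift_order <- function(n) order(shift_order(n))

# Circularly shift a 3D array so its center voxel lands at [1,1,1].
ifftshift3 <- function(x) {
  d <- dim(x)
  x[shift_order(d[1L]), shift_order(d[2L]), shift_order(d[3L]), drop = FALSE]
}

fftshift3 <- function(x) {
  d <- dim(x)
  x[unshift_order(d[1L]), unshift_order(d[2L]), unshift_order(d[3L]), drop = FALSE]
}

# DFT sample frequencies in cycles per sample (like numpy's fftfreq).
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, n - (n %/% 2L) - 1L), seq.int(-(n %/% 2L), -1L))
  k / (n * d)
}

# Replicate-pad a 3D array by the given per-axis (low, high) margins.
pad_replicate <- function(x, margins) {
  d <- dim(x)
  iz <- c(rep(1L, margins[1L, 1L]), seq_len(d[1L]), rep(d[1L], margins[1L, 2L]))
  iy <- c(rep(1L, margins[2L, 1L]), seq_len(d[2L]), rep(d[2L], margins[2L, 2L]))
  ix <- c(rep(1L, margins[3L, 1L]), seq_len(d[3L]), rep(d[3L], margins[3L, 2L]))
  x[iz, iy, ix, drop = FALSE]
}

# Zero-embed `x` centered in a (possibly larger) target shape, or crop it
# centered if the target is smaller along some axis.
embed_center <- function(x, shape) {
  d <- dim(x)
  out <- array(0, shape)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    cs <- center_index(d[a]); cd <- center_index(shape[a])
    lo <- min(cs - 1L, cd - 1L); hi <- min(d[a] - cs, shape[a] - cd)
    src[[a]] <- (cs - lo):(cs + hi)
    dst[[a]] <- (cd - lo):(cd + hi)
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- x[src[[1L]], src[[2L]], src[[3L]]]
  out
}

as_volume <- function(x, arg = "x") {
  if (inherits(x, "focal_stack")) x <- x$values
  if (is.matrix(x)) dim(x) <- c(1L, dim(x))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3D array (z, y, x)", arg), call. = FALSE)
  if (anyNA(x)) stop(sprintf("'%s' contains NA/NaN", arg), call. = FALSE)
  x
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) stop(sprintf("'%s' = %g out of range", name, x), call. = FALSE)
  invisible(x)
}
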