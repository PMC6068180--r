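# Difference operators use forward differences with replicate (Neumann)
# boundaries: the forward difference at the last index along an axis is 0,
# so affine intensity ramps have zero second difference everywhere in the
# interior and the penalties do not charge the volume edge artificially.
# Adjoints are exact transposes of these finite-dimensional linear maps.

# forward difference along axis a (1 = z, 2 = y, 3 = x), replicate boundary:
# (D x)_i = x_{i+1} - x_i for i < n, 0 at i = n
fdiff <- function(x, a) {
  out <- cpp_fdiff(x, dim(x), a - 1L)
  dim(out) <- dim(x)
  out
}

# exact adjoint of fdiff (transpose of the matrix above):
# (D^T y)_1 = -y_1 ; (D^T y)_i = y_{i-1} - y_i ; (D^T y)_n = y_{n-1}
fdiff_adj <- function(y, a) {
  out <- cpp_fdiff_adj(y, dim(y), a - 1L)
  dim(out) <- dim(y)
  out
}

#' Discrete Hessian operator
#'
#' Computes the six distinct second differences of a volume: pure terms
#' (`zz`, `yy`, `xx`) as twice-applied forward differences and mixed terms
#' (`zy`, `zx`, `yx`) as forward differences along both axes, with replicate
#' (Neumann) boundaries. The mixed components are scaled by `sqrt(2)` inside
#' the operator so that the plain Euclidean norm of the 6-vector at each
#' voxel equals the Frobenius norm of the symmetric 3x3 Hessian matrix
#' (which counts off-diagonal terms twice).
#'
#' @param x 3D array on the reconstruction grid.
#' @return An object of class `hessian_field`: a list of six arrays named
#'   `zz`, `yy`, `xx`, `zy`, `zx`, `yx`.
#' @seealso [hessian_adjoint()], [prox_frobenius_hessian()]
#' @export
hessian_apply <- function(x) {
  x <- as_volume(x, "x")
  s2 <- sqrt(2)
  dz <- fdiff(x, 1L); dy <- fdiff(x, 2L); dx <- fdiff(x, 3L)
  structure(list(zz = fdiff(dz, 1L), yy = fdiff(dy, 2L), xx = fdiff(dx, 3L),
                 zy = s2 * fdiff(dz, 2L), zx = s2 * fdiff(dz, 3L),
                 yx = s2 * fdiff(dy, 3L)),
            class = "hessian_field")
}

#' Adjoint of the discrete Hessian operator
#'
#' Exact transpose of [hessian_apply()] under the same component layout and
#' `sqrt(2)` mixed-term weighting, so that
#' `sum(hessian_apply(x) * Y) == sum(x * hessian_adjoint(Y))` to rounding.
#'
#' @param Y A `hessian_field` (list of six arrays as from [hessian_apply()]).
#' @return 3D array on the reconstruction grid.
#' @export
hessian_adjoint <- function(Y) {
  s2 <- sqrt(2)
  fdiff_adj(fdiff_adj(Y$zz, 1L), 1L) +
    fdiff_adj(fdiff_adj(Y$yy, 2L), 2L) +
    fdiff_adj(fdiff_adj(Y$xx, 3L), 3L) +
    s2 * fdiff_adj(fdiff_adj(Y$zy, 2L), 1L) +
    s2 * fdiff_adj(fdiff_adj(Y$zx, 3L), 1L) +
    s2 * fdiff_adj(fdiff_adj(Y$yx, 3L), 2L)
}

hessian_norms <- function(Y) {
  sqrt(Y$zz^2 + Y$yy^2 + Y$xx^2 + Y$zy^2 + Y$zx^2 + Y$yx^2)
}

#' Frobenius-Hessian penalty
#'
#' Sum over voxels of the Frobenius norm of the local Hessian matrix,
#' a convex, 1-homogeneous penalty that promotes piecewise-smooth intensity
#' (it vanishes on affine ramps, unlike total variation, so continuous
#' intensity changes across structures are not penalized).
#'
#' @param x 3D array.
#' @return Scalar penalty value.
#' @export
fh_penalty <- function(x) sum(hessian_norms(hessian_apply(x)))

#' Proximal operator of the Frobenius-Hessian norm (group soft-threshold)
#'
#' Per-voxel shrinkage of the 6-component Hessian field:
#' `Y_j * max(1 - tau / ||Y_j||_F, 0)`, with zero staying zero.
#'
#' @param Y A `hessian_field`.
#' @param tau Threshold (>= 0), typically `nu / rho`.
#' @return A `hessian_field`.
#' @export
prox_frobenius_hessian <- function(Y, tau) {
  check_scalar(tau, "tau", 0, Inf)
  nrm <- hessian_norms(Y)
  scale <- ifelse(nrm > tau, 1 - tau / pmax(nrm, .Machine$double.xmin), 0)
  structure(lapply(Y, function(comp) comp * scale), class = "hessian_field")
}

#' Forward-difference gradient and its adjoint
#'
#' Three-component forward-difference gradient with replicate boundaries,
#' used by the isotropic 3D total-variation regularizer.
#'
#' @param x 3D array.
#' @return `grad_apply`: list of arrays `z`, `y`, `x`; `grad_adjoint`: array.
#' @export
grad_apply <- function(x) {
  x <- as_volume(x, "x")
  list(z = fdiff(x, 1L), y = fdiff(x, 2L), x = fdiff(x, 3L))
}

#' @rdname grad_apply
#' @param G List of three gradient component arrays.
#' @export
grad_adjoint <- function(G) {
  fdiff_adj(G$z, 1L) + fdiff_adj(G$y, 2L) + fdiff_adj(G$x, 3L)
}

#' Isotropic 3D total variation penalty
#'
#' @param x 3D array.
#' @return Scalar: sum over voxels of the Euclidean norm of the gradient.
#' @export
tv_penalty <- function(x) {
  G <- grad_apply(x)
  sum(sqrt(G$z^2 + G$y^2 + G$x^2))
}

#' Group soft-threshold of a gradient field (isotropic TV prox)
#'
#' @param G List of three gradient component arrays.
#' @param tau Threshold (>= 0).
#' @return List of three shrunk component arrays.
#' @export
prox_tv_group <- function(G, tau) {
  check_scalar(tau, "tau", 0, Inf)
  nrm <- sqrt(G$z^2 + G$y^2 + G$x^2)
  scale <- ifelse(nrm > tau, 1 - tau / pmax(nrm, .Machine$double.xmin), 0)
  lapply(G, function(comp) comp * scale)
}

#' Soft-threshold (lasso prox)
#'
#' @param u Numeric array or vector.
#' @param tau Threshold (>= 0).
#' @return `sign(u) * max(|u| - tau, 0)`, same shape as `u`.
#' @export
prox_l1 <- function(u, tau) {
  check_scalar(tau, "tau", 0, Inf)
  sign(u) * pmax(abs(u) - tau, 0)
}

#' 7-point discrete Laplacian
#'
#' Second differences summed over the three axes (replicate boundaries);
#' used by the squared-Laplacian comparison regularizer.
#'
#' @param x 3D array.
#' @return 3D array.
#' @export
laplacian_apply <- function(x) {
  x <- as_volume(x, "x")
  fdiff(fdiff(x, 1L), 1L) + fdiff(fdiff(x, 2L), 2L) + fdiff(fdiff(x, 3L), 3L)
}

#' Regularization penalty value
#'
#' Evaluates `nu * R(x)` for the chosen regularizer: `fh` (Frobenius-Hessian
#' norm), `tv` (isotropic total variation), `l1` (entrywise 1-norm), `l2`
#' (squared 2-norm, Tikhonov), `laplacian` (squared 2-norm of the Laplacian
#' filtered volume), or `none`.
#'
#' @param x 3D array.
#' @param regularizer One of `"none"`, `"l2"`, `"laplacian"`, `"l1"`, `"tv"`,
#'   `"fh"`.
#' @param nu Regularization weight (>= 0).
#' @return Scalar.
#' @export
penalty_value <- function(x, regularizer, nu) {
  if (nu == 0 || regularizer == "none") return(0)
  nu * switch(regularizer,
              l2 = sum(x^2),
              laplacian = sum(laplacian_apply(x)^2),
              l1 = sum(abs(x)),
              tv = tv_penalty(x),
              fh = fh_penalty(x),
              stop("unknown regularizer: ", regularizer, call. = FALSE))
}

# Periodic transfer functions |F(stencil)|^2 summed over stencil components,
# used to diagonalize the x-update normal equations in the Fourier domain.
# sin^2 terms: |F(forward diff)|^2 = 4 sin^2(pi f), |F(second diff)|^2 =
# 16 sin^4(pi f); mixed Hessian terms carry the factor 2 of the Frobenius
# double count.
transfer_sin2 <- function(shape) {
  lapply(shape, function(n) {
    f <- (seq_len(n) - 1L) / n
    4 * sin(pi * f)^2
  })
}

hessian_transfer <- function(shape) {
  s <- transfer_sin2(shape)  # per-axis 4 sin^2
  add_outer <- function(az, ay, ax) {
    o <- outer(outer(az, ay, `+`), ax, `+`)
    o
  }
  pure <- add_outer(s[[1L]]^2, s[[2L]]^2, s[[3L]]^2)
  mixed <- 2 * (outer(outer(s[[1L]], s[[2L]]), rep(1, shape[3L])) +
                  outer(outer(s[[1L]], rep(1, shape[2L])), s[[3L]]) +
                  outer(outer(rep(1, shape[1L]), s[[2L]]), s[[3L]]))
  pure + mixed
}

grad_transfer <- function(shape) {
  s <- transfer_sin2(shape)
  outer(outer(s[[1L]], rep(1, shape[2L])), rep(1, shape[3L])) +
    outer(outer(rep(1, shape[1L]), s[[2L]]), rep(1, shape[3L])) +
    outer(outer(rep(1, shape[1L]), rep(1, shape[2L])), s[[3L]])
}

laplacian_transfer_sq <- function(shape) {
  # F([1,-2,1]) = 2 cos(2 pi f) - 2 per axis, summed, then squared
  l <- lapply(shape, function(n) {
    f <- (seq_len(n) - 1L) / n
    2 * cos(2 * pi * f) - 2
  })
  tot <- outer(outer(l[[1L]], rep(1, shape[2L])), rep(1, shape[3L])) +
    outer(outer(rep(1, shape[1L]), l[[2L]]), rep(1, shape[3L])) +
    outer(outer(rep(1, shape[1L]), rep(1, shape[2L])), l[[3L]])
  tot^2
}
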