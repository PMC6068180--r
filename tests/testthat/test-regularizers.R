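# Hessian / gradient operators, penalties and proximal maps.

test_that("Hessian components reproduce textbook second differences", {
  d <- c(8, 8, 8)
  x <- array(0, d)
  x[] <- slice.index(x, 3)^2          # quadratic along x
  H <- hessian_apply(x)
  expect_equal(H$xx[4, 4, 3], 2)      # interior second difference
  expect_equal(max(abs(H$yy)), 0)
  expect_equal(max(abs(H$zz)), 0)
  expect_equal(max(abs(H$zy)), 0)
  # affine volumes: all six components vanish on interior voxels
  aff <- 2 * slice.index(x, 1) - 3 * slice.index(x, 2) + 0.5 * slice.index(x, 3) + 7
  Ha <- hessian_apply(aff)
  interior <- 2:6
  for (comp in unclass(Ha))
    expect_equal(max(abs(comp[interior, interior, interior])), 0)
})

test_that("hessian_adjoint is the exact transpose of hessian_apply", {
  d <- c(8, 8, 8)
  set.seed(21)
  for (i in 1:5) {
    x <- array(rnorm(prod(d)), d)
    Y <- random_hessian_field(d, seed = 100 + i)
    lhs <- sum(mapply(function(a, b) sum(a * b), unclass(hessian_apply(x)), unclass(Y)))
    rhs <- sum(x * hessian_adjoint(Y))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1), 1e-10)
  }
  zero <- random_hessian_field(d)
  for (k in seq_along(zero)) zero[[k]][] <- 0
  expect_equal(hessian_adjoint(zero), array(0, d))
})

test_that("H^T H of a delta equals the autocorrelation stencil of the filters", {
  # direct convolution oracle: build the 9^3 matrix column for a centered
  # delta by applying the operators entrywise
  d <- c(9, 9, 9)
  delta <- array(0, d); delta[5, 5, 5] <- 1
  hth <- hessian_adjoint(hessian_apply(delta))
  # oracle: H^T H delta = sum over component filters of their discrete
  # autocorrelation, centered on the delta (the delta sits far enough from
  # the boundary that replicate and pure convolution agree)
  second <- function(axis) {
    f <- array(0, c(5, 5, 5)); idx <- c(3, 3, 3)
    for (o in 0:2) { j <- idx; j[axis] <- 3 + o
      f[j[1], j[2], j[3]] <- c(1, -2, 1)[o + 1] }
    f
  }
  mixed <- function(axes) {
    f <- array(0, c(5, 5, 5))
    for (o1 in 0:1) for (o2 in 0:1) {
      j <- c(3, 3, 3); j[axes[1]] <- 3 + o1; j[axes[2]] <- 3 + o2
      f[j[1], j[2], j[3]] <- (-1)^(1 - o1 + 1 - o2) * sqrt(2)
    }
    f
  }
  acor <- array(0, c(9, 9, 9))
  for (f in list(second(1), second(2), second(3),
                 mixed(c(1, 2)), mixed(c(1, 3)), mixed(c(2, 3)))) {
    # autocorrelation of f, centered at (5,5,5)
    sup <- which(f != 0, arr.ind = TRUE)
    for (a in seq_len(nrow(sup))) for (b in seq_len(nrow(sup))) {
      off <- sup[a, ] - sup[b, ]
      pos <- c(5, 5, 5) + off
      acor[pos[1], pos[2], pos[3]] <- acor[pos[1], pos[2], pos[3]] +
        f[sup[a, 1], sup[a, 2], sup[a, 3]] * f[sup[b, 1], sup[b, 2], sup[b, 3]]
    }
  }
  expect_equal(hth, acor)
})

test_that("group soft-thresholds shrink exactly as scalars predict", {
  d <- c(2, 2, 2)
  Y <- random_hessian_field(d)
  for (k in seq_along(Y)) Y[[k]][] <- 0
  Y$zz[1, 1, 1] <- 3
  out <- prox_frobenius_hessian(Y, 1)
  expect_equal(out$zz[1, 1, 1], 2)
  expect_equal(sum(abs(unlist(unclass(out)))), 2)   # all else stays 0
  # below-threshold voxels collapse to zero
  Y$zz[1, 1, 1] <- 0.9
  expect_equal(sum(abs(unlist(unclass(prox_frobenius_hessian(Y, 1))))), 0)
  # zero threshold is the identity
  Yr <- random_hessian_field(d, seed = 5)
  expect_equal(unclass(prox_frobenius_hessian(Yr, 0)), unclass(Yr))
  # TV group shrinkage on a (3,4,0) gradient vector
  G <- list(z = array(3, c(1, 1, 1)), y = array(4, c(1, 1, 1)),
            x = array(0, c(1, 1, 1)))
  expect_equal(unlist(prox_tv_group(G, 5)), c(z = 0, y = 0, x = 0))
  expect_equal(unlist(prox_tv_group(G, 2.5)), c(z = 1.5, y = 2, x = 0))
  # scalar soft threshold
  expect_equal(prox_l1(0.5, 1), 0)
  expect_equal(prox_l1(3, 1), 2)
  expect_equal(prox_l1(-3, 1), -2)
})

test_that("group prox solves its proximal problem (1-D numeric oracle)", {
  # single-voxel FH prox vs numeric minimization over the ray through Y
  Y <- random_hessian_field(c(1, 1, 1), seed = 9)
  nrm <- sqrt(sum(unlist(unclass(Y))^2))
  tau <- 0.6 * nrm
  out <- prox_frobenius_hessian(Y, tau)
  f <- function(t) tau * abs(t) * nrm + 0.5 * sum((t * unlist(unclass(Y)) - unlist(unclass(Y)))^2)
  tstar <- optimize(f, c(0, 1), tol = 1e-12)$minimum
  expect_equal(unlist(unclass(out)), tstar * unlist(unclass(Y)), tolerance = 1e-5)
})

test_that("penalties are convex, 1-homogeneous, and affine-blind (FH only)", {
  set.seed(23)
  d <- c(6, 7, 5)
  for (i in 1:10) {
    x1 <- array(rnorm(prod(d)), d); x2 <- array(rnorm(prod(d)), d)
    t <- runif(1)
    for (reg in c("fh", "tv", "l1", "l2", "laplacian")) {
      p <- function(x) penalty_value(x, reg, 1)
      expect_lte(p(t * x1 + (1 - t) * x2), t * p(x1) + (1 - t) * p(x2) + 1e-9)
    }
    for (reg in c("fh", "tv", "l1"))
      expect_equal(penalty_value(3 * x1, reg, 1), 3 * penalty_value(x1, reg, 1),
                   tolerance = 1e-12)
  }
  # adding an affine ramp leaves the interior FH energy unchanged, but not TV
  x <- array(rnorm(prod(d)), d)
  ramp <- 1.3 * slice.index(x, 2) + 0.7 * slice.index(x, 3)
  interior_energy <- function(x) {
    H <- hessian_apply(x)
    nrm <- fhdeconv:::hessian_norms(H)
    sum(nrm[2:(d[1] - 2), 2:(d[2] - 2), 2:(d[3] - 2)])
  }
  expect_equal(interior_energy(x + ramp), interior_energy(x), tolerance = 1e-10)
  expect_gt(abs(tv_penalty(x + ramp) - tv_penalty(x)), 1)
  expect_equal(tv_penalty(array(4, d)), 0)
})

test_that("periodic transfer functions match their operators on the torus", {
  # |F(D^T D)| for the periodic version of each stencil: compare the
  # quadratic form x^T (H^T H) x against sum T |X|^2 for periodic signals
  d <- c(8, 8, 8)
  TH <- fhdeconv:::hessian_transfer(d)
  expect_equal(TH[1, 1, 1], 0)                       # DC is unpenalized
  expect_true(all(TH >= 0))
  # Nyquist along one axis: 16 sin^4(pi/2) = 16
  expect_equal(TH[5, 1, 1], 16)
  TG <- fhdeconv:::grad_transfer(d)
  expect_equal(TG[1, 1, 1], 0)
  expect_equal(TG[5, 1, 1], 4)
  TL <- fhdeconv:::laplacian_transfer_sq(d)
  expect_equal(TL[1, 1, 1], 0)
  expect_equal(TL[5, 1, 1], 16)                      # (-4)^2
})
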