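# FFT convolution operator and the ADMM deconvolution loop.

test_that("a centered delta convolves to the PSF itself", {
  psf <- toy_psf()
  x <- array(0, c(9, 32, 32)); x[5, 17, 17] <- 1
  Ax <- convolve_psf(x, psf)
  expect_equal(Ax, psf$values, tolerance = 1e-12)
})

test_that("FFT convolution matches a direct spatial-domain oracle", {
  set.seed(31)
  d <- c(4, 8, 8)
  x <- array(runif(prod(d)), d)
  psf <- normalize_psf(psf_stack(array(runif(3 * 5 * 5), c(3, 5, 5)),
                                 -1:1, 65, 150))
  Ax <- convolve_psf(x, psf)
  pv <- fhdeconv:::embed_center(psf$values, d)
  c0 <- vapply(as.integer(d), fhdeconv:::center_index, integer(1))
  bf <- array(0, d)
  for (az in 1:d[1]) for (ay in 1:d[2]) for (ax in 1:d[3]) {
    s <- 0
    for (bz in 1:d[1]) for (by in 1:d[2]) for (bx in 1:d[3]) {
      kz <- ((az - bz + c0[1] - 1) %% d[1]) + 1
      ky <- ((ay - by + c0[2] - 1) %% d[2]) + 1
      kx <- ((ax - bx + c0[3] - 1) %% d[3]) + 1
      s <- s + x[bz, by, bx] * pv[kz, ky, kx]
    }
    bf[az, ay, ax] <- s
  }
  expect_equal(Ax, bf, tolerance = 1e-8)
})

test_that("slice normalization makes every focal plane collect the full flux", {
  # emitters confined to one z-plane: every output slice sums to the total
  # photon count (each plane of a slice-normalized widefield PSF integrates
  # to one)
  psf <- toy_psf()
  x <- array(0, c(9, 32, 32))
  set.seed(32)
  x[5, , ] <- matrix(runif(32 * 32), 32, 32)
  Ax <- convolve_psf(x, psf)
  expect_equal(apply(Ax, 1, sum), rep(sum(x), 9), tolerance = 1e-8)
})

test_that("ADMM with Gaussian fidelity and Tikhonov matches the Wiener filter", {
  psf <- toy_psf()
  d <- c(9, 32, 32)
  zz <- ((1:32) - 16.5) / 6
  xt <- outer(outer(exp(-(((1:9) - 5) / 2.5)^2), exp(-zz^2)), exp(-zz^2)) * 50 + 5
  y <- convolve_psf(xt, psf)
  nu <- 0.01
  otf <- fhdeconv:::psf_otf(psf$values, d)
  wiener <- Re(fhdeconv:::ifft3(Conj(otf) * fhdeconv:::fft3(y) /
                                  (Re(otf * Conj(otf)) + 2 * nu)))
  res <- admm_deconvolve(y, psf,
                         cfg = solver_config(nu = nu, rho = 1, max_iter = 500,
                                             tol = 1e-10, margins = 0,
                                             fidelity = "gaussian",
                                             regularizer = "l2"))
  expect_lt(sqrt(sum((res$x - wiener)^2) / sum(wiener^2)), 1e-4)
})

test_that("with no regularizer the solver reaches the convex optimum", {
  psf <- toy_psf()
  zz <- ((1:32) - 16.5) / 6
  xt <- outer(outer(exp(-(((1:9) - 5) / 2.5)^2), exp(-zz^2)), exp(-zz^2)) + 0.1
  y <- convolve_psf(xt, psf)   # noiseless, truth strictly positive
  res <- admm_deconvolve(y, psf,
                         cfg = solver_config(nu = 0, rho = 1, max_iter = 800,
                                             tol = 1e-13, margins = 0,
                                             fidelity = "gaussian",
                                             regularizer = "none"))
  obj <- function(x) 0.5 * sum((convolve_psf(x, psf) - y)^2)
  expect_lte(obj(res$x), obj(xt) + 1e-6)
})

test_that("solver is deterministic and honors the stopping rule", {
  sim <- small_blob_sim()
  cfg <- solver_config(nu = 0.1, margins = c(4, 6, 6))
  r1 <- admm_deconvolve(sim$noisy, sim$psf, noise = study_noise(), cfg = cfg)
  r2 <- admm_deconvolve(sim$noisy, sim$psf, noise = study_noise(), cfg = cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$x, r2$x)
  # stopping rule: either the relative change dropped below tol, or the
  # iteration cap was reached exactly
  expect_equal(nrow(r1$history), r1$iterations)
  if (r1$converged) {
    expect_lt(tail(r1$history$rel_change, 1), cfg$tol)
    expect_true(all(head(r1$history$rel_change, -1)[-1] >= cfg$tol))
  } else {
    expect_equal(r1$iterations, cfg$max_iter)
  }
  expect_true(all(r1$x >= 0))
  expect_equal(dim(r1$x_cropped), dim(sim$noisy$values))
  # iteration cap respected exactly
  r3 <- admm_deconvolve(sim$noisy, sim$psf, noise = study_noise(),
                        cfg = solver_config(nu = 0.1, margins = c(4, 6, 6),
                                            max_iter = 7, tol = 1e-12))
  expect_equal(r3$iterations, 7L)
  expect_false(r3$converged)
})

test_that("objective decreases over windows and residuals fall on a bead", {
  spec <- phantom_spec("hollow_shell", c(16, 48, 48), peak_photoelectrons = 50,
                       shell_diameter_nm = 2400, shell_thickness_nm = 300)
  truth <- make_phantom(spec)
  op <- study_optics()
  psf <- simulate_psf(op, c(16, 48, 48))
  sim <- simulate_focal_stack(truth, op, study_noise(), seed = 3, psf = psf)
  res <- admm_deconvolve(sim$noisy, psf, noise = study_noise(),
                         cfg = solver_config(nu = 0.1, margins = c(4, 8, 8),
                                             max_iter = 150, tol = 1e-12))
  obj <- res$history$objective
  # windowed monotonicity: each 10-iteration window improves on the last
  w <- sapply(split(obj, (seq_along(obj) - 1) %/% 10), min)
  expect_true(all(diff(w) < 1e-5 * abs(w[-length(w)])))
  # residual norms collapse over the run (exact KKT residuals need far more
  # iterations than the stopping rule allows; the decay is the invariant)
  expect_lt(tail(res$history$primal_residual, 1),
            0.02 * max(res$history$primal_residual))
  expect_lt(tail(res$history$dual_residual, 1),
            0.02 * max(res$history$dual_residual))
})

test_that("degenerate measurements are handled", {
  psf <- toy_psf()
  expect_warning(res <- admm_deconvolve(array(0, c(9, 32, 32)), psf),
                 "all-zero")
  expect_equal(max(res$x), 0)
  bad <- array(1, c(9, 32, 32)); bad[1] <- NaN
  expect_error(admm_deconvolve(bad, psf), "NA")
})

test_that("DN input with known noise equals normalized photoelectron input", {
  sim <- small_blob_sim()
  np <- study_noise()
  cfg <- solver_config(nu = 0.1, margins = c(4, 6, 6), max_iter = 20, tol = 1e-12)
  r_dn <- admm_deconvolve(sim$noisy, sim$psf, noise = np, cfg = cfg)
  ynorm <- focal_stack(sim$noisy$values / np$gain, "photoelectrons")
  r_pe <- admm_deconvolve(ynorm, sim$psf, noise = np, cfg = cfg)
  expect_equal(r_dn$x, r_pe$x, tolerance = 1e-12)
})
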