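# Mixed Poisson-Gaussian forward model, shifted-Poisson normalization, and
# on-the-fly gain / read-noise estimation.

test_that("simulated measurements have the moments of the mixed model", {
  n <- 1e5
  # pure Poisson (gain 1, no read noise)
  y1 <- simulate_measurement(array(5, c(1, 1, n)), noise_params(1, 0), seed = 1)
  se <- sqrt(5 / n)
  expect_lt(abs(mean(y1$values) - 5), 3 * se)
  # pure read noise at rate 0
  y0 <- simulate_measurement(array(0, c(1, 1, n)), noise_params(2, 3), seed = 2)
  expect_lt(abs(mean(y0$values)), 3 * sqrt(9 / n))
  expect_lt(abs(var(y0$values) - 9), 3 * 9 * sqrt(2 / n))
  # law of total variance: Var = gamma^2 theta + sigma^2
  for (theta in c(0.5, 5, 50)) {
    y <- simulate_measurement(array(theta, c(1, 1, n)), noise_params(2, 3), seed = 3)
    v_exp <- 4 * theta + 9
    expect_lt(abs(mean(y$values) - 2 * theta), 3 * sqrt(v_exp / n))
    expect_lt(abs(var(y$values) - v_exp), 3 * v_exp * sqrt(2 / n))
  }
  expect_error(simulate_measurement(array(-1, c(1, 1, 4)), noise_params(2, 3)),
               "non-negative")
})

test_that("fixed seeds reproduce draws and restore the RNG state", {
  cl <- array(3, c(2, 4, 4))
  np <- study_noise()
  set.seed(99); before <- rnorm(1)
  a <- simulate_measurement(cl, np, seed = 7)
  b <- simulate_measurement(cl, np, seed = 7)
  expect_identical(a$values, b$values)
  set.seed(99)
  a2 <- simulate_measurement(cl, np, seed = 7)
  expect_identical(rnorm(1), before)  # caller RNG stream untouched
})

test_that("normalization divides by the gain and tags photoelectron units", {
  y <- focal_stack(array(10, c(1, 2, 2)), "DN")
  out <- normalize_measurement(y, noise_params(2, 3))
  expect_equal(out$stack$values[1, 1, 1], 5)
  expect_equal(out$sigma_norm, 1.5)
  expect_equal(out$stack$unit, "photoelectrons")
  id <- normalize_measurement(y, noise_params(1, 0))
  expect_equal(id$stack$values, y$values)
})

test_that("shifted-Poisson surrogate matches the mixed model's moments", {
  # surrogate: P(theta + s) - s with s = sigma_norm^2, vs gamma-normalized
  # mixed draws; means and variances agree within 3 SE
  n <- 2e5
  for (theta in c(0.5, 5, 50)) for (sn in c(0.5, 1.5)) {
    set.seed(round(theta * 10 + sn * 100))
    surro <- rpois(n, theta + sn^2) - sn^2
    mixed <- rpois(n, theta) + rnorm(n, 0, sn)
    v <- theta + sn^2
    expect_lt(abs(mean(surro) - mean(mixed)), 4 * sqrt(2 * v / n))
    expect_lt(abs(var(surro) - var(mixed)), 4 * sqrt(2) * v * sqrt(2 / n) + 4 * sn^4 * sqrt(2/n))
  }
})

test_that("gain and read noise are recovered from a blob focal stack", {
  spec <- phantom_spec("blobs", c(10, 128, 128), peak_photoelectrons = 500,
                       n_blobs = 5)
  truth <- make_phantom(spec, seed = 3)
  np <- study_noise()
  psf <- simulate_psf(study_optics(), c(10, 128, 128))
  gains <- sigmas <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_focal_stack(truth, NULL, np, seed = s, psf = psf)
    est <- estimate_noise_params(sim$noisy)
    gains[s] <- est$gain; sigmas[s] <- est$read_sigma
    expect_equal(est$read_sigma_norm, est$read_sigma / est$gain)
  }
  expect_lt(median(abs(gains - 2) / 2), 0.05)   # parameter-recovery invariant
  expect_lt(abs(median(sigmas) - 3) / 3, 0.2)
})

test_that("degenerate and rescaled stacks behave as the affine law predicts", {
  set.seed(41)
  # pure Gaussian stack: slope ~ 0 (flagged), sigma^2 ~ 9
  g <- array(rnorm(6 * 96 * 96, 100, 3), c(6, 96, 96))
  est <- suppressWarnings(estimate_noise_params(g))
  expect_true(attr(est, "flagged"))
  expect_lt(abs(est$read_sigma^2 - 9) / 9, 0.2)
  # scaling y -> c y multiplies the gain and read sigma by c
  spec <- phantom_spec("blobs", c(6, 96, 96), peak_photoelectrons = 300, n_blobs = 4)
  sim <- simulate_focal_stack(make_phantom(spec, seed = 5), NULL, study_noise(),
                              seed = 13, psf = simulate_psf(study_optics(), c(6, 96, 96)))
  e1 <- estimate_noise_params(sim$noisy)
  e3 <- estimate_noise_params(focal_stack(sim$noisy$values * 3, "DN"))
  expect_equal(e3$gain / e1$gain, 3, tolerance = 0.02)
  expect_equal(e3$read_sigma / e1$read_sigma, 3, tolerance = 0.05)
})

test_that("dark- and flat-field correction is exact affine arithmetic", {
  d <- c(3, 8, 8)
  raw <- focal_stack(array(110, d), "DN")
  cal_id <- calibration_frames(matrix(0, 8, 8), matrix(1, 8, 8))
  expect_equal(dark_flat_correct(raw, cal_id)$values, raw$values)
  cal <- calibration_frames(matrix(10, 8, 8), matrix(2, 8, 8))
  expect_equal(dark_flat_correct(raw, cal)$values, array(50, d))
  dark_only <- focal_stack(array(10, d), "DN")
  expect_equal(dark_flat_correct(dark_only, cal)$values, array(0, d))
  # invertible given the calibration
  set.seed(8)
  raw2 <- focal_stack(array(rnorm(prod(d), 100, 5), d), "DN")
  corr <- dark_flat_correct(raw2, cal)
  back <- corr$values * 2 + 10
  expect_equal(back, raw2$values, tolerance = 1e-12)
  expect_error(dark_flat_correct(raw, calibration_frames(matrix(0, 4, 4),
                                                         matrix(1, 4, 4))),
               "shape")
})

test_that("flat fields are medians normalized to unit global median", {
  uni <- replicate(5, matrix(7, 6, 6), simplify = FALSE)
  dark0 <- matrix(0, 6, 6)
  expect_equal(build_flat_field(uni, dark0), matrix(1, 6, 6))
  # hot column x2 shows up as flat value ~2 on that column
  hot <- lapply(1:5, function(i) { m <- matrix(10, 6, 6); m[, 3] <- 20; m })
  ff <- build_flat_field(hot, dark0)
  expect_equal(median(ff), 1)
  expect_equal(ff[, 3], rep(2, 6))
  expect_error(build_flat_field(uni[1:2], dark0), "at least 3")
  neg <- lapply(1:3, function(i) matrix(c(0, rep(10, 35)), 6, 6))
  expect_error(build_flat_field(neg, matrix(5, 6, 6)), "non-positive")
})
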