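# Shared fixtures: small optical systems and simulated stacks used across
# test files. Everything is generated in code; no binary fixtures.

# default study optics (high-NA oil immersion, green emission)
study_optics <- function(oversample = 2L) {
  optical_params(na = 1.4, n_immersion = 1.51, wavelength_nm = 525,
                 dxy_nm = 65, dz_nm = 150, oversample = oversample)
}

study_noise <- function() noise_params(gain = 2, read_sigma = 3)

# small low-aperture system: coarse pitches keep PSF grids tiny
toy_optics <- function(oversample = 2L) {
  optical_params(na = 1.2, n_immersion = 1.51, wavelength_nm = 525,
                 dxy_nm = 130, dz_nm = 300, oversample = oversample)
}

# cached small PSF and blob stack used by several solver tests
local_sim_cache <- new.env(parent = emptyenv())

toy_psf <- function() {
  if (is.null(local_sim_cache$psf))
    local_sim_cache$psf <- simulate_psf(toy_optics(), c(9, 32, 32))
  local_sim_cache$psf
}

small_blob_sim <- function() {
  if (is.null(local_sim_cache$sim)) {
    spec <- phantom_spec("blobs", c(12, 48, 48), peak_photoelectrons = 100,
                         n_blobs = 4)
    truth <- make_phantom(spec, seed = 7)
    op <- study_optics()
    psf <- simulate_psf(op, c(12, 48, 48))
    local_sim_cache$sim <- c(simulate_focal_stack(truth, op, study_noise(),
                                                  seed = 11, psf = psf),
                             list(truth = truth))
  }
  local_sim_cache$sim
}

# random hessian-type field with named components
random_hessian_field <- function(d, seed = 1) {
  set.seed(seed)
  Y <- lapply(1:6, function(i) array(rnorm(prod(d)), d))
  names(Y) <- c("zz", "yy", "xx", "zy", "zx", "yx")
  class(Y) <- "hessian_field"
  Y
}
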