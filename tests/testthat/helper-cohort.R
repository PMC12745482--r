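# Shared synthetic-cohort fixtures, built in code at test time.

# Small-format spec for fast unit tests: 40 mm bone on a 96 x 96 grid.
tiny_spec <- function(n_bones = 2, ...) {
  cohort_spec(n_bones = n_bones, length_mm = 40, n_row = 96, n_col = 96, ...)
}

# Fully deterministic spec: no noise, no blur, no texture, uniform density d,
# no medullary cavity, flat axial profile.
uniform_spec <- function(d = 800, n_bones = 1, ...) {
  tiny_spec(n_bones = n_bones,
            cortical_density_mean = d, cortical_density_sd = 0,
            azimuthal_amplitude = 0, azimuthal_amplitude_sd = 0,
            radial_gradient = 0,
            endosteal_fraction = 0, endosteal_fraction_sd = 0,
            medullary_density_mean = d / 4, medullary_density_sd = 0,
            density_texture_sd = 0, hu_noise_sd = 0, blur_sigma = 0,
            axial_profile = cbind(c(0, 1), c(1, 1)), ...)
}

# Noise-free but heterogeneous spec (for exact calibration round-trips).
noisefree_spec <- function(...) {
  tiny_spec(density_texture_sd = 0, hu_noise_sd = 0, blur_sigma = 0, ...)
}

# The default study-scale cohort run (48 bones, full 128 x 128 format,
# seed 1), computed once and shared by every test that needs it.
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_run <- function() {
  if (is.null(.cohort_cache$run)) {
    .cohort_cache$run <- run_pipeline(cohort_spec(), trait_model(), seed = 1)
  }
  .cohort_cache$run
}
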