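# Shared fixtures: a low-noise generator for deterministic checks and a
# quick dataset builder.

noiseless_config <- function(...) {
  generator_config(scatter_sd_mult = 0, scatter_sd_add = 0, noise_sd = 0,
                   spad_noise_sd = 0, camera_noise_sd = 0, ...)
}

small_dataset <- function(n = 50, seed = 1L, ...) {
  generate_dataset(n, generator_config(seed = seed, ...))
}

# Expected noiseless baseline reflectance at a wavelength far from any
# absorber, recomputed from the configured baseline shape.
expected_baseline <- function(cfg, nm) {
  cfg$baseline_visible + (cfg$baseline_nir - cfg$baseline_visible) /
    (1 + exp(-(nm - cfg$red_edge_nm) / cfg$red_edge_width))
}
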