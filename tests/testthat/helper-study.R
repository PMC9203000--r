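# Shared fixtures, built once per test run.

EXT <- dos_extinction()
BASELINE <- baseline_medium()
FULL_INS <- instrument_spec()

# coarser CW grid for property-style tests (same physics, ~8x faster)
SMALL_INS <- instrument_spec(cw_wavelengths = seq(650, 1024, by = 4))

# full-instrument baseline data and fit, reused by the acceptance tests
BASE_DATA <- simulate_instrument(BASELINE, FULL_INS, EXT)
BASE_FIT <- dos_fit(BASE_DATA, EXT)

# draw a random homogeneous layer within the study's baseline ranges
random_layer <- function() {
  tissue_layer(total_hb = runif(1, 12, 120),
               sat = runif(1, 0.67, 0.83),
               water = runif(1, 0.05, 0.90),
               lipid = runif(1, 0.20, 0.70),
               musp830 = runif(1, 0.40, 0.60),
               b = runif(1, 0.1, 1.5))
}

layer_mua <- function(layer, wavelengths) {
  absorption_spectrum(layer$chromophores,
                      build_extinction_matrix(wavelengths, EXT))
}

layer_musp <- function(layer, wavelengths) {
  reduced_scattering_spectrum(layer$scattering, wavelengths)
}
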