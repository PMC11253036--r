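# Shared fixtures.  Expensive cell solves are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  v <- get0(key, envir = .fixture_cache)
  if (is.null(v)) {
    v <- force(expr)
    assign(key, v, envir = .fixture_cache)
  }
  v
}

default_params <- function(...) physiological_parameters(...)

# surrogate matrix spectrum at the tones of the pulsatile boundary
surrogate_spectrum <- function(K0 = 3.6e-9, tau = 0.05) {
  make_surrogate_spectrum(K0, tau, seq(0, 2, by = 0.5))
}

# Table-1 matrix conductivity spectrum from the 3D cell solve (coarse cell,
# memoised); tones 0 and 0.5 Hz
table1_matrix_spectrum <- function(resolution = 16) {
  memo(paste0("km_spec_", resolution), {
    pp <- default_params()
    cell <- build_vessel_cell(pp$r_c / pp$d, resolution = resolution)
    conductivity_spectrum(cell, cell_config_from_params(pp), c(0, 0.5),
                          K_ref = pp$d^2 / pp$mu)
  })
}

# Table-1 effective vessel conductivity (coarse cell, memoised)
table1_vessel_conductivity <- function(resolution = 32) {
  memo(paste0("kv_eff_", resolution), {
    effective_vessel_conductivity(default_params(),
                                  resolution = resolution)$K_v_eff
  })
}
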