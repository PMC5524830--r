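## Shared fixtures: group-mean parameter sets and small grids that keep the
## unit tests fast. Acceptance checks use the full-size study grid.

pd_params <- function(...) {
  tracer_params(d_eff = 2.744e-4, k_clear = 2.153e-4, ...)
}

control_params <- function(...) {
  tracer_params(d_eff = 2.023e-4, k_clear = 0.854e-4, ...)
}

small_grid <- function(n = 32L, voxel_size = 0.3,
                       center = c(-4.8, 1.9, -7.8)) {
  image_grid(n = n, voxel_size = voxel_size, center = center)
}

## Noise-free analytic concentrations on a grid, as a conc_series, bypassing
## the renderer (used to test the fit in isolation).
analytic_conc_series <- function(params, grid, times) {
  series <- render_image_series(params, grid = grid, times = times,
                                beta = 1, baseline = 0, noise_sd = 0)
  signal_to_concentration(series, baseline = 0, beta = 1)
}
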