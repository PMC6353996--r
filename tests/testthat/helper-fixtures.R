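# Small seeded fixtures shared across test files.

small_field_spec <- function(noise_model = "none", seed = 1L, ...) {
  cell_field_spec(
    image_shape = c(160L, 160L), n_cells = 6L, cell_axes_px = c(8, 12),
    noise_model = noise_model, seed = seed, ...
  )
}

small_coloc_spec <- function(co_occupancy = 0.5, noise_model = "poisson",
                             seed = 1L, ...) {
  coloc_field_spec(
    image_shape = c(192L, 192L), n_cells = 5L, co_occupancy = co_occupancy,
    noise_model = noise_model, seed = seed, ...
  )
}

fast_decay_spec <- function(..., n_bins = 1024L, n_photons = 2e5) {
  decay_spec(..., n_bins = n_bins, n_photons = n_photons)
}

# Two-pass textbook Pearson correlation, kept independent of pearson_r().
oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
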