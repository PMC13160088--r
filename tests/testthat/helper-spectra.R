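# Small fixtures shared across the suite. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# a short axis for cheap tests
tiny_axis <- function(step = 2) seq(700, 1700, by = step)

# a quiet generator configuration: no artifacts unless asked for
quiet_config <- function(..., step = 2) {
  defaults <- list(n_per_condition = 20, wavenumbers = tiny_axis(step),
                   donor_sd = 0, cell_sd = 0, hotspot_sd = 0, noise_sd = 0,
                   baseline_scale = 0, spike_rate = 0, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulate_config, args)
}

# hand-built spectra table: deterministic ramps
toy_spectra <- function(n = 3, axis = seq(700, 709)) {
  m <- outer(seq_len(n), seq_along(axis), function(i, j) i * 10 + j)
  new_spectra_tbl(
    tibble::tibble(spectrum_id = paste0("s", seq_len(n)),
                   donor_id = "D1", class_label = "TCELL",
                   time_min = NA_real_, batch_id = "B1"),
    m, axis)
}

# population z-score of a vector
pop_z <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))

expect_spectra_equal <- function(a, b) {
  expect_identical(spectra_matrix(a), spectra_matrix(b))
  ma <- as.data.frame(spectra_meta(a))
  mb <- as.data.frame(spectra_meta(b))
  attributes(ma) <- attributes(ma)[c("names", "row.names", "class")]
  attributes(mb) <- attributes(mb)[c("names", "row.names", "class")]
  expect_identical(ma, mb)
}
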