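test_that("despiking removes injected spikes and leaves clean channels alone", {
  # constant spectrum: unchanged, no spikes
  r <- spectracyte:::despike_vector(rep(5, 100))
  expect_identical(r$y, rep(5, 100))
  expect_length(r$spikes, 0)

  # one injected single-channel spike on a smooth noisy peak spectrum
  cfg <- quiet_config(noise_sd = 0.02, step = 1, seed = 11)
  set <- simulate_spectra(cfg, classes = "TCELL", donors = "D1")
  y <- spectra_matrix(set)[1, ]
  spiked <- y
  spiked[450] <- spiked[450] + 30 * max(y)
  r <- spectracyte:::despike_vector(spiked)
  expect_true(450 %in% r$spikes)
  expect_lt(abs(r$y[450] - y[450]), 2 * 0.02 * max(y) + 0.05 * max(y))
  untouched <- setdiff(seq_along(y), r$spikes)
  expect_identical(r$y[untouched], spiked[untouched])
})

test_that("false-flag rate on spike-free noisy spectra stays below 1%", {
  n_flag <- 0
  n_chan <- 0
  for (seed in 1:100) {
    cfg <- quiet_config(noise_sd = 0.05, hotspot_sd = 0.2,
                        baseline_scale = 2, n_per_condition = 1,
                        seed = seed)
    y <- spectra_matrix(simulate_spectra(cfg, "TCELL", "D1"))[1, ]
    r <- spectracyte:::despike_vector(y)
    n_flag <- n_flag + length(r$spikes)
    n_chan <- n_chan + length(y)
  }
  expect_lt(n_flag / n_chan, 0.01)
})

test_that("despiking a despiked spectrum flags nothing new", {
  again <- 0
  for (seed in 1:50) {
    cfg <- quiet_config(noise_sd = 0.05, spike_rate = 1, seed = seed,
                        n_per_condition = 1)
    y <- spectra_matrix(simulate_spectra(cfg, "TCELL", "D1"))[1, ]
    r1 <- spectracyte:::despike_vector(y)
    r2 <- spectracyte:::despike_vector(r1$y)
    if (length(r2$spikes) > 0) again <- again + 1
  }
  expect_lte(again, 1) # >= 98% of seeds clean on the second pass
})

test_that("wavelet transform reconstructs exactly and denoising contracts noise", {
  set.seed(1)
  x <- rnorm(512)
  dec <- spectracyte:::dwt_multi(x, 5)
  expect_equal(spectracyte:::idwt_multi(dec), x, tolerance = 1e-10)

  # zero in, zero out
  expect_equal(spectracyte:::denoise_vector(rep(0, 300)), rep(0, 300))

  # pure noise: variance shrinks in most draws
  shrunk <- 0
  for (seed in 1:50) {
    set.seed(seed)
    y <- 5 + rnorm(400)
    if (var(spectracyte:::denoise_vector(y)) < var(y)) shrunk <- shrunk + 1
  }
  expect_gte(shrunk, 48)

  # noiseless peaks barely change
  cfg <- quiet_config(step = 1)
  y <- spectra_matrix(simulate_spectra(cfg, "TCELL", "D1"))[1, ]
  expect_lt(max(abs(spectracyte:::denoise_vector(y) - y)), 0.01 * max(y))

  # too-short input returns unchanged with a warning
  expect_warning(out <- spectracyte:::denoise_vector(1:5), "unchanged")
  expect_identical(out, 1:5)
})

test_that("airPLS recovers smooth baselines under peaks", {
  # input equal to a smooth quartic: corrected residual is tiny
  u <- seq(-1, 1, length.out = 800)
  b <- 5 + u + 0.5 * u^2 + 0.2 * u^4
  r <- airpls_baseline(b)
  expect_lt(max(abs(r$corrected)), 0.01 * diff(range(b)))

  # zero spectrum is a fixed point
  r0 <- airpls_baseline(rep(0, 500))
  expect_equal(r0$baseline, rep(0, 500))
  expect_equal(r0$corrected, rep(0, 500))

  # synthetic peaks + known baseline: RMSE off the peak supports < 5% of range
  cfg <- quiet_config(baseline_scale = 3, step = 1, seed = 2)
  set <- simulate_spectra(cfg, "TCELL", "D1")
  tr <- sim_truth(set)
  y <- spectra_matrix(set)[1, ]
  r <- airpls_baseline(y)
  truth <- tr$baseline[1, ]
  on_peak <- rowSums(vapply(seq_len(nrow(cfg$bands)), function(k) {
    abs(tr$wavenumbers - cfg$bands$center_cm1[k]) <= 20
  }, logical(length(y)))) > 0
  rmse <- sqrt(mean((r$baseline[!on_peak] - truth[!on_peak])^2))
  expect_lt(rmse, 0.05 * diff(range(truth)))

  # smoothness: second-difference energy does not exceed the input's
  d2 <- function(v) sum(diff(diff(v))^2)
  expect_lte(d2(r$baseline), d2(y))
})

test_that("z-score normalization is exact and affine-invariant", {
  set <- toy_spectra(n = 4, axis = seq(700, 899))
  z <- normalize_spectra(set)
  m <- spectra_matrix(z)
  expect_true(all(abs(rowMeans(m)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(m^2)) - 1) < 1e-9))

  # a*x + b (a > 0) gives the identical output; a < 0 negates it
  x <- spectra_matrix(set)
  aff <- set_spec <- set
  aff_m <- 3.7 * x + 11
  z2 <- normalize_spectra(spectracyte:::set_spectra_matrix(aff, aff_m))
  expect_equal(spectra_matrix(z2), m, tolerance = 1e-12)
  z3 <- normalize_spectra(spectracyte:::set_spectra_matrix(aff, -2 * x + 3))
  expect_equal(spectra_matrix(z3), -m, tolerance = 1e-12)

  # zero-variance spectrum errors with its id
  flat <- spectracyte:::set_spectra_matrix(set, matrix(1, 4, 200))
  expect_error(normalize_spectra(flat), "s1")
})

test_that("outlier screening works per batch with one-sided thresholds", {
  axis <- seq(700, 799)
  n <- 100
  m <- matrix(1, n, length(axis)) + matrix(rnorm(n * length(axis), 0, 0.01), n)
  m[7, ] <- m[7, ] * 10
  set <- new_spectra_tbl(
    tibble::tibble(spectrum_id = sprintf("s%03d", 1:n)), m, axis)
  kept <- exclude_outliers(set)
  expect_identical(attr(kept, "excluded")$spectrum_id, "s007")

  # identical spectra: nothing excluded
  same <- new_spectra_tbl(tibble::tibble(spectrum_id = sprintf("s%03d", 1:50)),
                          matrix(2, 50, length(axis)), axis)
  expect_equal(nrow(exclude_outliers(same)), 50)

  # batch-relative: the same spectrum is extreme in a quiet batch only
  m2 <- rbind(matrix(1, 49, length(axis)), matrix(5, 1, length(axis)),
              matrix(5, 49, length(axis)), matrix(5, 1, length(axis)))
  m2 <- m2 + matrix(rnorm(100 * length(axis), 0, 0.01), 100)
  set2 <- new_spectra_tbl(
    tibble::tibble(spectrum_id = sprintf("s%03d", 1:100),
                   batch_id = rep(c("A", "B"), each = 50)), m2, axis)
  kept2 <- exclude_outliers(set2)
  excl <- attr(kept2, "excluded")$spectrum_id
  expect_identical(excl, "s050")
})

test_that("full chain is invariant to per-spectrum positive scaling", {
  cfg <- quiet_config(noise_sd = 0.03, baseline_scale = 0, spike_rate = 0,
                      n_per_condition = 3, step = 1, seed = 8)
  set <- simulate_spectra(cfg, "TCELL", "D1")
  scaled <- spectracyte:::set_spectra_matrix(set, 4.2 * spectra_matrix(set))
  cfgp <- preprocess_config(outlier_sd = 1e6)
  a <- preprocess_spectra(set, cfgp)
  b <- preprocess_spectra(scaled, cfgp)
  expect_equal(spectra_matrix(a), spectra_matrix(b), tolerance = 1e-8)
})

test_that("the preprocessed output recovers the generative signal", {
  cfg <- simulate_config(n_per_condition = 40, seed = 13)
  set <- simulate_spectra(cfg, classes = c("CAR", "MOCK"), donors = "D1")
  tr <- sim_truth(set)
  clean <- preprocess_spectra(set)
  m <- spectra_matrix(clean)
  idx <- match(clean$spectrum_id, set$spectrum_id)
  cors <- vapply(seq_len(nrow(m)), function(i) {
    cor(m[i, ], pop_z(tr$signal[idx[i], ]))
  }, numeric(1))
  expect_gt(min(cors), 0.95)

  # class-mean contrast signs survive the full chain
  wn <- spec_wavenumbers(clean)
  diffm <- colMeans(m[clean$class_label == "CAR", , drop = FALSE]) -
    colMeans(m[clean$class_label == "MOCK", , drop = FALSE])
  expect_gt(diffm[wn == 1002], 0)
  expect_lt(diffm[wn == 728], 0)
})

test_that("empty sets pass through with an empty report", {
  set <- toy_spectra()[0, ]
  class(set) <- c("spectra_tbl", class(set))
  out <- preprocess_spectra(set)
  expect_equal(nrow(out), 0)
  expect_equal(preprocess_report(out)$n_excluded, 0L)
})
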