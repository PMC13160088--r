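# classifier tests run on a reduced axis and with tune_trials = 0 (default
# hyperparameters, boosting rounds still selected on the training split)
# to keep the suite fast; the protocol structure is identical at scale.
fast_protocol <- function(seed = 1L, ...) {
  train_protocol(tune_trials = 0L, max_boosting_rounds = 300L,
                 early_stopping_rounds = 50L, seed = seed, ...)
}

test_that("Savitzky-Golay derivative blocks match analytic derivatives", {
  axis <- seq(700, 899)
  ch <- seq_along(axis)
  # cubic in channel index: first derivative must be exact for polyorder 3
  y_cubic <- 1e-6 * ch^3 - 2e-4 * ch^2 + 0.05 * ch
  d_cubic <- 3e-6 * ch^2 - 4e-4 * ch + 0.05
  set <- new_spectra_tbl(tibble::tibble(spectrum_id = "s1"),
                         rbind(y_cubic), axis)
  f <- augment_derivatives(set)
  expect_equal(ncol(f$features), 3 * length(axis))
  interior <- 6:(length(axis) - 6)
  d1 <- f$features[1, paste0("d1_", axis)]
  expect_equal(unname(d1[interior]), d_cubic[interior], tolerance = 1e-6)

  # quadratic: second derivative constant
  y_quad <- 0.01 * ch^2
  setq <- new_spectra_tbl(tibble::tibble(spectrum_id = "s1"),
                          rbind(y_quad), axis)
  d2 <- augment_derivatives(setq)$features[1, paste0("d2_", axis)]
  expect_equal(unname(d2[interior]), rep(0.02, length(interior)),
               tolerance = 1e-6)

  # constant spectrum: derivative blocks all zero
  setc <- new_spectra_tbl(tibble::tibble(spectrum_id = "s1"),
                          matrix(3, 1, length(axis)), axis)
  fc <- augment_derivatives(setc)$features
  expect_true(all(abs(fc[1, -(1:length(axis))]) < 1e-10))

  expect_error(augment_derivatives(set, window = 999L), "window")
})

test_that("zero-effect data classifies at chance, large effects near-perfectly", {
  null_effects <- utils::modifyList(default_class_effects(),
                                    list(CAR = numeric(0), MOCK = numeric(0)))
  cfg <- quiet_config(n_per_condition = 60, noise_sd = 0.05, cell_sd = 0.1,
                      hotspot_sd = 0.2, class_effects = null_effects,
                      seed = 21)
  set <- simulate_spectra(cfg, c("CAR", "MOCK"), "D1")
  clean <- preprocess_spectra(set)
  rep0 <- train_classifier(augment_derivatives(clean), fast_protocol(7))
  n_cv <- length(rep0$train_ids)
  band <- qbinom(c(0.005, 0.995), n_cv, 0.5) / n_cv
  expect_gte(rep0$cv_accuracy, band[1])
  expect_lte(rep0$cv_accuracy, band[2])

  big_effects <- utils::modifyList(default_class_effects(),
                                   list(CAR = c(PROTEIN_AROMATIC = 1.5),
                                        MOCK = c(NUCLEIC_ACID = 1.5)))
  cfg2 <- quiet_config(n_per_condition = 60, noise_sd = 0.02, cell_sd = 0.05,
                       hotspot_sd = 0.2, class_effects = big_effects,
                       seed = 22)
  set2 <- simulate_spectra(cfg2, c("CAR", "MOCK"), "D1")
  rep1 <- train_classifier(augment_derivatives(preprocess_spectra(set2)),
                           fast_protocol(7))
  expect_gte(rep1$cv_accuracy, 0.95)

  # report invariants
  expect_true(all(abs(rowSums(rep1$confusion) - 1) < 1e-9))
  expect_gte(rep1$auc, 0)
  expect_lte(rep1$auc, 1)
})

test_that("accuracy grows with the programmed effect size", {
  accs <- vapply(c(0, 0.1, 0.2, 0.4), function(delta) {
    eff <- utils::modifyList(default_class_effects(),
                             list(CAR = c(PROTEIN_AROMATIC = 1 + delta),
                                  MOCK = c(NUCLEIC_ACID = 1 + delta)))
    cfg <- quiet_config(n_per_condition = 50, noise_sd = 0.05, cell_sd = 0.1,
                        hotspot_sd = 0.2, class_effects = eff, seed = 31)
    set <- simulate_spectra(cfg, c("CAR", "MOCK"), "D1")
    train_classifier(augment_derivatives(preprocess_spectra(set)),
                     fast_protocol(3))$cv_accuracy
  }, numeric(1))
  # monotone power up to small CV noise; the extremes must clearly order
  expect_gt(accs[4], accs[1] + 0.2)
  expect_true(all(diff(accs) > -0.1))
})

test_that("training is seeded-deterministic and ignores test labels", {
  cfg <- quiet_config(n_per_condition = 40, noise_sd = 0.05, cell_sd = 0.1,
                      seed = 12)
  set <- simulate_spectra(cfg, c("CAR", "MOCK"), "D1")
  feats <- augment_derivatives(preprocess_spectra(set))
  r1 <- train_classifier(feats, fast_protocol(5))
  r2 <- train_classifier(feats, fast_protocol(5))
  expect_identical(r1$cv_accuracy, r2$cv_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$auc, r2$auc)

  # corrupting the held-out spectra cannot change the training-split CV:
  # the test rows are untouched by tuning and CV by construction
  feats_noise <- feats
  test_rows <- match(r1$test_ids, feats$meta$spectrum_id)
  set.seed(99)
  feats_noise$features[test_rows, ] <-
    matrix(rnorm(length(test_rows) * ncol(feats$features)),
           length(test_rows))
  r3 <- train_classifier(feats_noise, fast_protocol(5))
  expect_identical(r3$cv_accuracy, r1$cv_accuracy)
  expect_identical(r3$confusion, r1$confusion)
})

test_that("multiclass training separates four synthetic cell types", {
  cfg <- quiet_config(n_per_condition = 60, noise_sd = 0.03, cell_sd = 0.05,
                      hotspot_sd = 0.2, seed = 17)
  set <- simulate_spectra(cfg, c("TCELL", "BCELL_PRIMARY", "BCELL_JEKO",
                                 "RBC"), "D1")
  clean <- preprocess_spectra(set)
  rep4 <- train_multiclass(augment_derivatives(clean), fast_protocol(2))
  expect_gte(rep4$cv_accuracy, 0.95)
  expect_equal(dim(rep4$confusion), c(4, 4))

  # shuffled labels drop to chance (99% multinomial band around 1/4)
  shuf <- clean
  set.seed(4)
  shuf$class_label <- sample(shuf$class_label)
  rep_null <- train_multiclass(augment_derivatives(shuf), fast_protocol(2))
  n_cv <- length(rep_null$train_ids)
  band <- qbinom(c(0.005, 0.995), n_cv, 0.25) / n_cv
  expect_gte(rep_null$cv_accuracy, band[1])
  expect_lte(rep_null$cv_accuracy, band[2])

  expect_error(train_multiclass(augment_derivatives(preprocess_spectra(
    simulate_spectra(quiet_config(n_per_condition = 25), c("CAR", "MOCK"),
                     "D1")))), "3 classes")
})

test_that("donor-dominant variance favors per-donor over pooled training", {
  eff <- utils::modifyList(default_class_effects(),
                           list(CAR = c(PROTEIN_AROMATIC = 1.15),
                                MOCK = c(NUCLEIC_ACID = 1.15)))
  cfg <- quiet_config(n_per_condition = 30, donor_sd = 0.6, cell_sd = 0.1,
                      noise_sd = 0.05, hotspot_sd = 0.2,
                      class_effects = eff, seed = 23)
  set <- simulate_spectra(cfg, c("CAR", "MOCK"), paste0("D", 1:6))
  clean <- preprocess_spectra(set)
  per_donor <- suppressWarnings(train_per_donor(clean, fast_protocol(3),
                                                n_boot = 100))
  pooled <- train_classifier(augment_derivatives(clean), fast_protocol(3))
  expect_gt(per_donor$mean_cv_accuracy, pooled$cv_accuracy)
  expect_length(per_donor$reports, 6)
  expect_equal(nrow(per_donor$roc_grid), 101)
  expect_true(all(per_donor$roc_grid$tpr_lo <= per_donor$roc_grid$tpr_hi))
})

test_that("importance mass concentrates in the only informative band", {
  # inject signal only at 1002 +/- 10 via a single-band catalog effect
  bands <- raman_bands()
  eff <- utils::modifyList(default_class_effects(),
                           list(CAR = numeric(0), MOCK = numeric(0)))
  cfg <- quiet_config(n_per_condition = 40, noise_sd = 0.03, cell_sd = 0.05,
                      hotspot_sd = 0.1, class_effects = eff, step = 1,
                      seed = 29)
  set <- simulate_spectra(cfg, c("CAR", "MOCK"), "D1")
  # add the discriminative bump at 1002 cm^-1 for CAR rows
  m <- spectra_matrix(set)
  wn <- spec_wavenumbers(set)
  bump <- 0.6 * exp(-((wn - 1002) / 6)^2)
  car_rows <- which(set$class_label == "CAR")
  m[car_rows, ] <- m[car_rows, ] + rep(bump, each = length(car_rows))
  set <- spectracyte:::set_spectra_matrix(set, m)
  clean <- preprocess_spectra(set)
  rep_i <- train_classifier(augment_derivatives(clean, augment = FALSE),
                            fast_protocol(2))
  prof <- importance_profile(list(rep_i))
  in_band <- prof$wavenumber >= 992 & prof$wavenumber <= 1012
  # compare sum-normalized mass (recompute from gain fractions)
  gain <- setNames(rep(0, length(wn)), paste0("i_", wn))
  gain[rep_i$importance$feature] <- rep_i$importance$gain
  expect_gt(sum(gain[in_band]) / sum(gain), 0.5)

  # augmented models are rejected
  rep_a <- train_classifier(augment_derivatives(clean), fast_protocol(2))
  expect_error(importance_profile(list(rep_a)), "non-augmented")
})

test_that("tidiers summarize classifier reports", {
  cfg <- quiet_config(n_per_condition = 30, noise_sd = 0.05, cell_sd = 0.1,
                      seed = 3)
  set <- simulate_spectra(cfg, c("CAR", "MOCK"), "D1")
  r <- train_classifier(augment_derivatives(preprocess_spectra(set)),
                        fast_protocol(1))
  td <- tidy(r)
  expect_equal(nrow(td), 10)
  gl <- glance(r)
  expect_equal(gl$cv_accuracy, r$cv_accuracy)
  expect_equal(gl$n_train + gl$n_test, nrow(set))
})
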