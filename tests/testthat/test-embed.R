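test_that("balanced subsampling equalizes key combinations deterministically", {
  cfg <- quiet_config(noise_sd = 0.05, n_per_condition = 10, seed = 2)
  big <- simulate_spectra(quiet_config(noise_sd = 0.05, n_per_condition = 25,
                                       seed = 3), "CAR", "D1")
  small <- simulate_spectra(cfg, c("CAR", "MOCK"), c("D1", "D2"))
  small <- small[!(small$class_label == "CAR" & small$donor_id == "D1"), ]
  big$spectrum_id <- paste0("big_", big$spectrum_id)
  x <- as_spectra_tbl(dplyr::bind_rows(tibble::as_tibble(big),
                                       tibble::as_tibble(small)))
  sub <- balanced_subsample(x, seed = 7)
  counts <- table(sub$class_label, sub$donor_id)
  expect_true(all(counts == min(table(x$class_label, x$donor_id))))

  # same seed reproduces; different seed keeps counts but changes members
  sub2 <- balanced_subsample(x, seed = 7)
  expect_identical(sub$spectrum_id, sub2$spectrum_id)
  sub3 <- balanced_subsample(x, seed = 8)
  expect_identical(dim(sub3), dim(sub))
  expect_false(identical(sub$spectrum_id, sub3$spectrum_id))

  # already balanced: identity up to order
  bal <- simulate_spectra(cfg, c("CAR", "MOCK"), "D1")
  expect_identical(sort(balanced_subsample(bal)$spectrum_id),
                   sort(bal$spectrum_id))
})

test_that("embedding separates well-separated classes and respects seeding", {
  eff <- utils::modifyList(default_class_effects(),
                           list(CAR = c(PROTEIN_AROMATIC = 1.6),
                                MOCK = c(NUCLEIC_ACID = 1.6)))
  cfg <- quiet_config(n_per_condition = 60, noise_sd = 0.03, cell_sd = 0.05,
                      class_effects = eff, seed = 5)
  set <- preprocess_spectra(simulate_spectra(cfg, c("CAR", "MOCK"), "D1"))
  co <- embed_spectra(set, embed_config(seed = 1))
  expect_equal(nrow(co), nrow(set))

  sil <- function(coords, lab) {
    d <- as.matrix(dist(cbind(coords$umap1, coords$umap2)))
    mean(vapply(seq_len(nrow(d)), function(i) {
      a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
      b <- mean(d[i, lab != lab[i]])
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  expect_gt(sil(co, set$class_label), 0.25)

  co2 <- embed_spectra(set, embed_config(seed = 1))
  expect_identical(co, co2)

  # a single blob does not split under random labels
  cfg0 <- quiet_config(n_per_condition = 80, noise_sd = 0.05, cell_sd = 0.05,
                       class_effects = utils::modifyList(
                         default_class_effects(), list(CAR = numeric(0))),
                       seed = 6)
  blob <- preprocess_spectra(simulate_spectra(cfg0, "CAR", "D1"))
  cob <- embed_spectra(blob, embed_config(seed = 2))
  set.seed(3)
  rand_lab <- sample(rep(c("A", "B"), 40))
  expect_lt(sil(cob, rand_lab), 0.1)

  expect_error(embed_spectra(set[1:10, ]), "n_neighbors")
})

test_that("time bins follow the printed half-open scheme", {
  b <- time_bins()
  expect_identical(b$starts, c(15, 25, 35, 45, 55, 75))
  expect_equal(assign_time_bin(30), 25)
  expect_equal(assign_time_bin(55), 55)   # half-open: 55 starts its own bin
  expect_equal(assign_time_bin(25), 25)
  expect_equal(assign_time_bin(95), 75)   # last bin closed at 95
  expect_equal(assign_time_bin(74.999), 55)
  expect_true(is.na(assign_time_bin(96)))
  expect_true(is.na(assign_time_bin(10)))
})

test_that("time-binned centroids match brute-force means and SEs", {
  set.seed(1)
  co <- tibble::tibble(
    spectrum_id = sprintf("s%02d", 1:40), donor_id = "D1",
    class_label = rep(c("CAR", "UNSTIM"), 20),
    time_min = runif(40, 15, 95), batch_id = "B1",
    umap1 = rnorm(40), umap2 = rnorm(40))
  cen <- time_bin_centroids(co)
  for (i in seq_len(nrow(cen))) {
    rows <- co$class_label == cen$class_label[i] &
      assign_time_bin(co$time_min) == cen$bin_start[i]
    expect_equal(cen$umap1_mean[i], mean(co$umap1[rows]))
    expect_equal(cen$umap1_se[i], sd(co$umap1[rows]) / sqrt(sum(rows)))
  }

  # all-equal coordinates: centroid is that point with zero SE (bins with a
  # single member have an undefined sample SD and are left NA)
  co2 <- co
  co2$umap1 <- 2; co2$umap2 <- -1
  cen2 <- time_bin_centroids(co2)
  expect_true(all(cen2$umap1_mean == 2))
  expect_true(all(cen2$umap2_se[cen2$n > 1] == 0))

  co$time_min[1] <- NA
  expect_error(time_bin_centroids(co), "time_min")
})

test_that("difference curves recover programmed contrasts", {
  eff <- utils::modifyList(default_class_effects(),
                           list(CAR = c(PROTEIN_AROMATIC = 1.4),
                                MOCK = c(NUCLEIC_ACID = 1.4)))
  cfg <- quiet_config(n_per_condition = 50, noise_sd = 0.05, cell_sd = 0.05,
                      hotspot_sd = 0.2, donor_sd = 0.2, class_effects = eff,
                      step = 1, seed = 9)
  set <- preprocess_spectra(simulate_spectra(cfg, c("CAR", "MOCK"),
                                             c("D1", "D2", "D3")))
  # Mock-minus-CAR: negative at 1002 (CAR-enriched), positive at 728
  dc <- difference_curves(set, class_a = "CAR", class_b = "MOCK",
                          n_boot = 200)
  expect_lt(dc$median[dc$wavenumber == 1002], 0)
  expect_gt(dc$median[dc$wavenumber == 728], 0)
  expect_true(all(abs(dc$median) <= 1))
  expect_true(all(dc$q25 <= dc$q75))

  # identical classes give the zero curve: duplicate one class under the
  # other label
  car_only <- as_spectra_tbl(tibble::as_tibble(set)[set$class_label == "CAR", ])
  twin <- tibble::as_tibble(car_only)
  twin$class_label <- "MOCK"
  twin$spectrum_id <- paste0("twin_", twin$spectrum_id)
  same <- as_spectra_tbl(dplyr::bind_rows(tibble::as_tibble(car_only), twin))
  dc0 <- difference_curves(same, "CAR", "MOCK", n_boot = 50)
  expect_true(all(abs(dc0$median) < 1e-9))

  # single donor: median equals that donor's normalized curve
  one <- as_spectra_tbl(tibble::as_tibble(set)[set$donor_id == "D1", ])
  dc1 <- difference_curves(one, "CAR", "MOCK", n_boot = 50)
  ma <- colMeans(spectra_matrix(one)[one$class_label == "MOCK", ]) -
    colMeans(spectra_matrix(one)[one$class_label == "CAR", ])
  expect_equal(dc1$median, unname(ma / max(abs(ma))), tolerance = 1e-12)

  # donor missing a class is skipped with a warning
  gap <- as_spectra_tbl(tibble::as_tibble(set)[
    !(set$donor_id == "D2" & set$class_label == "CAR"), ])
  expect_warning(difference_curves(gap, "CAR", "MOCK", n_boot = 50), "D2")
})
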