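#' Default per-class band-amplitude effects
#'
#' Multiplicative factors applied to the base amplitude of every band of a
#' biochemical class, per cell class. The defaults encode the effect
#' *directions* seen in engineered-T-cell SERS: CAR cells enriched in
#' protein/aromatic and membrane bands, Mock and Unstim cells relatively
#' enriched in nucleic-acid bands, JeKo-1 B cells protein-rich, and red
#' blood cells dominated by hemoprotein modes with almost no nucleic-acid
#' or mitochondrial signal. Magnitudes are free parameters of the
#' generator, not measured quantities.
#'
#' @return A named list mapping class labels to named numeric vectors over
#'   biochemical classes (unnamed classes default to 1).
#' @export
default_class_effects <- function() {
  list(
    CAR    = c(PROTEIN_AROMATIC = 1.2, MEMBRANE_LIPID = 1.1),
    MOCK   = c(NUCLEIC_ACID = 1.2),
    UNSTIM = c(NUCLEIC_ACID = 1.25),
    TCELL  = c(),
    BCELL_PRIMARY = c(NUCLEIC_ACID = 0.85, PROTEIN_AROMATIC = 1.1),
    BCELL_JEKO    = c(NUCLEIC_ACID = 0.7, PROTEIN_AROMATIC = 1.3),
    RBC    = c(HEMOPROTEIN = 3.0, NUCLEIC_ACID = 0.05, MITOCHONDRIAL = 0.05),
    OTHER  = c()
  )
}

#' Activation trajectory program
#'
#' Time-dependent multipliers applied to band amplitudes of antigen-engaged
#' CAR cells in a co-culture time course. The default protein/aromatic
#' curve rises during the first hour of co-culture and then partially
#' declines (unimodal with an interior maximum at 60 min); the default
#' nucleic-acid curve declines strictly monotonically with a late leveling
#' of its relative rate; the membrane/mitochondrial curve rises slowly at
#' first and accelerates late, emulating the sustained membrane
#' reorganization and metabolic ramp of prolonged effector engagement (the
#' late-course biochemical progression that keeps dynamics resolvable
#' after protein bands have peaked). All curves are validated numerically
#' on a fine grid at construction.
#'
#' @param protein_curve,nucleic_curve Functions of time (minutes) returning
#'   a positive multiplier.
#' @param membrane_mito_curve Non-decreasing multiplier applied to
#'   membrane/lipid and mitochondrial bands.
#' @param amide_shift_curve Non-decreasing wavenumber shift (cm^-1) applied
#'   to the centers of the amide-region protein bands (>= 1200 cm^-1),
#'   emulating the progressive secondary-structure reorganization that
#'   moves amide I/III positions during sustained engagement; a
#'   position shift re-shapes the spectrum while leaving 20 cm^-1 band
#'   means nearly unchanged.
#' @param t_min,t_max Time range (minutes) over which acquisition times are
#'   drawn uniformly (defaults 15 and 95).
#' @param applies_to Class labels that receive the time-dependent
#'   multipliers (default `"CAR"`); other conditions stay stationary apart
#'   from the shared acquisition drift.
#' @return An object of class `trajectory_program`.
#' @export
trajectory_program <- function(
    protein_curve = function(t) {
      ifelse(t <= 60, 1 + 0.4 * (t / 60)^2,
             1 + 0.4 * (1 - 0.4 * (t - 60) / 35))
    },
    nucleic_curve = function(t) 1 - 0.3 * ((t - 15) / 80)^0.8,
    membrane_mito_curve = function(t) 1 + 0.3 * ((t - 15) / 80)^2.5,
    amide_shift_curve = function(t) 4 * ((t - 15) / 80)^2,
    t_min = 15, t_max = 95, applies_to = "CAR") {
  grid <- seq(t_min, t_max, length.out = 201)
  nc <- nucleic_curve(grid)
  if (any(diff(nc) > 1e-12)) {
    abort("nucleic_curve must be non-increasing over the time range")
  }
  pc <- protein_curve(grid)
  imax <- which.max(pc)
  if (imax == 1 || imax == length(pc)) {
    abort("protein_curve must be unimodal with an interior maximum")
  }
  if (any(diff(membrane_mito_curve(grid)) < -1e-12)) {
    abort("membrane_mito_curve must be non-decreasing over the time range")
  }
  if (any(diff(amide_shift_curve(grid)) < -1e-12)) {
    abort("amide_shift_curve must be non-decreasing over the time range")
  }
  structure(list(protein_curve = protein_curve, nucleic_curve = nucleic_curve,
                 membrane_mito_curve = membrane_mito_curve,
                 amide_shift_curve = amide_shift_curve,
                 t_min = t_min, t_max = t_max, applies_to = applies_to),
            class = "trajectory_program")
}

#' Generator configuration
#'
#' Parameters of the synthetic single-cell SERS spectrum generator. Each
#' spectrum is a sum of pseudo-Voigt bands (mixing parameter `eta`, full
#' width at half maximum `fwhm_cm1`), with amplitudes set by the band
#' catalog, per-class effects, lognormal per-donor biochemical multipliers
#' and a lognormal per-spectrum hotspot factor; plus a smooth fluorescence
#' baseline (quartic polynomial and a broad Gaussian), additive Gaussian
#' noise, and Poisson-count cosmic-ray spikes of 10--50 times the peak
#' amplitude.
#'
#' @param n_per_condition Spectra per (class, donor) combination.
#' @param wavenumbers Axis (default 700--1700 cm^-1, 1 cm^-1 steps).
#' @param bands Band catalog, see [raman_bands()].
#' @param class_effects See [default_class_effects()].
#' @param donor_sd Log-scale SD of per-donor, per-biochemical-class
#'   multipliers (default 0.15; donor effects of this size dominate class
#'   effects in pooled embeddings).
#' @param cell_sd Log-scale SD of per-spectrum, per-band amplitude jitter
#'   (default 0.1), the cell-to-cell biochemical variability of single-cell
#'   sampling volumes.
#' @param hotspot_sd Log-scale SD of the per-spectrum global multiplier
#'   (default 0.3), mimicking SERS hotspot variability.
#' @param noise_sd Additive Gaussian SD relative to the mean peak amplitude
#'   (default 0.05).
#' @param baseline_scale Baseline height relative to the mean peak
#'   amplitude (default 3; 0 disables the baseline).
#' @param spike_rate Expected cosmic-ray spikes per spectrum (default 0.1).
#' @param eta Pseudo-Voigt Lorentzian fraction in `[0, 1]` (default 0.5).
#' @param fwhm_cm1 Band full width at half maximum (default 12 cm^-1).
#' @param trajectory A [trajectory_program()] or `NULL` for static
#'   experiments.
#' @param drift_rate Per-minute log-slope of the multiplicative acquisition
#'   drift shared by all conditions in a time course (default 0.002).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
simulate_config <- function(n_per_condition = 200,
                            wavenumbers = seq(700, 1700, by = 1),
                            bands = raman_bands(),
                            class_effects = default_class_effects(),
                            donor_sd = 0.15,
                            cell_sd = 0.1,
                            hotspot_sd = 0.3,
                            noise_sd = 0.05,
                            baseline_scale = 3,
                            spike_rate = 0.1,
                            eta = 0.5,
                            fwhm_cm1 = 12,
                            trajectory = NULL,
                            drift_rate = 0.002,
                            seed = 1L) {
  stopifnot(donor_sd >= 0, cell_sd >= 0, hotspot_sd >= 0, noise_sd >= 0,
            spike_rate >= 0,
            eta >= 0, eta <= 1, fwhm_cm1 > 0, n_per_condition >= 1)
  structure(list(n_per_condition = n_per_condition, wavenumbers = wavenumbers,
                 bands = bands, class_effects = class_effects,
                 donor_sd = donor_sd, cell_sd = cell_sd,
                 hotspot_sd = hotspot_sd,
                 noise_sd = noise_sd, baseline_scale = baseline_scale,
                 spike_rate = spike_rate, eta = eta, fwhm_cm1 = fwhm_cm1,
                 trajectory = trajectory, drift_rate = drift_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Unit-height pseudo-Voigt line shape.
pseudo_voigt <- function(nu, center, fwhm, eta) {
  u <- (nu - center) / (fwhm / 2)
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

#' Simulate a static spectra set
#'
#' Draws `n_per_condition` spectra for every (class, donor) combination.
#' The full latent state (donor multipliers, hotspot factors, noise-free
#' signal, baseline, spike locations) is recorded and retrievable with
#' [sim_truth()], so downstream stages can be validated against ground
#' truth.
#'
#' @param config A [simulate_config()].
#' @param classes Class labels to generate.
#' @param donors Donor identifiers.
#' @return A [spectra table][as_spectra_tbl] carrying a `truth` attribute.
#' @export
simulate_spectra <- function(config = simulate_config(),
                             classes = c("CAR", "MOCK"),
                             donors = c("D1", "D2", "D3")) {
  stopifnot(length(classes) >= 1)
  meta <- tidyr::expand_grid(class_label = classes, donor_id = donors) |>
    dplyr::slice(rep(seq_len(dplyr::n()), each = config$n_per_condition)) |>
    mutate(time_min = NA_real_,
           batch_id = paste0("B_", .data$donor_id),
           spectrum_id = sprintf("%s_%s_%05d", .data$class_label,
                                 .data$donor_id, row_number()))
  generate_from_meta(config, meta)
}

#' Simulate an activation time course
#'
#' Paired co-culture conditions over a 15--95 min window: condition(s)
#' named in the trajectory program receive its time-dependent band
#' multipliers, the others are time-stationary; a shared multiplicative
#' acquisition drift `exp(drift_rate * (t - t_min))` is applied to every
#' spectrum so that log-ratio statistics must remove it. Acquisition times
#' are drawn uniformly and rows are ordered by time within each
#' (condition, donor), matching semi-continuous acquisition order.
#'
#' @inheritParams simulate_spectra
#' @param conditions Class labels of the paired conditions.
#' @return A [spectra table][as_spectra_tbl] with a `truth` attribute.
#' @export
simulate_timecourse <- function(config = simulate_config(trajectory = trajectory_program()),
                                conditions = c("CAR", "UNSTIM"),
                                donors = "D1") {
  traj <- config$trajectory
  if (is.null(traj)) abort("config$trajectory must be a trajectory_program")
  meta <- tidyr::expand_grid(class_label = conditions, donor_id = donors) |>
    dplyr::slice(rep(seq_len(dplyr::n()), each = config$n_per_condition))
  # times are drawn and sorted inside the seeded generator
  meta$batch_id <- paste0("B_", meta$donor_id, "_", meta$class_label)
  meta$time_min <- NA_real_
  meta$spectrum_id <- sprintf("%s_%s_%05d", meta$class_label, meta$donor_id,
                              seq_len(nrow(meta)))
  generate_from_meta(config, meta, timecourse = TRUE)
}

#' @rdname simulate_spectra
#' @param x A simulated spectra table.
#' @export
sim_truth <- function(x) {
  tr <- attr(x, "truth", exact = TRUE)
  if (is.null(tr)) abort("no truth record attached to this spectra table")
  tr
}

generate_from_meta <- function(config, meta, timecourse = FALSE) {
  withr::local_seed(config$seed)
  nu <- config$wavenumbers
  bands <- config$bands
  n <- nrow(meta)
  traj <- config$trajectory

  bad <- setdiff(unique(meta$class_label), names(config$class_effects))
  if (length(bad) > 0) {
    abort(paste0("class_label(s) missing from class_effects: ",
                 paste(bad, collapse = ", ")))
  }

  if (timecourse) {
    t <- runif(n, traj$t_min, traj$t_max)
    # acquisition order: sort times within each (condition, donor)
    key <- paste(meta$class_label, meta$donor_id)
    for (k in unique(key)) {
      idx <- which(key == k)
      t[idx] <- sort(t[idx])
    }
    meta$time_min <- t
  }

  # peak profiles: n_bands x n_channels
  P <- t(vapply(seq_len(nrow(bands)), function(k) {
    pseudo_voigt(nu, bands$center_cm1[k], config$fwhm_cm1, config$eta)
  }, numeric(length(nu))))

  donors <- unique(meta$donor_id)
  donor_eff <- tidyr::expand_grid(donor_id = donors,
                                  biochemical_class = .bio_classes)
  donor_eff$multiplier <- exp(rnorm(nrow(donor_eff), 0, config$donor_sd))

  # class-effect lookup table: classes x biochemical classes
  classes_u <- unique(meta$class_label)
  eff_tab <- matrix(1, length(classes_u), length(.bio_classes),
                    dimnames = list(classes_u, .bio_classes))
  for (cl in classes_u) {
    eff <- config$class_effects[[cl]]
    hit <- intersect(names(eff), .bio_classes)
    eff_tab[cl, hit] <- unname(eff[hit])
  }

  # amplitude matrix A: n_spectra x n_bands
  A <- matrix(0, n, nrow(bands))
  de_key <- paste(donor_eff$donor_id, donor_eff$biochemical_class)
  de_mult <- setNames(donor_eff$multiplier, de_key)
  prot_mult <- rep(1, n)
  nuc_mult <- rep(1, n)
  mm_mult <- rep(1, n)
  amide_shift <- rep(0, n)
  if (timecourse) {
    on_traj <- meta$class_label %in% traj$applies_to
    prot_mult[on_traj] <- traj$protein_curve(meta$time_min[on_traj])
    nuc_mult[on_traj] <- traj$nucleic_curve(meta$time_min[on_traj])
    mm_mult[on_traj] <- traj$membrane_mito_curve(meta$time_min[on_traj])
    amide_shift[on_traj] <- traj$amide_shift_curve(meta$time_min[on_traj])
  }
  amide_bands <- which(bands$biochemical_class == "PROTEIN_AROMATIC" &
                         bands$center_cm1 >= 1200)
  for (k in seq_len(nrow(bands))) {
    bc <- bands$biochemical_class[k]
    a <- bands$base_amplitude[k] *
      eff_tab[meta$class_label, bc] *
      unname(de_mult[paste(meta$donor_id, bc)])
    if (bc == "PROTEIN_AROMATIC") a <- a * prot_mult
    if (bc == "NUCLEIC_ACID") a <- a * nuc_mult
    if (bc %in% c("MEMBRANE_LIPID", "MITOCHONDRIAL")) a <- a * mm_mult
    A[, k] <- a
  }
  # per-cell biochemical jitter: independent lognormal amplitude factor
  # per spectrum and band
  if (config$cell_sd > 0) {
    A <- A * exp(matrix(rnorm(length(A), 0, config$cell_sd), nrow(A)))
  }

  if (any(amide_shift != 0) && length(amide_bands) > 0) {
    # amide-region protein bands move with the shift curve: compute their
    # contribution per spectrum at the shifted centers
    signal <- A[, -amide_bands, drop = FALSE] %*% P[-amide_bands, , drop = FALSE]
    for (k in amide_bands) {
      centers <- bands$center_cm1[k] + amide_shift
      u <- (matrix(nu, n, length(nu), byrow = TRUE) - centers) /
        (config$fwhm_cm1 / 2)
      pk <- config$eta / (1 + u^2) + (1 - config$eta) * exp(-log(2) * u^2)
      signal <- signal + A[, k] * pk
    }
  } else {
    signal <- A %*% P
  }
  ref_amp <- mean(apply(signal, 1, max))

  hotspot <- exp(rnorm(n, 0, config$hotspot_sd))
  drift <- if (timecourse) exp(config$drift_rate * (meta$time_min - traj$t_min)) else rep(1, n)
  clean <- (hotspot * drift) * signal

  # smooth fluorescence baseline: quartic + broad Gaussian, per-spectrum scale
  u <- 2 * (nu - min(nu)) / (max(nu) - min(nu)) - 1
  shape <- 0.6 + 0.25 * u + 0.1 * u^2 + 0.05 * u^4 +
    0.8 * exp(-(nu - 1150)^2 / (2 * 300^2))
  base_scale <- config$baseline_scale * ref_amp * exp(rnorm(n, 0, 0.2))
  baseline <- (base_scale * drift) %o% shape

  noise <- matrix(rnorm(n * length(nu), 0, config$noise_sd * ref_amp),
                  n, length(nu))

  m <- clean + baseline + noise

  # cosmic-ray spikes: Poisson count per spectrum, width 1-3 channels,
  # amplitude 10-50x that spectrum's max peak height
  n_spikes <- rpois(n, config$spike_rate)
  spikes <- vector("list", n)
  for (i in which(n_spikes > 0)) {
    rows <- lapply(seq_len(n_spikes[i]), function(j) {
      width <- sample(1:3, 1)
      start <- sample(seq_len(length(nu) - width + 1), 1)
      amp <- runif(1, 10, 50) * max(clean[i, ])
      tibble(channel = start:(start + width - 1), amplitude = amp)
    })
    sp <- bind_rows(rows)
    m[i, sp$channel] <- m[i, sp$channel] + sp$amplitude
    spikes[[i]] <- mutate(sp, spectrum_id = meta$spectrum_id[i],
                          .before = 1)
  }
  spikes <- bind_rows(spikes)
  if (nrow(spikes) == 0) {
    spikes <- tibble(spectrum_id = character(), channel = integer(),
                     amplitude = double())
  }

  out <- new_spectra_tbl(meta, m, nu)
  truth <- structure(list(
    spectra = bind_cols(spectra_meta(out),
                        tibble(hotspot = hotspot, drift = drift,
                               protein_mult = prot_mult,
                               nucleic_mult = nuc_mult,
                               membrane_mito_mult = mm_mult,
                               amide_shift = amide_shift)),
    donor_effects = donor_eff,
    spikes = spikes,
    signal = signal,       # noise-free, hotspot-free, baseline-free
    clean = clean,         # hotspot * drift * signal
    baseline = baseline,
    ref_amp = ref_amp,
    wavenumbers = nu,
    config = config
  ), class = "sim_truth")
  attr(out, "truth") <- truth
  out
}
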