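#' Preprocessing configuration
#'
#' @param despike_z_threshold Robust z threshold on first differences for
#'   cosmic-ray flagging (default 6: simulated spikes of 10x the peak
#'   height or more are always caught, sharp Raman peaks never are).
#' @param despike_window Odd window (channels) whose non-flagged members
#'   supply the replacement mean (default 5).
#' @param airpls_lambda,airpls_max_iter,airpls_tol See [airpls_baseline()].
#' @param outlier_sd Per-batch exclusion threshold in SDs above the batch
#'   mean of the average raw intensity (default 3).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(despike_z_threshold = 6,
                              despike_window = 5L,
                              airpls_lambda = 1e5,
                              airpls_max_iter = 30L,
                              airpls_tol = 1e-3,
                              outlier_sd = 3) {
  stopifnot(despike_z_threshold > 0, despike_window %% 2 == 1,
            airpls_lambda > 0, airpls_max_iter > 0, airpls_tol > 0,
            outlier_sd > 0)
  structure(list(despike_z_threshold = despike_z_threshold,
                 despike_window = as.integer(despike_window),
                 airpls_lambda = airpls_lambda,
                 airpls_max_iter = as.integer(airpls_max_iter),
                 airpls_tol = airpls_tol,
                 outlier_sd = outlier_sd),
            class = "preprocess_config")
}

# Modified Whitaker-Hayes despiking of one spectrum. Robust z-scores of the
# first differences flag spike edges; each flagged difference marks the
# channel on either side of it; flagged channels are replaced by the mean
# of the non-flagged channels inside a centered window (widened if the
# window holds no clean channel). The flag/replace pass is repeated until
# it converges so that the plateau centers of multi-channel spikes - whose
# first differences are small - are caught once their flanks are cleaned.
despike_vector <- function(y, z_threshold = 6, window = 5L,
                           max_passes = 5L) {
  n <- length(y)
  if (n < 3 || all(y == y[1])) return(list(y = y, spikes = integer()))
  half <- (window - 1L) %/% 2L

  one_pass <- function(v, known) {
    d <- diff(v)
    med <- median(d)
    scale <- mad(d)
    if (scale == 0) scale <- sd(d)
    if (scale == 0) return(integer())
    z <- (d - med) / scale
    hit <- which(abs(z) > z_threshold)
    setdiff(sort(unique(c(hit, hit + 1L))), known)
  }

  replace_flagged <- function(v, flagged) {
    out <- v
    for (ch in flagged) {
      h <- half
      repeat {
        nbr <- max(1L, ch - h):min(n, ch + h)
        good <- setdiff(nbr, flagged)
        if (length(good) > 0) break
        h <- h + 1L
      }
      out[ch] <- mean(v[good])
    }
    out
  }

  flagged <- integer()
  work <- y
  for (pass in seq_len(max_passes)) {
    new_hits <- one_pass(work, flagged)
    if (length(new_hits) == 0) break
    flagged <- sort(unique(c(flagged, new_hits)))
    work <- replace_flagged(work, flagged)
  }
  list(y = work, spikes = flagged)
}

#' Cosmic-ray despiking
#'
#' Applies the modified Whitaker-Hayes procedure to every spectrum: robust
#' z-scores (median/MAD) of the channel-to-channel first differences flag
#' spike channels, which are replaced by the local mean of clean channels.
#' Untouched channels are bit-identical to the input.
#'
#' @param x A spectra table.
#' @param config A [preprocess_config()].
#' @return The corrected spectra table; flagged channels are recorded in
#'   the `spikes` attribute (a tibble `spectrum_id`, `channel`).
#' @export
despike <- function(x, config = preprocess_config()) {
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  spikes <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- despike_vector(m[i, ], config$despike_z_threshold,
                        config$despike_window)
    m[i, ] <- r$y
    if (length(r$spikes) > 0) {
      spikes[[i]] <- tibble(spectrum_id = x$spectrum_id[i],
                            channel = r$spikes)
    }
  }
  spikes <- bind_rows(spikes)
  if (nrow(spikes) == 0) {
    spikes <- tibble(spectrum_id = character(), channel = integer())
  }
  out <- set_spectra_matrix(x, m)
  attr(out, "spikes") <- spikes
  out
}

#' Wavelet denoising
#'
#' sym8 wavelet decomposition with per-subband BayesShrink soft
#' thresholding (noise SD estimated from the finest detail coefficients by
#' median absolute deviation / 0.6745), applied to every spectrum.
#'
#' @inheritParams despike
#' @return The denoised spectra table.
#' @export
denoise <- function(x, config = preprocess_config()) {
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  for (i in seq_len(nrow(m))) m[i, ] <- denoise_vector(m[i, ])
  set_spectra_matrix(x, m)
}

#' Baseline correction for a spectra table
#'
#' Runs [airpls_baseline()] on every spectrum and subtracts the fitted
#' baseline.
#'
#' @inheritParams despike
#' @return The corrected spectra table; attributes `baselines` (matrix) and
#'   `airpls_converged` (logical vector) record the fits.
#' @export
correct_baseline <- function(x, config = preprocess_config()) {
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  bl <- m
  conv <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- airpls_baseline(m[i, ], config$airpls_lambda,
                         config$airpls_max_iter, config$airpls_tol)
    bl[i, ] <- r$baseline
    m[i, ] <- r$corrected
    conv[i] <- r$converged
  }
  out <- set_spectra_matrix(x, m)
  attr(out, "baselines") <- bl
  attr(out, "airpls_converged") <- conv
  out
}

#' Per-spectrum normalization
#'
#' `"zscore"` standardizes each spectrum to mean 0 and population SD 1
#' (population rather than sample SD, fixed for bit-reproducibility; the
#' difference is immaterial at ~1000 channels). `"total"` divides each
#' spectrum by its summed intensity, a positive representation required by
#' log-ratio band statistics.
#'
#' @inheritParams despike
#' @param method `"zscore"` or `"total"`.
#' @return The normalized spectra table.
#' @export
normalize_spectra <- function(x, method = c("zscore", "total")) {
  method <- match.arg(method)
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  if (method == "zscore") {
    mu <- rowMeans(m)
    s <- sqrt(rowMeans((m - mu)^2))
    if (any(s == 0)) {
      abort(paste0("zero-variance spectrum cannot be z-scored: '",
                   x$spectrum_id[which(s == 0)[1]], "'"))
    }
    m <- (m - mu) / s
  } else {
    tot <- rowSums(m)
    if (any(tot <= 0)) {
      abort(paste0("non-positive total intensity in spectrum '",
                   x$spectrum_id[which(tot <= 0)[1]], "'"))
    }
    m <- m / tot
  }
  set_spectra_matrix(x, m)
}

#' Per-batch intensity outlier screening
#'
#' Within each acquisition group (default `batch_id`), spectra whose
#' average raw intensity exceeds the group mean by more than `outlier_sd`
#' group SDs are excluded (one-sided, high intensities only -- the
#' signature of laser artifacts or detector saturation). Group statistics
#' are computed once from all spectra, without re-iteration.
#'
#' @inheritParams despike
#' @param group Metadata column defining the acquisition group.
#' @return The retained spectra table; the `excluded` attribute is a tibble
#'   of removed spectra with the triggering statistics.
#' @export
exclude_outliers <- function(x, config = preprocess_config(),
                             group = "batch_id") {
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  avg <- rowMeans(m)
  g <- x[[group]]
  drop <- logical(nrow(x))
  thr_all <- rep(NA_real_, nrow(x))
  for (gg in unique(g)) {
    idx <- which(g == gg)
    if (length(idx) == 1) {
      warn(paste0("group '", gg, "' has a single spectrum; kept without screening"))
      next
    }
    thr <- mean(avg[idx]) + config$outlier_sd * sd(avg[idx])
    thr_all[idx] <- thr
    drop[idx] <- avg[idx] > thr
  }
  excluded <- tibble(spectrum_id = x$spectrum_id[drop],
                     group = g[drop],
                     mean_intensity = avg[drop],
                     threshold = thr_all[drop],
                     reason = "high_intensity")
  out <- x[!drop, ]
  class(out) <- unique(c("spectra_tbl", class(out)))
  attr(out, "excluded") <- excluded
  out
}

#' Full preprocessing chain
#'
#' The four-step cleanup plus QC screening, in the order: outlier exclusion
#' on raw intensities, then per spectrum despiking, wavelet denoising,
#' airPLS baseline correction, and normalization. Excluded spectra are
#' removed; all others keep their relative order.
#'
#' @inheritParams despike
#' @param normalize `"zscore"` (default), `"total"` (positive
#'   representation for log-ratio band statistics), or `"none"`.
#' @param group Acquisition-group column for outlier screening.
#' @return The preprocessed spectra table. [preprocess_report()] retrieves
#'   the per-spectrum report (exclusions, spike channels, fitted baselines,
#'   non-converged airPLS fits).
#' @examples
#' raw <- simulate_spectra(simulate_config(n_per_condition = 5, seed = 7),
#'                         classes = c("CAR", "MOCK"), donors = "D1")
#' clean <- preprocess_spectra(raw)
#' preprocess_report(clean)$n_excluded
#' @export
preprocess_spectra <- function(x, config = preprocess_config(),
                               normalize = c("zscore", "total", "none"),
                               group = "batch_id") {
  normalize <- match.arg(normalize)
  x <- as_spectra_tbl(x)
  if (nrow(x) == 0) {
    report <- structure(list(
      excluded = tibble(spectrum_id = character(), group = character(),
                        mean_intensity = double(), threshold = double(),
                        reason = character()),
      spikes = tibble(spectrum_id = character(), channel = integer()),
      baselines = NULL, non_converged = character(), n_excluded = 0L),
      class = "preprocess_report")
    attr(x, "preprocess_report") <- report
    return(x)
  }
  kept <- exclude_outliers(x, config, group)
  excluded <- attr(kept, "excluded")
  out <- despike(kept, config)
  spikes <- attr(out, "spikes")
  out <- denoise(out, config)
  out <- correct_baseline(out, config)
  baselines <- attr(out, "baselines")
  conv <- attr(out, "airpls_converged")
  if (normalize != "none") out <- normalize_spectra(out, normalize)
  report <- structure(list(
    excluded = excluded,
    spikes = spikes,
    baselines = baselines,
    non_converged = out$spectrum_id[!conv],
    n_excluded = nrow(excluded)
  ), class = "preprocess_report")
  attr(out, "spikes") <- NULL
  attr(out, "baselines") <- NULL
  attr(out, "airpls_converged") <- NULL
  attr(out, "preprocess_report") <- report
  out
}

#' @rdname preprocess_spectra
#' @export
preprocess_report <- function(x) {
  r <- attr(x, "preprocess_report", exact = TRUE)
  if (is.null(r)) abort("no preprocess report attached to this spectra table")
  r
}
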