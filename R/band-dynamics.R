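#' Time-binned mean spectra
#'
#' Channel-wise arithmetic mean spectrum of every (group, time bin)
#' combination; empty bins are omitted.
#'
#' @param x A preprocessed spectra table with `time_min`.
#' @param binning A [time_bins()] object.
#' @param group Metadata column to group by (default `class_label`).
#' @return A wide tibble: `group`, `bin_start`, `n`, then one column per
#'   wavenumber.
#' @export
bin_mean_spectra <- function(x, binning = time_bins(),
                             group = "class_label") {
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  bin <- assign_time_bin(x$time_min, binning)
  keep <- !is.na(bin)
  key <- paste(x[[group]][keep], bin[keep], sep = "\r")
  groups <- unique(key)
  rows <- lapply(groups, function(kk) {
    idx <- which(key == kk)
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    bind_cols(tibble(group = parts[1], bin_start = as.numeric(parts[2]),
                     n = length(idx)),
              as_tibble(rbind(colMeans(m[keep, , drop = FALSE][idx, ,
                                                               drop = FALSE]))))
  })
  bind_rows(rows) |> arrange(.data$group, .data$bin_start)
}

# Shared core of the log-ratio trajectory statistic. Inputs are
# per-spectrum band-intensity matrices and bin labels for the two
# conditions; output is the per-biochemical-class z-scored log-ratio
# series over the common bins.
logratio_stat <- function(bi_a, bin_a, bi_b, bin_b, panel, bin_starts,
                          aggregate = "mean") {
  nb <- length(bin_starts)
  r <- matrix(NA_real_, nrow(panel), nb)
  for (j in seq_len(nb)) {
    ia <- which(bin_a == bin_starts[j])
    ib <- which(bin_b == bin_starts[j])
    mean_a <- colMeans(bi_a[ia, , drop = FALSE])
    mean_b <- colMeans(bi_b[ib, , drop = FALSE])
    if (any(mean_a <= 0) || any(mean_b <= 0)) {
      abort(paste0("non-positive mean band intensity; feed a positive ",
                   "representation (preprocess with normalize = \"total\")"))
    }
    r[, j] <- log(mean_a / mean_b)
  }
  # z-score each band's series across bins (population SD)
  degenerate <- FALSE
  z <- r
  for (b in seq_len(nrow(panel))) {
    mu <- mean(r[b, ])
    s <- sqrt(mean((r[b, ] - mu)^2))
    if (s == 0) {
      z[b, ] <- 0
      degenerate <- TRUE
    } else {
      z[b, ] <- (r[b, ] - mu) / s
    }
  }
  agg <- if (identical(aggregate, "median")) {
    function(v) median(v)
  } else {
    function(v) mean(v)
  }
  classes <- unique(panel$biochemical_class)
  out <- vapply(classes, function(cl) {
    apply(z[panel$biochemical_class == cl, , drop = FALSE], 2, agg)
  }, numeric(nb))
  structure(list(value = t(matrix(out, nrow = nb,
                                  dimnames = list(NULL, classes))),
                 degenerate = degenerate))
}

prepare_band_inputs <- function(car, unstim, panel, binning) {
  car <- as_spectra_tbl(car)
  unstim <- as_spectra_tbl(unstim)
  wn <- spec_wavenumbers(car)
  if (!identical(wn, spec_wavenumbers(unstim))) {
    abort("both conditions must share one wavenumber axis")
  }
  bi_a <- band_intensity_matrix(spectra_matrix(car), panel, wn)
  bi_b <- band_intensity_matrix(spectra_matrix(unstim), panel, wn)
  bin_a <- assign_time_bin(car$time_min, binning)
  bin_b <- assign_time_bin(unstim$time_min, binning)
  common <- intersect(unique(bin_a[!is.na(bin_a)]),
                      unique(bin_b[!is.na(bin_b)]))
  all_bins <- union(unique(bin_a[!is.na(bin_a)]),
                    unique(bin_b[!is.na(bin_b)]))
  if (length(setdiff(all_bins, common)) > 0) {
    warn(paste0("bin(s) present in only one condition dropped: ",
                paste(sort(setdiff(all_bins, common)), collapse = ", ")))
  }
  bin_starts <- sort(common)
  list(bi_a = bi_a, bin_a = bin_a, bi_b = bi_b, bin_b = bin_b,
       bin_starts = bin_starts)
}

#' Band trajectories relative to an unstimulated control
#'
#' The time-resolved band-intensity statistic: per band and time bin, the
#' natural log of the ratio of the mean band intensity in the
#' antigen-engaged condition to the unstimulated control (a multiplicative
#' drift applied equally to both conditions cancels exactly); each band's
#' series is z-score standardized across bins; the z-scored series are
#' then averaged across the bands of each biochemical class. Inputs must
#' be a positive spectral representation -- preprocess with
#' `normalize = "total"`.
#'
#' @param car Spectra table of the antigen-engaged (CAR) co-culture.
#' @param unstim Spectra table of the unstimulated control co-culture.
#' @param panel Band panel, see [band_panel()].
#' @param binning A [time_bins()] object.
#' @param aggregate `"mean"` (default) or `"median"` across bands.
#' @return A tibble of class `band_trajectory`: `biochemical_class`,
#'   `bin_start`, `value`, `n_car`, `n_unstim`. If every band series is
#'   constant (e.g. identical conditions) the values are all zero and the
#'   `degenerate` attribute is `TRUE`.
#' @export
logratio_trajectory <- function(car, unstim, panel = band_panel(),
                                binning = time_bins(), aggregate = "mean") {
  inp <- prepare_band_inputs(car, unstim, panel, binning)
  st <- logratio_stat(inp$bi_a, inp$bin_a, inp$bi_b, inp$bin_b, panel,
                      inp$bin_starts, aggregate)
  classes <- rownames(st$value)
  out <- tidyr::expand_grid(biochemical_class = classes,
                            bin_start = inp$bin_starts) |>
    mutate(value = as.vector(t(st$value)),
           n_car = vapply(.data$bin_start, function(b)
             sum(inp$bin_a == b, na.rm = TRUE), integer(1)),
           n_unstim = vapply(.data$bin_start, function(b)
             sum(inp$bin_b == b, na.rm = TRUE), integer(1)))
  class(out) <- c("band_trajectory", class(out))
  attr(out, "degenerate") <- st$degenerate
  attr(out, "panel") <- panel
  out
}

#' Block-bootstrap confidence intervals for band trajectories
#'
#' Uncertainty for [logratio_trajectory()] that respects serial dependence
#' in semi-continuous acquisition: within every (condition, time bin) the
#' spectra are partitioned, in acquisition order, into contiguous blocks
#' of length `ceiling(sqrt(n))`; blocks are resampled with replacement,
#' the full statistic (log-ratio, within-band z-scoring, class averaging)
#' is recomputed on each resample, and percentile intervals are formed per
#' (class, bin). With a single block a warning is raised (the interval
#' collapses toward a point).
#'
#' @inheritParams logratio_trajectory
#' @param n_boot Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return The [logratio_trajectory()] tibble with `ci_lo` and `ci_hi`
#'   columns added.
#' @export
block_bootstrap_ci <- function(car, unstim, panel = band_panel(),
                               binning = time_bins(), n_boot = 1000L,
                               level = 0.95, seed = 1L,
                               aggregate = "mean") {
  inp <- prepare_band_inputs(car, unstim, panel, binning)
  point <- logratio_trajectory(car, unstim, panel, binning, aggregate)

  make_blocks <- function(bins) {
    lapply(inp$bin_starts, function(b) {
      idx <- which(bins == b)              # acquisition (row) order
      len <- max(1L, ceiling(sqrt(length(idx))))
      blocks <- split(idx, ceiling(seq_along(idx) / len))
      if (length(blocks) < 2) {
        warn(paste0("a (condition, bin ", b, ") group has a single block; ",
                    "its bootstrap interval collapses toward a point"))
      }
      blocks
    })
  }
  blocks_a <- make_blocks(inp$bin_a)
  blocks_b <- make_blocks(inp$bin_b)

  resample_bin <- function(blocks) {
    n_target <- length(unlist(blocks))
    out <- integer(0)
    while (length(out) < n_target) {
      out <- c(out, blocks[[sample.int(length(blocks), 1)]])
    }
    out[seq_len(n_target)]
  }

  withr::local_seed(seed)
  classes <- unique(panel$biochemical_class)
  nb <- length(inp$bin_starts)
  draws <- array(NA_real_, c(length(classes), nb, n_boot))
  for (bt in seq_len(n_boot)) {
    idx_a <- lapply(blocks_a, resample_bin)
    idx_b <- lapply(blocks_b, resample_bin)
    bin_a_new <- rep(inp$bin_starts, lengths(idx_a))
    bin_b_new <- rep(inp$bin_starts, lengths(idx_b))
    st <- logratio_stat(inp$bi_a[unlist(idx_a), , drop = FALSE], bin_a_new,
                        inp$bi_b[unlist(idx_b), , drop = FALSE], bin_b_new,
                        panel, inp$bin_starts, aggregate)
    draws[, , bt] <- st$value
  }
  a <- (1 - level) / 2
  ci_lo <- apply(draws, c(1, 2), quantile, a)
  ci_hi <- apply(draws, c(1, 2), quantile, 1 - a)
  point$ci_lo <- as.vector(t(ci_lo))
  point$ci_hi <- as.vector(t(ci_hi))
  point
}

#' Monotonicity of band trajectories
#'
#' Two-sided Spearman rank correlation (midrank ties) between each
#' biochemical class's trajectory values and the bin start times.
#'
#' @param trajectory A [logratio_trajectory()] result (at least 3 bins).
#' @return A tibble `biochemical_class`, `rho`, `p_value`, `n_bins`, or
#'   `NA` rows with a warning when fewer than 3 bins are present.
#' @export
trajectory_spearman <- function(trajectory) {
  trajectory |>
    group_by(.data$biochemical_class) |>
    summarise({
      if (dplyr::n() < 3) {
        warn("fewer than 3 time bins; Spearman correlation not computed")
        tibble(rho = NA_real_, p_value = NA_real_, n_bins = dplyr::n())
      } else {
        ct <- suppressWarnings(cor.test(.data$value, .data$bin_start,
                                        method = "spearman", exact = FALSE))
        tibble(rho = unname(ct$estimate), p_value = ct$p.value,
               n_bins = dplyr::n())
      }
    }, .groups = "drop")
}
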