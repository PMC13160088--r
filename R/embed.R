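#' Embedding configuration
#'
#' UMAP parameters for spectral visualization: 2 components, 20 neighbours,
#' minimum distance 0.1, city-block (manhattan) metric.
#'
#' @param n_components,n_neighbors,min_dist,metric UMAP parameters.
#' @param seed Integer seed.
#' @return A list of class `embed_config`.
#' @export
embed_config <- function(n_components = 2L, n_neighbors = 20L,
                         min_dist = 0.1, metric = "manhattan", seed = 1L) {
  structure(list(n_components = as.integer(n_components),
                 n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, metric = metric,
                 seed = as.integer(seed)),
            class = "embed_config")
}

#' Class/donor-balanced subsampling
#'
#' Downsamples every combination of the key columns, without replacement,
#' to the smallest combination count, so that embeddings are not
#' overweighted by abundant conditions. Deterministic under `seed`.
#'
#' @param x A spectra table.
#' @param keys Metadata columns defining the combinations.
#' @param seed Integer seed.
#' @return The subsampled spectra table (original relative order kept).
#' @export
balanced_subsample <- function(x, keys = c("class_label", "donor_id"),
                               seed = 1L) {
  x <- as_spectra_tbl(x)
  combo <- interaction(as_tibble(x)[keys], drop = FALSE, sep = " / ")
  counts <- table(combo)
  if (any(counts == 0)) {
    abort(paste0("empty key combination(s): ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  m <- min(counts)
  withr::local_seed(seed)
  keep <- sort(unlist(lapply(levels(combo), function(lv) {
    idx <- which(combo == lv)
    if (length(idx) > m) sample(idx, m) else idx
  })))
  out <- x[keep, ]
  class(out) <- unique(c("spectra_tbl", class(out)))
  out
}

#' UMAP embedding of spectra
#'
#' Two-dimensional manifold projection of preprocessed spectra, a
#' visualization product: apart from time-binned centroids, no downstream
#' statistic consumes the embedding coordinates (UMAP does not preserve
#' global distances).
#'
#' @param x A preprocessed spectra table.
#' @param config An [embed_config()].
#' @return A tibble: metadata columns plus `umap1`, `umap2`.
#' @export
embed_spectra <- function(x, config = embed_config()) {
  x <- as_spectra_tbl(x)
  if (nrow(x) < config$n_neighbors + 1) {
    abort("need at least n_neighbors + 1 spectra to embed")
  }
  m <- spectra_matrix(x)
  withr::local_seed(config$seed)
  coords <- uwot::umap(m, n_components = config$n_components,
                       n_neighbors = config$n_neighbors,
                       min_dist = config$min_dist, metric = config$metric,
                       n_threads = 1, n_sgd_threads = 1)
  bind_cols(spectra_meta(x),
            tibble(umap1 = coords[, 1], umap2 = coords[, 2]))
}

#' Time bins
#'
#' The acquisition-time binning of co-culture time courses: bins
#' 15--25, 25--35, 35--45, 45--55, 55--75 and 75--95 min, each labeled by
#' its earliest time point. Intervals are half-open `[a, b)`; the last bin
#' is closed at 95 so an acquisition at exactly 95 min joins it.
#'
#' @param edges_min Strictly increasing bin edges in minutes.
#' @return A list of class `time_binning` with `edges` and `starts`.
#' @export
time_bins <- function(edges_min = c(15, 25, 35, 45, 55, 75, 95)) {
  stopifnot(all(diff(edges_min) > 0), length(edges_min) >= 2)
  structure(list(edges = edges_min, starts = head(edges_min, -1)),
            class = "time_binning")
}

#' @rdname time_bins
#' @param time_min Numeric acquisition times (minutes).
#' @param binning A `time_binning`.
#' @return `assign_time_bin()` returns the bin start label per time (`NA`
#'   outside the binning range).
#' @export
assign_time_bin <- function(time_min, binning = time_bins()) {
  e <- binning$edges
  idx <- findInterval(time_min, e, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(time_min))
  ok <- !is.na(idx) & idx >= 1 & idx <= length(e) - 1
  out[ok] <- binning$starts[idx[ok]]
  out
}

#' Time-binned embedding centroids
#'
#' Mean UMAP coordinate of each class within each time bin, with the
#' per-axis standard error (SD / sqrt(n)); a qualitative illustration of
#' cluster evolution during activation. Empty bins are omitted.
#'
#' @param coords Output of [embed_spectra()] (must include `time_min`).
#' @param binning A [time_bins()] object.
#' @param group Metadata column to group by (default `class_label`).
#' @return A tibble with one row per (group, bin).
#' @export
time_bin_centroids <- function(coords, binning = time_bins(),
                               group = "class_label") {
  if (anyNA(coords$time_min)) {
    abort("all spectra must carry time_min for time-binned centroids")
  }
  coords |>
    mutate(bin_start = assign_time_bin(.data$time_min, binning)) |>
    filter(!is.na(.data$bin_start)) |>
    group_by(.data[[group]], .data$bin_start) |>
    summarise(n = dplyr::n(),
              umap1_mean = mean(.data$umap1),
              umap2_mean = mean(.data$umap2),
              umap1_se = sd(.data$umap1) / sqrt(dplyr::n()),
              umap2_se = sd(.data$umap2) / sqrt(dplyr::n()),
              .groups = "drop")
}

#' Donor-aggregated class difference curves
#'
#' For each donor carrying both classes, the channel-wise difference of the
#' class-mean spectra (`class_b` minus `class_a`), normalized by its own
#' maximum absolute value so each donor curve spans at most `[-1, 1]`;
#' aggregated across donors by the channel-wise median. Two uncertainty
#' bands are emitted: the 2.5/97.5% bootstrap percentiles over donors and
#' the 25--75% across-donor quantile range.
#'
#' @param x A preprocessed spectra table.
#' @param class_a,class_b Class labels to contrast.
#' @param n_boot Bootstrap resamples over donors (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble per wavenumber: `median`, `boot_lo`, `boot_hi`, `q25`,
#'   `q75`, `n_donors`.
#' @export
difference_curves <- function(x, class_a, class_b, n_boot = 1000L, seed = 1L) {
  x <- as_spectra_tbl(x)
  wn <- spec_wavenumbers(x)
  m <- spectra_matrix(x)
  donors <- sort(unique(x$donor_id))
  curves <- list()
  for (d in donors) {
    ia <- which(x$donor_id == d & x$class_label == class_a)
    ib <- which(x$donor_id == d & x$class_label == class_b)
    if (length(ia) == 0 || length(ib) == 0) {
      warn(paste0("donor '", d, "' lacks class ",
                  if (length(ia) == 0) class_a else class_b, "; skipped"))
      next
    }
    delta <- colMeans(m[ib, , drop = FALSE]) - colMeans(m[ia, , drop = FALSE])
    peak <- max(abs(delta))
    curves[[d]] <- if (peak > 0) delta / peak else delta
  }
  if (length(curves) == 0) abort("no donor carries both classes")
  cm <- do.call(rbind, curves)
  withr::local_seed(seed)
  boot <- matrix(NA_real_, n_boot, ncol(cm))
  for (b in seq_len(n_boot)) {
    pick <- sample(nrow(cm), replace = TRUE)
    boot[b, ] <- apply(cm[pick, , drop = FALSE], 2, median)
  }
  tibble(
    wavenumber = wn,
    median = unname(apply(cm, 2, median)),
    boot_lo = unname(apply(boot, 2, quantile, 0.025)),
    boot_hi = unname(apply(boot, 2, quantile, 0.975)),
    q25 = unname(apply(cm, 2, quantile, 0.25)),
    q75 = unname(apply(cm, 2, quantile, 0.75)),
    n_donors = nrow(cm)
  )
}
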