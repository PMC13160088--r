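#' Plot class-mean spectra
#'
#' Mean spectrum per class with a +/- 1 SD ribbon.
#'
#' @param x A spectra table.
#' @return A ggplot object.
#' @export
plot_spectra <- function(x) {
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  wn <- spec_wavenumbers(x)
  df <- lapply(split(seq_len(nrow(x)), x$class_label), function(idx) {
    tibble(wavenumber = wn,
           mean = colMeans(m[idx, , drop = FALSE]),
           sd = apply(m[idx, , drop = FALSE], 2, sd))
  })
  df <- bind_rows(df, .id = "class_label")
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$mean,
                                   color = .data$class_label,
                                   fill = .data$class_label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Normalized intensity", color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a donor-aggregated difference curve
#'
#' @param curve Output of [difference_curves()].
#' @param band `"bootstrap"` (95% band) or `"quartile"` (25--75% range).
#' @return A ggplot object.
#' @export
plot_difference_curve <- function(curve, band = c("bootstrap", "quartile")) {
  band <- match.arg(band)
  lo <- if (band == "bootstrap") curve$boot_lo else curve$q25
  hi <- if (band == "bootstrap") curve$boot_hi else curve$q75
  ggplot2::ggplot(curve, ggplot2::aes(.data$wavenumber, .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Median normalized difference") +
    ggplot2::theme_minimal()
}

#' Plot an embedding
#'
#' @param coords Output of [embed_spectra()].
#' @param color Metadata column mapped to color (default `class_label`).
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, color = "class_label") {
  ggplot2::ggplot(coords, ggplot2::aes(.data$umap1, .data$umap2,
                                       color = .data[[color]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an importance profile
#'
#' @param profile Output of [importance_profile()].
#' @return A ggplot object.
#' @export
plot_importance <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$wavenumber,
                                        .data$mean_importance)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_importance - .data$sd_importance, 0),
      ymax = pmin(.data$mean_importance + .data$sd_importance, 1)),
      alpha = 0.25, fill = "darkorange") +
    ggplot2::geom_line(color = "darkorange3") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Scaled gain importance") +
    ggplot2::theme_minimal()
}

#' Plot band trajectories
#'
#' @param trajectory A [logratio_trajectory()] or [block_bootstrap_ci()]
#'   result.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  p <- ggplot2::ggplot(trajectory,
                       ggplot2::aes(.data$bin_start, .data$value,
                                    color = .data$biochemical_class,
                                    fill = .data$biochemical_class))
  if (all(c("ci_lo", "ci_hi") %in% names(trajectory))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                               ymax = .data$ci_hi),
                                  alpha = 0.2, color = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Time bin start (min)",
                  y = "z-scored log-ratio intensity",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory
#' @param object A `band_trajectory` object.
#' @param ... Ignored.
#' @export
autoplot.band_trajectory <- function(object, ...) plot_trajectory(object)
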