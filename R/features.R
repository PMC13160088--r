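#' Derivative-augmented feature matrix
#'
#' Builds the classifier input from a preprocessed spectra table. With
#' `augment = TRUE` the columns are the concatenation of the normalized
#' intensities and their first- and second-order Savitzky-Golay derivatives
#' (window 11, polynomial order 3), so slope and curvature information can
#' inform classification; with `augment = FALSE` only the intensity block
#' is used (required for interpretable feature-importance profiles). Edge
#' channels are handled by the asymmetric-window polynomial fits of the
#' Savitzky-Golay projection matrix (no padding).
#'
#' @param x A preprocessed spectra table.
#' @param augment Append derivative blocks? (default `TRUE`)
#' @param window Odd Savitzky-Golay window length (default 11).
#' @param polyorder Polynomial order (default 3).
#' @return An object of class `spectra_features`: the feature matrix plus
#'   metadata. Feature names are `i_<wavenumber>`, `d1_<wavenumber>`,
#'   `d2_<wavenumber>`.
#' @export
augment_derivatives <- function(x, augment = TRUE, window = 11L,
                                polyorder = 3L) {
  x <- as_spectra_tbl(x)
  m <- spectra_matrix(x)
  wn <- spec_wavenumbers(x)
  if (window > ncol(m)) abort("Savitzky-Golay window exceeds the channel count")
  wn_lab <- format_wavenumber(wn)
  colnames(m) <- paste0("i_", wn_lab)
  if (augment) {
    dx <- mean(diff(wn))
    d1 <- t(apply(m, 1, function(r) signal::sgolayfilt(r, p = polyorder,
                                                       n = window, m = 1,
                                                       ts = dx)))
    d2 <- t(apply(m, 1, function(r) signal::sgolayfilt(r, p = polyorder,
                                                       n = window, m = 2,
                                                       ts = dx)))
    colnames(d1) <- paste0("d1_", wn_lab)
    colnames(d2) <- paste0("d2_", wn_lab)
    m <- cbind(m, d1, d2)
  }
  structure(list(features = m, meta = spectra_meta(x), wavenumbers = wn,
                 augmented = augment, window = window, polyorder = polyorder),
            class = "spectra_features")
}
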