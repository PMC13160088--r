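#' Vibrational band catalog
#'
#' The default catalog of Raman bands used throughout the package, grouped
#' by biochemical origin: nucleic-acid modes (adenine ring breathing near
#' 728 cm^-1, DNA backbone PO2- stretch near 1095 cm^-1, ...), protein and
#' aromatic modes (phenylalanine ring breathing at 1002 cm^-1, amide III
#' around 1222-1262 cm^-1, amide I/II broadly 1560-1660 cm^-1),
#' mitochondrial cytochrome-c-associated modes (755, 1130, 1310, 1584
#' cm^-1), membrane/lipid headgroup modes, and hemoprotein modes. The
#' `base_amplitude` column sets the relative peak height the synthetic
#' generator assigns to each band in an unmodified cell.
#'
#' @return A tibble with columns `center_cm1`, `width_cm1`,
#'   `biochemical_class`, `base_amplitude`.
#' @export
raman_bands <- function() {
  tibble::tribble(
    ~center_cm1, ~width_cm1, ~biochemical_class, ~base_amplitude,
    719,  20, "MEMBRANE_LIPID",   0.45,
    728,  20, "NUCLEIC_ACID",     1.00,
    755,  20, "MITOCHONDRIAL",    0.55,
    875,  20, "MEMBRANE_LIPID",   0.40,
    898,  20, "PROTEIN_AROMATIC", 0.55,
    964,  20, "NUCLEIC_ACID",     0.45,
    1002, 20, "PROTEIN_AROMATIC", 1.00,
    1025, 20, "PROTEIN_AROMATIC", 0.60,
    1095, 20, "NUCLEIC_ACID",     0.80,
    1128, 20, "HEMOPROTEIN",      0.35,
    1130, 20, "MITOCHONDRIAL",    0.45,
    1222, 20, "PROTEIN_AROMATIC", 0.55,
    1225, 20, "HEMOPROTEIN",      0.30,
    1262, 20, "PROTEIN_AROMATIC", 0.60,
    1310, 20, "MITOCHONDRIAL",    0.50,
    1334, 20, "NUCLEIC_ACID",     0.85,
    1453, 20, "NUCLEIC_ACID",     0.55,
    1460, 20, "MEMBRANE_LIPID",   0.50,
    1567, 20, "HEMOPROTEIN",      0.35,
    1584, 20, "MITOCHONDRIAL",    0.55,
    1602, 20, "PROTEIN_AROMATIC", 0.70,
    1622, 20, "HEMOPROTEIN",      0.30,
    1660, 20, "PROTEIN_AROMATIC", 0.90
  )
}

#' Band panel for time-resolved tracking
#'
#' The 20 cm^-1-wide bands tracked in activation time courses: six
#' protein/aromatic centers (898, 1002, 1025, 1222, 1262, 1602 cm^-1) and
#' three nucleic-acid centers (728, 1092, 1334 cm^-1).
#'
#' @return A tibble with columns `center_cm1`, `width_cm1`,
#'   `biochemical_class`.
#' @export
band_panel <- function() {
  tibble(
    center_cm1 = c(898, 1002, 1025, 1222, 1262, 1602, 728, 1092, 1334),
    width_cm1 = 20,
    biochemical_class = rep(c("PROTEIN_AROMATIC", "NUCLEIC_ACID"), c(6, 3))
  )
}

#' Channels covered by a band
#'
#' Returns the indices of the contiguous channels whose wavenumbers lie in
#' the closed interval `[center - width/2, center + width/2]`.
#'
#' @param center_cm1 Band center (cm^-1).
#' @param width_cm1 Full band width (cm^-1, default 20).
#' @param wavenumbers Numeric axis (strictly increasing).
#' @return Integer vector of channel indices.
#' @examples
#' band_channels(1002, 20, seq(700, 1700))
#' @export
band_channels <- function(center_cm1, width_cm1 = 20, wavenumbers) {
  lo <- center_cm1 - width_cm1 / 2
  hi <- center_cm1 + width_cm1 / 2
  if (lo < min(wavenumbers) || hi > max(wavenumbers)) {
    abort(paste0("band [", lo, ", ", hi, "] cm^-1 lies outside the axis range [",
                 min(wavenumbers), ", ", max(wavenumbers), "]"))
  }
  which(wavenumbers >= lo & wavenumbers <= hi)
}

#' Mean intensity within a band
#'
#' Arithmetic mean of a spectrum-like vector over the channels of one band.
#' For log-ratio trajectories this must be fed a positive representation of
#' the spectra (see [preprocess_spectra()] with `normalize = "total"`).
#'
#' @param y Numeric vector, one value per channel.
#' @inheritParams band_channels
#' @return A scalar.
#' @export
band_intensity <- function(y, center_cm1, width_cm1 = 20, wavenumbers) {
  mean(y[band_channels(center_cm1, width_cm1, wavenumbers)])
}

# Per-spectrum band intensities for a panel: n_spectra x n_bands matrix.
band_intensity_matrix <- function(m, panel, wavenumbers) {
  out <- vapply(seq_len(nrow(panel)), function(i) {
    idx <- band_channels(panel$center_cm1[i], panel$width_cm1[i], wavenumbers)
    rowMeans(m[, idx, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m))
  colnames(out) <- format_wavenumber(panel$center_cm1)
  out
}
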