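#' Spectra tables
#'
#' The central container of the package is an ordinary wide tibble, one row
#' per single-cell spectrum. The first five columns are metadata
#' (`spectrum_id`, `donor_id`, `class_label`, `time_min`, `batch_id`); every
#' remaining column is one wavenumber channel, named by the numeric
#' wavenumber in cm^-1 (printed with up to four decimals). Because the axis
#' lives in the column names, the object survives any dplyr verb; call
#' [as_spectra_tbl()] to re-validate after heavy manipulation.
#'
#' Validation enforces: a strictly increasing axis within 400--3200 cm^-1,
#' finite intensities, unique spectrum ids, and class labels drawn from the
#' fixed vocabulary (`CAR`, `MOCK`, `UNSTIM`, `TCELL`, `BCELL_PRIMARY`,
#' `BCELL_JEKO`, `RBC`, `OTHER`). `time_min` may be `NA` for static
#' experiments; operations that need time reject spectra lacking it.
#'
#' @param x A data frame in the wide layout described above.
#' @return `as_spectra_tbl()` returns a validated tibble with class
#'   `spectra_tbl`; `spec_wavenumbers()` the numeric axis;
#'   `spectra_matrix()` the intensity matrix (rows named by `spectrum_id`).
#' @examples
#' set <- simulate_spectra(simulate_config(n_per_condition = 3),
#'                         classes = "TCELL", donors = "D1")
#' spec_wavenumbers(set)[1:5]
#' dim(spectra_matrix(set))
#' @export
as_spectra_tbl <- function(x) {
  x <- as_tibble(x)
  missing_meta <- setdiff(.meta_cols, names(x))
  if (length(missing_meta) > 0) {
    abort(paste0("missing required metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  wn_names <- setdiff(names(x), .meta_cols)
  if (length(wn_names) == 0) abort("no wavenumber columns found")
  wn <- suppressWarnings(as.numeric(wn_names))
  if (anyNA(wn)) {
    abort(paste0("non-numeric wavenumber column name(s): ",
                 paste(wn_names[is.na(wn)][1:3], collapse = ", ")))
  }
  ord <- order(wn)
  wn <- wn[ord]
  wn_names <- wn_names[ord]
  if (any(diff(wn) <= 0)) abort("wavenumber axis must be strictly increasing")
  if (min(wn) < 400 || max(wn) > 3200) {
    abort("wavenumber axis must lie within [400, 3200] cm^-1")
  }
  x <- x[, c(.meta_cols, wn_names)]
  x$spectrum_id <- as.character(x$spectrum_id)
  x$donor_id <- as.character(x$donor_id)
  x$class_label <- as.character(x$class_label)
  x$batch_id <- as.character(x$batch_id)
  x$time_min <- as.numeric(x$time_min)
  bad_class <- setdiff(unique(x$class_label), .class_levels)
  if (length(bad_class) > 0) {
    abort(paste0("unknown class_label(s): ", paste(bad_class, collapse = ", ")))
  }
  if (anyDuplicated(x$spectrum_id)) {
    dup <- x$spectrum_id[duplicated(x$spectrum_id)][1]
    abort(paste0("duplicate spectrum_id: ", dup))
  }
  if (nrow(x) > 0) {
    m <- as.matrix(x[, wn_names])
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0("non-finite intensity in spectrum '",
                   x$spectrum_id[bad[1, 1]], "'"))
    }
  }
  class(x) <- unique(c("spectra_tbl", class(x)))
  x
}

#' Construct a spectra table from parts
#'
#' @param meta Data frame with the five metadata columns (missing ones other
#'   than `spectrum_id` are filled with defaults).
#' @param intensities Numeric matrix, one row per spectrum.
#' @param wavenumbers Numeric axis, one value per matrix column.
#' @return A validated `spectra_tbl`.
#' @export
new_spectra_tbl <- function(meta, intensities, wavenumbers) {
  meta <- as_tibble(meta)
  if (!is.matrix(intensities)) intensities <- rbind(intensities)
  if (ncol(intensities) != length(wavenumbers)) {
    abort("ncol(intensities) must equal length(wavenumbers)")
  }
  if (nrow(meta) != nrow(intensities)) {
    abort("meta and intensities disagree on the number of spectra")
  }
  if (any(diff(wavenumbers) <= 0)) {
    abort("wavenumber axis must be strictly increasing")
  }
  if (min(wavenumbers) < 400 || max(wavenumbers) > 3200) {
    abort("wavenumber axis must lie within [400, 3200] cm^-1")
  }
  if (!"spectrum_id" %in% names(meta)) {
    meta$spectrum_id <- sprintf("s%04d", seq_len(nrow(meta)))
  }
  if (!"donor_id" %in% names(meta)) meta$donor_id <- "D1"
  if (!"class_label" %in% names(meta)) meta$class_label <- "OTHER"
  if (!"time_min" %in% names(meta)) meta$time_min <- NA_real_
  if (!"batch_id" %in% names(meta)) meta$batch_id <- "B1"
  colnames(intensities) <- format_wavenumber(wavenumbers)
  as_spectra_tbl(bind_cols(meta[, .meta_cols], as_tibble(intensities)))
}

#' @rdname as_spectra_tbl
#' @export
spec_wavenumbers <- function(x) {
  as.numeric(setdiff(names(x), .meta_cols))
}

#' @rdname as_spectra_tbl
#' @export
spectra_matrix <- function(x) {
  wn_names <- setdiff(names(x), .meta_cols)
  m <- as.matrix(x[, wn_names, drop = FALSE])
  rownames(m) <- x$spectrum_id
  storage.mode(m) <- "double"
  m
}

#' @rdname as_spectra_tbl
#' @export
spectra_meta <- function(x) {
  as_tibble(x)[, .meta_cols]
}

# Replace the intensity block, keeping metadata and class.
set_spectra_matrix <- function(x, m) {
  wn_names <- setdiff(names(x), .meta_cols)
  stopifnot(ncol(m) == length(wn_names), nrow(m) == nrow(x))
  x[, wn_names] <- as_tibble(`colnames<-`(m, wn_names))
  x
}

# Print wavenumbers with up to four decimals, trailing zeros stripped.
format_wavenumber <- function(w) {
  out <- sprintf("%.4f", w)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}
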