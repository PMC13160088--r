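#' Read and write spectra tables
#'
#' Two comma-delimited UTF-8 dialects are supported. The *wide* dialect is
#' one file: metadata columns first, then one column per wavenumber, headed
#' by the numeric wavenumber. The *long* dialect is a pair of files: a
#' spectra file with columns `spectrum_id`, `wavenumber`, `intensity`, and a
#' metadata file keyed by `spectrum_id`. Both round-trip bit-exactly for
#' intensities and metadata.
#'
#' @param path File to read or write (the spectra file, for the long dialect).
#' @param format `"wide"` (default) or `"long"`.
#' @param metadata Metadata file path, required for the long dialect.
#' @return `read_spectra()` returns a validated [spectra table][as_spectra_tbl].
#' @examples
#' set <- simulate_spectra(simulate_config(n_per_condition = 2),
#'                         classes = "TCELL", donors = "D1")
#' f <- tempfile(fileext = ".csv")
#' write_spectra(set, f)
#' identical(spectra_matrix(read_spectra(f)), spectra_matrix(set))
#' @export
read_spectra <- function(path, format = c("wide", "long"), metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "wide") {
    x <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(spectrum_id = "character",
                                        donor_id = "character",
                                        class_label = "character",
                                        time_min = "numeric",
                                        batch_id = "character"))
    return(as_spectra_tbl(x))
  }
  if (is.null(metadata)) abort("long format requires a `metadata` file path")
  if (!file.exists(metadata)) abort(paste0("file not found: ", metadata))
  long <- utils::read.csv(path, colClasses = c(spectrum_id = "character",
                                               wavenumber = "numeric",
                                               intensity = "numeric"))
  meta <- as_tibble(utils::read.csv(metadata,
                                    colClasses = c(spectrum_id = "character",
                                                   donor_id = "character",
                                                   class_label = "character",
                                                   time_min = "numeric",
                                                   batch_id = "character")))
  axis <- sort(unique(long$wavenumber))
  # every spectrum must cover the deduplicated axis exactly once
  chan_counts <- table(long$spectrum_id)
  bad <- names(chan_counts)[chan_counts != length(axis)]
  if (length(bad) > 0) {
    abort(paste0("spectrum '", bad[1], "' does not match the shared axis (",
                 chan_counts[bad[1]], " channels, expected ", length(axis), ")"))
  }
  wide <- tidyr::pivot_wider(as_tibble(long), names_from = "wavenumber",
                             values_from = "intensity",
                             names_sort = TRUE)
  if (anyNA(wide)) {
    bad <- wide$spectrum_id[which(rowSums(is.na(wide)) > 0)][1]
    abort(paste0("spectrum '", bad, "' does not match the shared axis"))
  }
  missing_meta <- setdiff(wide$spectrum_id, meta$spectrum_id)
  if (length(missing_meta) > 0) {
    abort(paste0("no metadata for spectrum '", missing_meta[1], "'"))
  }
  out <- left_join(meta, wide, by = "spectrum_id")
  # preserve names in the canonical printed form
  wn <- as.numeric(setdiff(names(out), .meta_cols))
  names(out)[-seq_along(.meta_cols)] <- format_wavenumber(wn)
  as_spectra_tbl(out)
}

#' @param x A spectra table.
#' @rdname read_spectra
#' @export
write_spectra <- function(x, path, format = c("wide", "long"), metadata = NULL) {
  x <- as_spectra_tbl(x)
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.csv(fmt_doubles(as_tibble(x)), path, row.names = FALSE,
                     quote = FALSE, na = "")
    return(invisible(path))
  }
  if (is.null(metadata)) abort("long format requires a `metadata` file path")
  wn <- spec_wavenumbers(x)
  m <- spectra_matrix(x)
  long <- tibble(
    spectrum_id = rep(rownames(m), each = length(wn)),
    wavenumber = rep(wn, times = nrow(m)),
    intensity = as.vector(t(m))
  )
  if (nrow(x) == 0) {
    long <- tibble(spectrum_id = character(), wavenumber = double(),
                   intensity = double())
  }
  utils::write.csv(fmt_doubles(long), path, row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(fmt_doubles(spectra_meta(x)), metadata, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

# print doubles with 17 significant digits so every value round-trips
# bit-exactly through the text dialects (time_min and wavenumber columns
# keep their natural short form when exact)
fmt_doubles <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- df[[j]]
      out <- sprintf("%.17g", v)
      short <- sprintf("%.15g", v)
      exact <- !is.na(v) & suppressWarnings(as.numeric(short)) == v
      exact[is.na(exact)] <- FALSE
      out[exact] <- short[exact]
      out[is.na(v)] <- NA_character_
      df[[j]] <- out
    }
  }
  df
}
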