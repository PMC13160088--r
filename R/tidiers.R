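#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a fitted spectral classifier
#'
#' `tidy()` returns one row per cross-validation fold; `glance()` one row
#' summarizing the whole report.
#'
#' @param x A `spectra_classifier`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.spectra_classifier <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracy), accuracy = x$fold_accuracy)
}

#' @rdname tidy.spectra_classifier
#' @export
glance.spectra_classifier <- function(x, ...) {
  tibble(cv_accuracy = x$cv_accuracy, test_accuracy = x$test_accuracy,
         auc = x$auc, nrounds = x$nrounds,
         n_train = length(x$train_ids), n_test = length(x$test_ids),
         n_classes = length(x$classes), augmented = x$augmented)
}

#' Tidy a pseudotime result
#'
#' `tidy()` returns the per-spectrum table (pseudotime, component
#' membership); `glance()` the spectrum- and bin-level Spearman
#' correlations with real time in one row.
#'
#' @param x A `pseudotime_result`.
#' @param binning A [time_bins()] object used by `glance()`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.pseudotime_result <- function(x, ...) {
  x$cells
}

#' @rdname tidy.pseudotime_result
#' @export
glance.pseudotime_result <- function(x, binning = time_bins(), ...) {
  tc <- time_correlation(x, binning)
  tibble(
    n_cells = nrow(x$cells), n_in_component = sum(x$cells$in_component),
    root_id = x$root_id,
    rho_spectrum = tc$rho[tc$level == "spectrum"],
    rho_bin = tc$rho[tc$level == "bin"],
    p_spectrum = tc$p_value[tc$level == "spectrum"],
    p_bin = tc$p_value[tc$level == "bin"]
  )
}

#' @export
print.spectra_classifier <- function(x, ...) {
  cat("<spectra_classifier> ", paste(x$classes, collapse = " vs "), "\n",
      sep = "")
  cat(sprintf("  %d-fold CV accuracy: %.3f\n", length(x$fold_accuracy),
              x$cv_accuracy))
  if (!is.na(x$auc)) cat(sprintf("  held-out AUC: %.3f\n", x$auc))
  cat(sprintf("  train/test: %d/%d spectra, %s features\n",
              length(x$train_ids), length(x$test_ids),
              if (x$augmented) "derivative-augmented" else "intensity-only"))
  invisible(x)
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat("<pseudotime_result> ", nrow(x$cells), " spectra, ",
      sum(x$cells$in_component), " in the largest component\n", sep = "")
  cat("  root:", x$root_id, "\n")
  invisible(x)
}
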