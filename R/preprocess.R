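#' Interquartile-range denoising of a peak table
#'
#' GC-MS peak lists contain entries whose intensity barely varies across all
#' samples; these carry no group information and inflate multiple testing.
#' The screen drops (1) every analyte whose across-sample IQR is exactly
#' zero, then (2) analytes whose IQR falls strictly below the `quantile_cut`
#' quantile of the remaining (nonzero) IQR distribution. Quartiles use the
#' linear-interpolation convention (R type 7), recorded in the report.
#'
#' @param table a [peak_table()].
#' @param quantile_cut fraction in `[0, 1)`; the default 0 removes only
#'   zero-spread analytes, so no genuine signal is discarded silently.
#' @param threshold optional absolute IQR threshold; when given it overrides
#'   `quantile_cut`. Re-running with the `threshold_used` recorded in a
#'   previous report is idempotent.
#' @return list with elements `table` (retained analytes, original order) and
#'   `report` (a `denoise_report`: `n_input_peaks`, `n_retained`,
#'   `dropped_ids`, `threshold_used`, `quartile_type`).
#' @examples
#' pt <- peak_table(matrix(c(rep(1, 6), rexp(6)), 2, 6, byrow = TRUE,
#'                         dimnames = list(c("flat", "varying"), paste0("s", 1:6))),
#'                  setNames(rep(c("W", "P"), 3), paste0("s", 1:6)))
#' iqr_denoise(pt)$report$dropped_ids  # "flat"
#' @export
iqr_denoise <- function(table, quantile_cut = 0, threshold = NULL) {
  stopifnot(inherits(table, "omics_table"))
  if (!is.numeric(quantile_cut) || quantile_cut < 0 || quantile_cut >= 1)
    stop("parameter error: quantile_cut must lie in [0, 1)", call. = FALSE)
  if (ncol(table$intensities) < 4L)
    stop("design error: IQR denoising needs at least 4 samples", call. = FALSE)
  iqr <- apply(table$intensities, 1L, stats::IQR, na.rm = TRUE, type = 7)
  drop <- iqr == 0
  if (is.null(threshold)) {
    threshold <- 0
    nonzero <- iqr[!drop]
    if (quantile_cut > 0 && length(nonzero))
      threshold <- unname(stats::quantile(nonzero, quantile_cut, type = 7))
  }
  drop <- drop | iqr < threshold
  report <- structure(
    list(n_input_peaks = nrow(table$intensities),
         n_retained = sum(!drop),
         dropped_ids = rownames(table$intensities)[drop],
         threshold_used = threshold,
         quartile_type = 7L),
    class = "denoise_report")
  list(table = table[!drop, ], report = report)
}

#' @export
print.denoise_report <- function(x, ...) {
  cat(sprintf("IQR denoising: %d peaks in, %d retained, %d dropped (IQR threshold %.4g, type-%d quartiles)\n",
              x$n_input_peaks, x$n_retained, length(x$dropped_ids),
              x$threshold_used, x$quartile_type))
  invisible(x)
}

#' Normalize a peak table to its internal standard
#'
#' Divides every intensity by the internal-standard intensity of the same
#' sample (run-to-run injection/derivatization correction), then removes the
#' internal-standard analyte from the table. The per-sample IS vector is kept
#' as attribute `is_vector` so the scaling is invertible.
#'
#' @param table a [peak_table()].
#' @param is_id analyte id of the internal standard; must be observed with
#'   strictly positive intensity in every sample.
#' @return normalized `peak_table` without the internal-standard row.
#' @export
normalize_internal_standard <- function(table, is_id) {
  stopifnot(inherits(table, "omics_table"))
  if (!is_id %in% rownames(table$intensities))
    stop("normalization error: internal standard '", is_id,
         "' not present in table", call. = FALSE)
  is_vec <- table$intensities[is_id, ]
  bad <- is.na(is_vec) | is_vec <= 0
  if (any(bad))
    stop("normalization error: internal standard missing or non-positive in sample(s): ",
         paste(names(is_vec)[bad], collapse = ", "), call. = FALSE)
  out <- table[setdiff(rownames(table$intensities), is_id), ]
  out$intensities <- sweep(out$intensities, 2L, is_vec, "/")
  attr(out, "is_vector") <- is_vec
  out
}

#' Impute missing peak intensities
#'
#' GC-MS missingness is predominantly left-censoring (peaks below the
#' detection limit), so the default replaces each missing cell with half the
#' analyte's minimum observed intensity. `method = "none"` leaves missing
#' values in place and flags the affected analytes as ineligible for
#' two-sample testing (attribute `test_ineligible`).
#'
#' @param table a [peak_table()].
#' @param method "half_min" or "none".
#' @return imputed `peak_table`.
#' @export
impute_missing <- function(table, method = c("half_min", "none")) {
  stopifnot(inherits(table, "omics_table"))
  method <- match.arg(method)
  m <- table$intensities
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing))
    stop("imputation error: analyte(s) with no observed value: ",
         paste(rownames(m)[all_missing], collapse = ", "), call. = FALSE)
  if (method == "none") {
    attr(table, "test_ineligible") <- rownames(m)[rowSums(is.na(m)) > 0L]
    return(table)
  }
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss)) {
    half_min <- apply(m, 1L, min, na.rm = TRUE) / 2
    m[miss] <- half_min[miss[, "row"]]
    table$intensities <- m
  }
  table
}
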