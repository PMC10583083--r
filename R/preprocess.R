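# Gene filtering applied before testing: drop genes that are not
# expressed, and genes with only small variability across samples.

new_filter_report <- function(n_in, n_unexpr, n_lowvar, thresholds) {
  structure(list(n_input_genes = n_in,
                 n_removed_unexpressed = n_unexpr,
                 n_removed_low_variability = n_lowvar,
                 n_output_genes = n_in - n_unexpr - n_lowvar,
                 thresholds = thresholds),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Gene filter report\n")
  cat("  input genes:            ", x$n_input_genes, "\n")
  cat("  removed (unexpressed):  ", x$n_removed_unexpressed, "\n")
  cat("  removed (low variance): ", x$n_removed_low_variability, "\n")
  cat("  output genes:           ", x$n_output_genes, "\n")
  thr <- x$thresholds
  cat("  thresholds:", paste(names(thr), signif(unlist(thr), 4),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Remove unexpressed genes
#'
#' Keeps genes with at least `min_samples_above` samples strictly above
#' an intensity floor.  The default floor is data-driven: the 5th
#' percentile of the whole matrix plus 0.5 log2 units, which tracks the
#' chip's background level without a platform-specific constant.
#'
#' @param matrix Genes x samples log2 matrix.
#' @param floor Log2 intensity floor; `NULL` for the data-driven
#'   default.
#' @param min_samples_above Minimum samples strictly above the floor.
#' @return List with `matrix` (filtered, order preserved) and `report`
#'   (a `filter_report`).
#' @export
filter_unexpressed <- function(matrix, floor = NULL, min_samples_above = 2) {
  validate_expression_matrix(matrix)
  if (min_samples_above > ncol(matrix))
    stop("min_samples_above exceeds the number of samples")
  if (is.null(floor))
    floor <- stats::quantile(matrix, 0.05, names = FALSE) + 0.5
  keep <- rowSums(matrix > floor) >= min_samples_above
  report <- new_filter_report(nrow(matrix), sum(!keep), 0L,
                              list(floor = floor,
                                   min_samples_above = min_samples_above))
  out <- matrix[keep, , drop = FALSE]
  attr(out, "is_log2") <- attr(matrix, "is_log2")
  list(matrix = out, report = report)
}

#' Remove low-variability genes
#'
#' Removes genes whose across-sample variance (unbiased, n-1
#' denominator) falls strictly below the given empirical quantile of
#' all gene variances.  Zero-variance genes are always removed, even at
#' quantile 0, because downstream z-scoring is undefined for them.
#'
#' The quantile resolves to an absolute variance cutoff on the input
#' matrix; the cutoff is recorded in the report, and re-applying the
#' filter with that recorded cutoff is the identity (idempotence holds
#' at the level of resolved thresholds, not of the quantile, whose
#' reference distribution shrinks after filtering).
#'
#' @param matrix Genes x samples log2 matrix.
#' @param variance_quantile Fraction in [0, 1).
#' @param variance_cutoff Absolute variance cutoff; when given,
#'   `variance_quantile` is ignored.
#' @return List with `matrix` and `report` as in
#'   [filter_unexpressed()].
#' @export
filter_low_variability <- function(matrix, variance_quantile = 0.10,
                                   variance_cutoff = NULL) {
  validate_expression_matrix(matrix)
  if (variance_quantile >= 1 || variance_quantile < 0)
    stop("variance_quantile must lie in [0, 1)")
  if (ncol(matrix) < 2) stop("need at least 2 samples")
  v <- row_vars(matrix)
  cut <- if (is.null(variance_cutoff))
    stats::quantile(v, variance_quantile, names = FALSE)
  else variance_cutoff
  keep <- v >= cut & v > 0
  report <- new_filter_report(nrow(matrix), 0L, sum(!keep),
                              list(variance_quantile = variance_quantile,
                                   variance_cutoff = cut))
  out <- matrix[keep, , drop = FALSE]
  attr(out, "is_log2") <- attr(matrix, "is_log2")
  list(matrix = out, report = report)
}
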