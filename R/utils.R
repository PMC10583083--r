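# Internal helpers shared across modules.

#' The dendritic-cell population labels used throughout the package
#'
#' Five populations: the two skin dermal DC subsets (CD141+ and CD1c+
#' DDCs) and three blood monocyte-derived DC conditions (untreated moDC
#' and the CD141-high / CD141-low fractions of vitamin-D3-treated moDC).
#'
#' @return Character vector of the five population labels.
#' @export
study_populations <- function() {
  c("CD141+DDC", "CD1c+DDC", "moDC", "CD141hi_VitD3_moDC", "CD141lo_VitD3_moDC")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-stage substream seed from one global seed so stages can
# be regenerated independently; kept within 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(matrix = 1L, sets = 2L, ct = 3L, svm = 4L, pipeline = 5L)
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

# Validate a genes x samples log2 expression matrix.
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop(what, " has duplicate gene ids")
  if (anyDuplicated(colnames(x)))
    stop(what, " has duplicate sample ids")
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values; resolve missing data at load time")
  invisible(x)
}

# Row variances with the unbiased (n-1) estimator, no apply() overhead.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("need at least 2 samples to compute variances")
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
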