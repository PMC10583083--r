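# Pathway-level inference: per-gene z-transform, combined z-score
# activity with sqrt(k) variance stabilisation, reference-anchored
# subset Z-scores, SVM ranking of discriminative pathways, and a local
# hypergeometric over-representation test.

#' Z-transform every gene across samples
#'
#' `z_gj = (g_gj - mean_g) / sd_g` with the unbiased (n-1) SD, taken
#' across all samples jointly.  Zero-variance genes are an error: they
#' belong to the preprocessing filters, not here.
#'
#' @param matrix Genes x samples log2 matrix.
#' @return Matrix of the same shape; every row has mean 0 and SD 1.
#' @export
zscore_genes <- function(matrix) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2) stop("need at least 2 samples")
  v <- row_vars(matrix)
  if (any(v == 0))
    stop("zero-variance gene(s) present (",
         paste(utils::head(rownames(matrix)[v == 0], 3), collapse = ", "),
         "); run filter_low_variability first")
  (matrix - rowMeans(matrix)) / sqrt(v)
}

#' Pathway activity matrix from z-scores
#'
#' For pathway P with member genes present in the matrix `G_P`
#' (`k = |G_P|`), the activity in sample j is
#' `a_j = sum(z_gj, g in G_P) / sqrt(k)`: the combined z-score, with
#' the square root of the member count as denominator to stabilise the
#' variance of the mean.  Pathways matching fewer than `min_genes`
#' genes are dropped and reported via [message()].
#'
#' @param z Z-matrix from [zscore_genes()].
#' @param catalog `gene_set_catalog`.
#' @param min_genes Minimum matched genes per retained pathway
#'   (default 5).
#' @return Pathways x samples numeric matrix with attribute `k`
#'   (named integer vector of matched gene counts).
#' @export
pathway_activity <- function(z, catalog, min_genes = 5) {
  validate_expression_matrix(z, "z-matrix")
  if (!inherits(catalog, "gene_set_catalog")) stop("catalog must be a gene_set_catalog")
  members <- lapply(catalog, function(s) intersect(s$genes, rownames(z)))
  k <- vapply(members, length, 1L)
  keep <- k >= min_genes
  if (!any(keep)) stop("no pathway matches >= ", min_genes, " genes in the matrix")
  if (any(!keep))
    message(sum(!keep), " pathway(s) dropped with fewer than ", min_genes,
            " matched genes")
  act <- t(vapply(members[keep], function(g)
    colSums(z[g, , drop = FALSE]) / sqrt(length(g)),
    numeric(ncol(z))))
  rownames(act) <- names(catalog)[keep]
  attr(act, "k") <- k[keep]
  act
}

#' Population-level pathway Z-scores anchored to a reference
#'
#' Per pathway, activities are standardised by the reference
#' population's mean and SD; the table entry for each population is
#' the mean standardised activity over its samples.  The reference
#' population's entry is therefore 0 by construction, and populations
#' with entries close to 0 resemble the reference for that pathway,
#' while large |Z| marks strong divergence.  Pathways whose reference
#' SD is zero are returned as `NA` and flagged.
#'
#' @param activity Pathways x samples matrix from [pathway_activity()].
#' @param annotation Sample annotation data.frame.
#' @param reference Reference population label (>= 2 samples).
#' @return Pathways x populations matrix of class `"subset_zscores"`
#'   with attributes `reference` and `undefined` (pathway names with
#'   zero reference SD).
#' @export
subset_zscores <- function(activity, annotation, reference) {
  if (!reference %in% annotation$population)
    stop("reference population not in annotation: ", reference)
  pops <- unique(annotation$population)
  ref_samples <- intersect(colnames(activity),
                           annotation$sample_id[annotation$population == reference])
  if (length(ref_samples) < 2)
    stop("reference population needs >= 2 samples in the activity matrix")
  ref <- activity[, ref_samples, drop = FALSE]
  mu <- rowMeans(ref)
  sd_ <- sqrt(row_vars(ref))
  undefined <- rownames(activity)[sd_ == 0]
  std <- (activity - mu) / ifelse(sd_ == 0, NA_real_, sd_)
  out <- vapply(pops, function(p) {
    s <- intersect(colnames(activity),
                   annotation$sample_id[annotation$population == p])
    rowMeans(std[, s, drop = FALSE])
  }, numeric(nrow(activity)))
  out <- matrix(out, nrow = nrow(activity),
                dimnames = list(rownames(activity), pops))
  structure(out, reference = reference, undefined = undefined,
            class = c("subset_zscores", class(out)))
}

#' Rank pathways by linear-SVM discrimination
#'
#' Fits one-vs-rest linear maximum-margin classifiers (one binary
#' machine per population) on the standardised pathway-activity
#' features and scores each pathway by the sum over classes of its
#' squared primal weight.  Ranking is by descending score with
#' lexicographic pathway-name tie-break, and is deterministic given
#' the seed.
#'
#' @param activity Pathways x samples matrix.
#' @param annotation Sample annotation data.frame.
#' @param seed RNG seed (libsvm training is seeded for
#'   reproducibility).
#' @param cost Soft-margin regularisation constant (default 1).
#' @return data.frame of class `"pathway_ranking"`: `pathway`,
#'   `score`, `rank`; attribute `seed`.
#' @export
svm_rank_pathways <- function(activity, annotation, seed = 1, cost = 1) {
  ann <- annotation[match(colnames(activity), annotation$sample_id), ]
  if (any(is.na(ann$sample_id)))
    stop("activity samples missing from annotation")
  y <- factor(ann$population)
  if (nlevels(y) < 2) stop("need at least 2 populations to rank pathways")
  if (any(table(y) < 2)) stop("every population needs >= 2 samples")
  x <- t(activity)
  # standardise features; constant features carry no signal, weight 0
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  x <- sweep(sweep(x, 2, mu), 2, ifelse(sd_ == 0, 1, sd_), "/")
  w2 <- numeric(ncol(x))
  with_seed(stage_seed(seed, "svm"), {
    for (lev in levels(y)) {
      yy <- factor(ifelse(y == lev, lev, "rest"), levels = c(lev, "rest"))
      fit <- e1071::svm(x, yy, kernel = "linear", cost = cost, scale = FALSE)
      w <- crossprod(fit$coefs, fit$SV)[1, ]
      w2 <- w2 + w^2
    }
  })
  ord <- order(-w2, colnames(x))
  out <- data.frame(pathway = colnames(x)[ord], score = w2[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("pathway_ranking", "data.frame")
  out
}

#' Hypergeometric over-representation of a signature in gene sets
#'
#' For each catalog set, tests whether the signature's overlap with the
#' set is larger than expected when drawing `|signature|` genes from
#' the universe without replacement: the upper hypergeometric tail
#' P(X >= observed).  Benjamini-Hochberg q-values are reported across
#' sets.  A local stand-in for web-service enrichment tools.
#'
#' @param signature A `gene_signature`, or a character vector of genes.
#' @param catalog `gene_set_catalog`.
#' @param universe Character vector: the tested gene universe
#'   (signature must be a subset; sets are intersected with it).
#' @return data.frame: `set`, `set_size`, `overlap`, `expected`,
#'   `p_value`, `q_value`, ordered by p.
#' @export
overrepresentation <- function(signature, catalog, universe) {
  genes <- if (inherits(signature, "gene_signature"))
    c(signature$up_genes, signature$down_genes) else signature
  genes <- unique(genes)
  if (anyDuplicated(universe)) universe <- unique(universe)
  extra <- setdiff(genes, universe)
  if (length(extra) > 0)
    stop("signature genes outside the universe: ",
         paste(utils::head(extra, 3), collapse = ", "))
  n_univ <- length(universe)
  n_sig <- length(genes)
  rows <- lapply(catalog, function(s) {
    set_in <- intersect(s$genes, universe)
    K <- length(set_in)
    ov <- length(intersect(genes, set_in))
    p <- if (K == 0) 1 else
      stats::phyper(ov - 1, K, n_univ - K, n_sig, lower.tail = FALSE)
    data.frame(set = s$name, set_size = K, overlap = ov,
               expected = n_sig * K / n_univ, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value, out$set), ]
}
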