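# Bidirectional hierarchical clustering of an expression submatrix:
# correlation distances on both axes, agglomerative trees, and the
# leaf orders used to render the heatmap.

#' Correlation distance between genes or samples
#'
#' `d = 1 - Pearson r`, so d is 0 for identical profiles and 2 for
#' perfect anti-correlation.  Items with zero variance have no defined
#' correlation and must be filtered out beforehand.
#'
#' @param matrix Genes x samples matrix.
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @return `dist` object over the chosen axis, in input order.
#' @export
correlation_distance <- function(matrix, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  x <- if (axis == "genes") t(matrix) else matrix
  if (ncol(x) < 2) stop("need at least 2 items on the ", axis, " axis")
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance ", axis, " present (",
         paste(utils::head(colnames(x)[v == 0], 3), collapse = ", "),
         "); filter before clustering")
  d <- 1 - stats::cor(x)
  stats::as.dist(d)
}

#' Agglomerative hierarchical clustering
#'
#' Thin wrapper over [stats::hclust()] restricted to the monotone
#' linkages used for expression heatmaps, with input validation: a
#' square numeric matrix is accepted if symmetric with zero diagonal.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return `hclust` object (merge list, heights, leaf order).
#' @export
hierarchical_cluster <- function(dist, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(dist)) {
    if (nrow(dist) != ncol(dist) || !isSymmetric(unname(dist), tol = 1e-10))
      stop("distance matrix must be square and symmetric")
    if (any(abs(diag(dist)) > 1e-12))
      stop("distance matrix must have a zero diagonal")
    dist <- stats::as.dist(dist)
  }
  if (!inherits(dist, "dist")) stop("dist must be a dist object or matrix")
  stats::hclust(dist, method = linkage)
}

#' Bidirectional clustering of an expression matrix
#'
#' Clusters genes on correlation distance between raw log2 rows, and
#' samples on correlation distance between per-gene z-scored columns
#' (the standard expression-heatmap convention: row standardisation
#' keeps highly expressed genes from dominating the sample tree).
#'
#' @param matrix Genes x samples matrix; both axes must be free of
#'   zero-variance items.
#' @param linkage Linkage method for both axes.
#' @return List with `gene_order`, `sample_order` (leaf orders as
#'   labels), `gene_dendrogram`, `sample_dendrogram` (hclust), and the
#'   row-scaled matrix `scaled` used for display.
#' @export
bicluster_order <- function(matrix, linkage = "average") {
  validate_expression_matrix(matrix)
  z <- zscore_genes(matrix)
  gd <- hierarchical_cluster(correlation_distance(matrix, "genes"), linkage)
  sd_ <- hierarchical_cluster(correlation_distance(z, "samples"), linkage)
  list(gene_order = rownames(matrix)[gd$order],
       sample_order = colnames(matrix)[sd_$order],
       gene_dendrogram = gd, sample_dendrogram = sd_, scaled = z)
}

#' Serialise a dendrogram as a Newick string
#'
#' @param hc An `hclust` object.
#' @param digits Significant digits for branch lengths.
#' @return Newick string (leaf labels, branch lengths from merge
#'   heights), terminated with a semicolon.
#' @export
dendrogram_newick <- function(hc, digits = 6) {
  labels <- hc$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(hc$merge) + 1))
  rec <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%s", labels[-node], signif(parent_height, digits))
    } else {
      h <- hc$height[node]
      left <- rec(hc$merge[node, 1], h)
      right <- rec(hc$merge[node, 2], h)
      sprintf("(%s,%s):%s", left, right, signif(parent_height - h, digits))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  sprintf("(%s,%s);", rec(hc$merge[root, 1], h), rec(hc$merge[root, 2], h))
}
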