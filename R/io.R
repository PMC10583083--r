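# Readers and writers for the tabular and gene-set formats every stage
# touches: expression matrices (TSV/CSV), sample annotations, GMT gene
# sets, qPCR Ct tables, and a generic TSV round-trip writer.

#' Read a genes x samples expression matrix
#'
#' The first column holds gene identifiers, the header row sample
#' identifiers, and the body numeric log2 intensities.  Duplicate gene
#' rows (e.g. several probes summarising one gene) are collapsed by the
#' per-sample maximum — the brightest-probe rule — and the collapse is
#' reported via [message()].  Missing values are a load-time error by
#' default; `na_policy = "drop_gene"` instead removes every gene row
#' containing a missing value.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param na_policy `"error"` (default) or `"drop_gene"`.
#' @return Numeric matrix (genes x samples) with `is_log2` attribute.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv"),
                                   na_policy = c("error", "drop_gene")) {
  dialect <- match.arg(dialect)
  na_policy <- match.arg(na_policy)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene-id column and >=1 sample")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                  dimnames = list(NULL, samples)))
  missing_cell <- is.na(body) | body %in% c("NA", "", "na", "NaN")
  bad <- which(is.na(vals) & !missing_cell, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 body[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 samples[bad[1, 2]]))
  miss <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    if (na_policy == "error")
      stop(sprintf("missing value at gene '%s', sample '%s'",
                   genes[miss[1, 1]], samples[miss[1, 2]]))
    drop <- unique(miss[, 1])
    message(length(drop), " gene row(s) dropped under na_policy='drop_gene'")
    vals <- vals[-drop, , drop = FALSE]
    genes <- genes[-drop]
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing ", length(dup),
            " duplicated gene id(s) by per-sample maximum: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    keep_order <- unique(genes)
    vals <- do.call(rbind, lapply(keep_order, function(g) {
      rows <- vals[genes == g, , drop = FALSE]
      apply(rows, 2, max)
    }))
    genes <- keep_order
  }
  rownames(vals) <- genes
  attr(vals, "is_log2") <- TRUE
  validate_expression_matrix(vals)
  vals
}

#' Read a GMT gene-set catalog
#'
#' Standard MSigDB interchange format: one set per line,
#' `name TAB description TAB gene TAB gene ...`.  Genes are stored as a
#' set (duplicates within a line dropped, order irrelevant); line order
#' of the catalog is preserved.  Matching downstream is case-sensitive.
#'
#' @param path Path to a .gmt file.
#' @return Named list of gene-set objects, each a list with `name`,
#'   `description` and `genes` (character vector); class
#'   `"gene_set_catalog"`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("GMT line ", i, " has an empty gene set")
    nm[i] <- fields[1]
    sets[[i]] <- list(name = fields[1], description = fields[2], genes = genes)
  }
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  structure(sets, class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat("Gene-set catalog:", length(x), "sets; set sizes",
      paste(range(vapply(x, function(s) length(s$genes), 1L)), collapse = "-"),
      "\n")
  invisible(x)
}

#' Write a gene-set catalog as GMT
#'
#' @param catalog A `gene_set_catalog`.
#' @param path Output path.
#' @export
write_gene_sets <- function(catalog, path) {
  lines <- vapply(catalog, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with required columns `sample_id`, `population`, `donor_id`,
#' `replicate`.  Population labels outside `allowed_populations` are
#' rejected so contrast definitions cannot silently reference samples
#' that do not exist.
#'
#' @param path Path to the TSV.
#' @param allowed_populations Character vector of legal labels; defaults
#'   to [study_populations()].  Pass `NULL` to accept any label.
#' @return `data.frame` with the four columns, validated.
#' @export
read_sample_annotation <- function(path,
                                   allowed_populations = study_populations()) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_annotation(ann, allowed_populations)
}

validate_sample_annotation <- function(ann,
                                       allowed_populations = study_populations()) {
  required <- c("sample_id", "population", "donor_id", "replicate")
  missing <- setdiff(required, colnames(ann))
  if (length(missing) > 0)
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  if (!is.null(allowed_populations)) {
    unknown <- setdiff(unique(ann$population), allowed_populations)
    if (length(unknown) > 0)
      stop("unknown population label(s): ", paste(unknown, collapse = ", "),
           " (pass allowed_populations to override)")
  }
  ann$replicate <- as.integer(ann$replicate)
  if (any(is.na(ann$replicate)) || any(ann$replicate < 1))
    stop("replicate must be an integer >= 1")
  ann
}

#' Write a pipeline table as TSV
#'
#' Writes any of the pipeline's tabular outputs (data.frame or matrix
#' with row names) so that [read_tabular()] reproduces it bit-exactly
#' for integer and character columns and to at least 12 significant
#' digits for reals (values are printed with 15 significant digits).
#'
#' @param result data.frame, or matrix whose row names become the first
#'   column.
#' @param path Output path (must not be a directory).
#' @param rowname_col Column name for matrix row names.
#' @export
write_tabular <- function(result, path, rowname_col = "id") {
  if (dir.exists(path)) stop("path is a directory: ", path)
  if (is.matrix(result)) {
    df <- data.frame(rownames(result), result, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- rowname_col
    result <- df
  }
  if (!is.data.frame(result)) stop("result is not a tabular pipeline output")
  out <- result
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a table written by [write_tabular()]
#'
#' @param path Path to the TSV.
#' @return data.frame with numeric columns restored.
#' @export
read_tabular <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a qPCR Ct table
#'
#' Wide TSV: `sample_id`, `condition`, then one numeric Ct column per
#' gene (housekeeping gene included as a column).
#'
#' @param path Path to the TSV.
#' @return data.frame of class `"ct_table"`.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_ct_table(ct)
}

validate_ct_table <- function(ct) {
  if (!all(c("sample_id", "condition") %in% colnames(ct)))
    stop("Ct table needs sample_id and condition columns")
  if (anyDuplicated(ct$sample_id)) stop("duplicate sample_id in Ct table")
  genes <- setdiff(colnames(ct), c("sample_id", "condition"))
  if (length(genes) == 0) stop("Ct table has no gene columns")
  vals <- as.matrix(ct[, genes, drop = FALSE])
  if (!is.numeric(vals) || !all(is.finite(vals)) || any(vals <= 0))
    stop("Ct values must be finite and positive")
  class(ct) <- c("ct_table", "data.frame")
  ct
}
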