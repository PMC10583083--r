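# End-to-end orchestration: simulate or load -> filter -> pairwise DE
# -> core module -> bicluster -> pathway activity -> subset Z-scores
# -> SVM ranking, from a single config, with every threshold recorded
# in a run manifest.

#' Pipeline configuration
#'
#' Bundles the inputs (a [synthetic_config()] or in-memory data), the
#' two ordered contrasts of the pairwise design, every stage threshold,
#' the reference population for subset Z-scores, and the seed.
#'
#' @param synthetic A `synthetic_config`, or `NULL` when `data` is
#'   supplied.
#' @param data Optional list with `expression`, `annotation`,
#'   `catalog` (as returned by the readers) used instead of
#'   simulation.
#' @param contrasts List of two character pairs
#'   `c(group_a, group_b)`; defaults to the study design
#'   (CD141+DDC vs CD1c+DDC, CD141hi_VitD3_moDC vs moDC).
#' @param reference Reference population for subset Z-scores
#'   (default `"CD141+DDC"`).
#' @param p_threshold,fch_threshold Signature gates (defaults 0.05,
#'   1.5).
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @param expression_floor,min_samples_above,variance_quantile Filter
#'   thresholds (see [filter_unexpressed()],
#'   [filter_low_variability()]).
#' @param min_genes Minimum matched genes per pathway.
#' @param svm_cost SVM regularisation constant.
#' @param seed Global seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            data = NULL,
                            contrasts = list(c("CD141+DDC", "CD1c+DDC"),
                                             c("CD141hi_VitD3_moDC", "moDC")),
                            reference = "CD141+DDC",
                            p_threshold = 0.05, fch_threshold = 1.5,
                            variant = "pooled",
                            expression_floor = NULL, min_samples_above = 2,
                            variance_quantile = 0.10,
                            min_genes = 5, svm_cost = 1, seed = 1) {
  if (is.null(synthetic) && is.null(data))
    stop("provide a synthetic config or in-memory data")
  if (length(contrasts) != 2 || !all(lengths(contrasts) == 2))
    stop("contrasts must be a list of two (group_a, group_b) pairs")
  if (p_threshold <= 0 || fch_threshold < 1)
    stop("thresholds out of bounds: need p_threshold > 0, fch_threshold >= 1")
  if (variance_quantile < 0 || variance_quantile >= 1)
    stop("variance_quantile must lie in [0, 1)")
  # one global seed: the pipeline seed overrides the simulator's own
  if (!is.null(synthetic)) synthetic$seed <- seed
  structure(list(synthetic = synthetic, data = data, contrasts = contrasts,
                 reference = reference, p_threshold = p_threshold,
                 fch_threshold = fch_threshold, variant = variant,
                 expression_floor = expression_floor,
                 min_samples_above = min_samples_above,
                 variance_quantile = variance_quantile,
                 min_genes = min_genes, svm_cost = svm_cost, seed = seed),
            class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Executes simulate/load, unexpressed- and low-variability filtering,
#' both pairwise differential-expression contrasts, the directional
#' core-module intersection, bidirectional clustering of the
#' core-module submatrix, pathway-activity scoring, reference-anchored
#' subset Z-scores, and SVM pathway ranking.  The run is fully
#' determined by the config (same config + seed, same bundle).
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, every stage table
#'   is written as TSV plus a JSON-like run manifest.
#' @return Object of class `"coresig_run"`: list with `expression`
#'   (filtered), `annotation`, `filter_reports`, `stats` (two
#'   `gene_stats`), `signatures`, `core_module`, `clustering`,
#'   `activity`, `subset_z`, `ranking`, `truth` (when simulated),
#'   `config`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  pre_flight(config)
  if (is.null(config$data)) {
    ds <- generate_dataset(config$synthetic)
  } else {
    ds <- config$data
    ds$truth <- NULL
    validate_expression_matrix(ds$expression)
    ds$annotation <- validate_sample_annotation(ds$annotation, NULL)
  }

  f1 <- filter_unexpressed(ds$expression, config$expression_floor,
                           config$min_samples_above)
  f2 <- filter_low_variability(f1$matrix, config$variance_quantile)
  expr <- f2$matrix

  stats_list <- lapply(config$contrasts, function(cc)
    two_group_stats(expr, ds$annotation, cc[1], cc[2], config$variant))
  sigs <- lapply(stats_list, call_signature, p_threshold = config$p_threshold,
                 fch_threshold = config$fch_threshold)
  core <- intersect_signatures(sigs[[1]], sigs[[2]])

  clustering <- NULL
  cg <- core_genes(core)
  if (length(cg) >= 2) {
    sub <- expr[cg, , drop = FALSE]
    clustering <- tryCatch(bicluster_order(sub),
                           error = function(e) {
                             warning("core-module clustering skipped: ",
                                     conditionMessage(e))
                             NULL
                           })
  }

  activity <- subset_z <- ranking <- NULL
  if (!is.null(ds$catalog)) {
    z <- zscore_genes(expr)
    activity <- pathway_activity(z, ds$catalog, config$min_genes)
    subset_z <- subset_zscores(activity, ds$annotation, config$reference)
    ranking <- svm_rank_pathways(activity, ds$annotation,
                                 seed = config$seed, cost = config$svm_cost)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("coresig")),
    seed = config$seed,
    contrasts = vapply(config$contrasts, paste, "", collapse = " vs "),
    thresholds = list(p = config$p_threshold, fch = config$fch_threshold,
                      variant = config$variant,
                      floor = f1$report$thresholds$floor,
                      min_samples_above = config$min_samples_above,
                      variance_quantile = config$variance_quantile,
                      variance_cutoff = f2$report$thresholds$variance_cutoff,
                      min_genes = config$min_genes,
                      svm_cost = config$svm_cost),
    counts = list(genes_input = f1$report$n_input_genes,
                  genes_tested = nrow(expr),
                  signature_sizes = vapply(sigs, signature_size, 1L),
                  core_module = length(cg)))

  run <- structure(list(expression = expr, annotation = ds$annotation,
                        filter_reports = list(unexpressed = f1$report,
                                              low_variability = f2$report),
                        stats = stats_list, signatures = sigs,
                        core_module = core, clustering = clustering,
                        activity = activity, subset_z = subset_z,
                        ranking = ranking, truth = ds$truth,
                        config = config, manifest = manifest),
                   class = "coresig_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

pre_flight <- function(config) {
  pops <- if (is.null(config$data)) config$synthetic$populations
  else unique(config$data$annotation$population)
  bad <- setdiff(c(unlist(config$contrasts), config$reference), pops)
  if (length(bad) > 0)
    stop("contrast/reference population(s) not in the data: ",
         paste(unique(bad), collapse = ", "))
  invisible(config)
}

write_run <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  write_tabular(run$expression, p("expression_filtered.tsv"), "gene")
  write_tabular(run$annotation, p("annotation.tsv"))
  for (i in seq_along(run$stats))
    write_tabular(as.data.frame(run$stats[[i]]), p(sprintf("gene_stats_%d.tsv", i)))
  sig_df <- function(s) data.frame(
    gene = c(s$up_genes, s$down_genes),
    direction = rep(c("up", "down"), c(length(s$up_genes), length(s$down_genes))),
    stringsAsFactors = FALSE)
  for (i in seq_along(run$signatures))
    write_tabular(sig_df(run$signatures[[i]]), p(sprintf("signature_%d.tsv", i)))
  write_tabular(sig_df(run$core_module), p("core_module.tsv"))
  if (!is.null(run$activity))
    write_tabular(run$activity, p("pathway_activity.tsv"), "pathway")
  if (!is.null(run$subset_z))
    write_tabular(unclass(run$subset_z), p("subset_zscores.tsv"), "pathway")
  if (!is.null(run$ranking))
    write_tabular(as.data.frame(run$ranking), p("pathway_ranking.tsv"))
  if (!is.null(run$clustering)) {
    writeLines(dendrogram_newick(run$clustering$gene_dendrogram),
               p("gene_dendrogram.nwk"))
    writeLines(dendrogram_newick(run$clustering$sample_dendrogram),
               p("sample_dendrogram.nwk"))
  }
  writeLines(deparse_manifest(run$manifest), p("manifest.txt"))
  invisible(output_dir)
}

deparse_manifest <- function(m, prefix = "") {
  unlist(lapply(names(m), function(k) {
    v <- m[[k]]
    if (is.list(v)) deparse_manifest(v, paste0(prefix, k, "."))
    else paste0(prefix, k, "\t", paste(format(v, digits = 15), collapse = ","))
  }))
}

#' @export
print.coresig_run <- function(x, ...) {
  cat("coresig pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  genes tested: ", nrow(x$expression), " of ",
      x$manifest$counts$genes_input, "\n", sep = "")
  for (s in x$signatures) print(s)
  print(x$core_module)
  if (!is.null(x$ranking))
    cat("  top pathway: ", x$ranking$pathway[1],
        " (score ", signif(x$ranking$score[1], 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.coresig_run <- function(object, ...) {
  x <- object
  cat("Pipeline summary\n================\n")
  print(x$filter_reports$unexpressed)
  print(x$filter_reports$low_variability)
  for (s in x$signatures) print(s)
  print(x$core_module)
  if (!is.null(x$subset_z)) {
    cat("Subset Z-scores vs ", attr(x$subset_z, "reference"),
        " (top |Z| pathways):\n", sep = "")
    mx <- apply(abs(unclass(x$subset_z)), 1, max, na.rm = TRUE)
    print(round(unclass(x$subset_z)[order(-mx)[seq_len(min(5, length(mx)))], ,
                                    drop = FALSE], 2))
  }
  if (!is.null(x$ranking)) {
    cat("Top-ranked pathways:\n")
    print(utils::head(as.data.frame(x$ranking), 5))
  }
  invisible(x)
}

#' Heatmap of the core-module submatrix
#'
#' Draws the row-scaled core-module expression in the bicluster leaf
#' order — genes as rows, samples as columns.
#'
#' @param x A `coresig_run` with a non-empty clustering element.
#' @param ... Passed to [graphics::image()].
#' @export
plot.coresig_run <- function(x, ...) {
  if (is.null(x$clustering)) stop("run has no clustering (core module too small)")
  z <- x$clustering$scaled[x$clustering$gene_order, x$clustering$sample_order]
  op <- graphics::par(mar = c(7, 5, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(z)[, rev(seq_len(nrow(z))), drop = FALSE],
                  axes = FALSE, col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  main = "Core module (row z-scores)", ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(z)),
                 labels = colnames(z), las = 2, cex.axis = 0.6, tick = FALSE)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(z)),
                 labels = rev(rownames(z)), las = 2, cex.axis = 0.6, tick = FALSE)
  invisible(x)
}

#' Mean, SD and n of a numeric vector
#'
#' The summary used for participant tables: arithmetic mean and
#' unbiased SD, with a 1-decimal presentation helper.  SD is `NA` (and
#' flagged) for a single value.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `mean`, `sd`, `n`, `sd_defined`.
#' @export
summarize_numeric <- function(values) {
  if (length(values) < 1 || !is.numeric(values)) stop("need >= 1 numeric value")
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       n = length(values), sd_defined = length(values) >= 2)
}

#' Format a summarize_numeric result as "mean +/- SD" at 1 decimal
#' @param s Result of [summarize_numeric()].
#' @return Character scalar.
#' @export
format_mean_sd <- function(s) {
  if (!s$sd_defined) return(sprintf("%.1f (n=1, SD undefined)", s$mean))
  sprintf("%.1f ± %.1f", round(s$mean, 1), round(s$sd, 1))
}
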