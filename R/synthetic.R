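# Synthetic expression data with planted ground truth.  The generator
# emulates the two-pairwise-contrast design used to relate skin CD141+
# DDCs to vitamin-D3-induced CD141hi moDCs: per-gene Gaussian log2
# intensities, differential genes planted in each contrast, a shared
# directional core module, a floor of unexpressed genes, and one gene
# set whose members shift coherently in the two CD141+ populations.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the study conditions the package's analyses are
#' validated under: 1000 genes across the five DC populations with six
#' replicates each, gene-level noise SD drawn from 0.2-0.4 log2 units,
#' planted log2 effect of 1.5 (fold 2.8) for differential genes, a
#' 20-gene shared core module, 50 gene sets of 20 genes, and 50
#' unexpressed floor genes.  The planted set's members shift
#' coherently by 0.5 log2 units in the two CD141+ populations — a
#' fold of 1.41, deliberately below the 1.5 single-gene signature
#' gate, so the set is visible to pathway-level aggregation without
#' bleeding into the planted core module.
#'
#' @param n_genes Total genes.
#' @param populations Population labels; must contain both contrast
#'   pairs (see [generate_dataset()]).
#' @param n_replicates_per_population Samples per population.
#' @param baseline_mean Mean of gene baselines, log2 units.
#' @param gene_sd_range Length-2 range from which per-gene SDs are
#'   drawn uniformly (log2 units).
#' @param n_de_genes_contrast1,n_de_genes_contrast2 Planted DE genes in
#'   the CD141+DDC vs CD1c+DDC and CD141hi_VitD3_moDC vs moDC
#'   contrasts (each count includes the core module).
#' @param n_core_module Genes differential, same direction, in both
#'   contrasts.
#' @param de_effect_log2 Absolute planted log2 shift for DE genes.
#' @param n_gene_sets,genes_per_set Catalog dimensions; sets other than
#'   the planted one draw members from null genes.
#' @param planted_set_shift_log2 Log2 shift applied to the planted
#'   set's members in the two CD141+ populations.
#' @param n_unexpressed_genes Genes pinned at a floor intensity with
#'   near-zero variance.
#' @param seed Global seed; per-stage substreams derive from it.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genes = 1000,
                             populations = study_populations(),
                             n_replicates_per_population = 6,
                             baseline_mean = 8,
                             gene_sd_range = c(0.2, 0.4),
                             n_de_genes_contrast1 = 60,
                             n_de_genes_contrast2 = 40,
                             n_core_module = 20,
                             de_effect_log2 = 1.5,
                             n_gene_sets = 50,
                             genes_per_set = 20,
                             planted_set_shift_log2 = 0.5,
                             n_unexpressed_genes = 50,
                             seed = 1) {
  cfg <- list(n_genes = n_genes, populations = populations,
              n_replicates_per_population = n_replicates_per_population,
              baseline_mean = baseline_mean, gene_sd_range = gene_sd_range,
              n_de_genes_contrast1 = n_de_genes_contrast1,
              n_de_genes_contrast2 = n_de_genes_contrast2,
              n_core_module = n_core_module, de_effect_log2 = de_effect_log2,
              n_gene_sets = n_gene_sets, genes_per_set = genes_per_set,
              planted_set_shift_log2 = planted_set_shift_log2,
              n_unexpressed_genes = n_unexpressed_genes, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_de_genes_contrast1, cfg$n_de_genes_contrast2,
              cfg$n_core_module, cfg$n_gene_sets, cfg$genes_per_set,
              cfg$n_unexpressed_genes, cfg$n_replicates_per_population)
  if (any(counts < 0)) stop("synthetic config counts must be non-negative")
  if (cfg$n_core_module > min(cfg$n_de_genes_contrast1, cfg$n_de_genes_contrast2))
    stop("n_core_module exceeds a contrast's planted DE count")
  if (length(cfg$populations) < 2)
    stop("need at least two populations")
  if (cfg$n_de_genes_contrast1 > 0 &&
      !all(c("CD141+DDC", "CD1c+DDC") %in% cfg$populations))
    stop("contrast-1 DE genes planted but CD141+DDC / CD1c+DDC missing")
  if (cfg$n_de_genes_contrast2 > 0 &&
      !all(c("CD141hi_VitD3_moDC", "moDC") %in% cfg$populations))
    stop("contrast-2 DE genes planted but CD141hi_VitD3_moDC / moDC missing")
  if (cfg$n_gene_sets > 0 && cfg$planted_set_shift_log2 != 0 &&
      !all(c("CD141+DDC", "CD141hi_VitD3_moDC") %in% cfg$populations))
    stop("planted-set shift requested but CD141+ populations missing")
  n_planted <- cfg$n_de_genes_contrast1 + cfg$n_de_genes_contrast2 -
    cfg$n_core_module +
    (if (cfg$n_gene_sets > 0) cfg$genes_per_set else 0) +
    cfg$n_unexpressed_genes
  if (n_planted > cfg$n_genes)
    stop("planted gene counts exceed n_genes")
  if (length(cfg$gene_sd_range) != 2 || cfg$gene_sd_range[1] > cfg$gene_sd_range[2] ||
      cfg$gene_sd_range[1] < 0)
    stop("gene_sd_range must be a non-negative (lo, hi) pair")
  if (cfg$n_gene_sets > 0 && cfg$genes_per_set < 1)
    stop("genes_per_set must be >= 1 when gene sets are requested")
  invisible(cfg)
}

#' Generate a synthetic dataset with planted truth
#'
#' Gene values are drawn Normal(baseline_g, sd_g) in log2 space.
#' Contrast-1 DE genes are shifted by +/- `de_effect_log2` in
#' CD141+DDC (vs CD1c+DDC); contrast-2 genes analogously in
#' CD141hi_VitD3_moDC (vs moDC); core-module genes are shifted in both,
#' with the same sign.  Unexpressed genes sit at `baseline_mean - 4`
#' log2 units with SD 0.01.  The planted gene set's members gain
#' `planted_set_shift_log2` in the two CD141+ populations.  Everything
#' is reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `expression` (genes x samples matrix),
#'   `annotation` (data.frame), `catalog` (`gene_set_catalog`), and
#'   `truth` (planted DE maps, core module, planted set name,
#'   unexpressed genes, seed).
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  pops <- cfg$populations
  n_rep <- cfg$n_replicates_per_population
  samples <- unlist(lapply(pops, function(p) paste0(p, "_r", seq_len(n_rep))))
  pop_of <- rep(pops, each = n_rep)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  # disjoint planted blocks, in gene order
  idx <- seq_len(cfg$n_genes)
  take <- function(n) {
    if (n == 0) return(integer(0))
    out <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    out
  }
  i_core <- take(cfg$n_core_module)
  i_de1 <- c(i_core, take(cfg$n_de_genes_contrast1 - cfg$n_core_module))
  i_de2 <- c(i_core, take(cfg$n_de_genes_contrast2 - cfg$n_core_module))
  i_set <- if (cfg$n_gene_sets > 0) take(cfg$genes_per_set) else integer(0)
  i_floor <- take(cfg$n_unexpressed_genes)
  i_null <- idx

  expr <- with_seed(stage_seed(cfg$seed, "matrix"), {
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, 1)
    sds <- stats::runif(cfg$n_genes, cfg$gene_sd_range[1], cfg$gene_sd_range[2])
    baseline[i_floor] <- cfg$baseline_mean - 4
    sds[i_floor] <- 0.01
    dir1 <- dir2 <- integer(0)
    if (length(i_de1) > 0) dir1 <- sample(c(-1L, 1L), length(i_de1), TRUE)
    if (length(i_de2) > 0) dir2 <- sample(c(-1L, 1L), length(i_de2), TRUE)
    # core genes share the contrast-1 direction in both contrasts
    if (cfg$n_core_module > 0)
      dir2[seq_len(cfg$n_core_module)] <- dir1[seq_len(cfg$n_core_module)]
    shift <- matrix(0, cfg$n_genes, length(pops),
                    dimnames = list(NULL, pops))
    if (length(i_de1) > 0 && "CD141+DDC" %in% pops)
      shift[i_de1, "CD141+DDC"] <- shift[i_de1, "CD141+DDC"] +
        dir1 * cfg$de_effect_log2
    if (length(i_de2) > 0 && "CD141hi_VitD3_moDC" %in% pops)
      shift[i_de2, "CD141hi_VitD3_moDC"] <- shift[i_de2, "CD141hi_VitD3_moDC"] +
        dir2 * cfg$de_effect_log2
    for (p in intersect(c("CD141+DDC", "CD141hi_VitD3_moDC"), pops)) {
      if (length(i_set) > 0)
        shift[i_set, p] <- shift[i_set, p] + cfg$planted_set_shift_log2
    }
    m <- matrix(stats::rnorm(cfg$n_genes * length(samples)),
                nrow = cfg$n_genes) * sds + baseline
    m <- m + shift[, pop_of, drop = FALSE]
    dimnames(m) <- list(genes, samples)
    attr(m, "planted_dir1") <- dir1
    attr(m, "planted_dir2") <- dir2
    m
  })
  dir1 <- attr(expr, "planted_dir1"); attr(expr, "planted_dir1") <- NULL
  dir2 <- attr(expr, "planted_dir2"); attr(expr, "planted_dir2") <- NULL
  attr(expr, "is_log2") <- TRUE

  annotation <- data.frame(
    sample_id = samples,
    population = pop_of,
    donor_id = paste0("D", rep(seq_len(n_rep), times = length(pops))),
    replicate = rep(seq_len(n_rep), times = length(pops)),
    stringsAsFactors = FALSE)

  catalog <- NULL
  planted_set_name <- NA_character_
  if (cfg$n_gene_sets > 0) {
    catalog <- with_seed(stage_seed(cfg$seed, "sets"), {
      planted_set_name <- "PLANTED_CD141_SET"
      sets <- vector("list", cfg$n_gene_sets)
      sets[[1]] <- list(name = planted_set_name,
                        description = "planted coherent shift, CD141+ populations",
                        genes = genes[i_set])
      pool <- genes[i_null]
      for (k in seq_len(cfg$n_gene_sets - 1)) {
        sets[[k + 1]] <- list(
          name = sprintf("NULL_SET_%02d", k),
          description = "random background set",
          genes = sample(pool, min(cfg$genes_per_set, length(pool))))
      }
      names(sets) <- vapply(sets, `[[`, "", "name")
      structure(sets, class = "gene_set_catalog")
    })
    planted_set_name <- "PLANTED_CD141_SET"
  }

  named_dir <- function(i, d) stats::setNames(ifelse(d > 0, "up", "down"), genes[i])
  truth <- list(
    de_genes_contrast1 = named_dir(i_de1, dir1),
    de_genes_contrast2 = named_dir(i_de2, dir2),
    core_module = named_dir(i_core, dir1[seq_len(cfg$n_core_module)]),
    planted_set_name = planted_set_name,
    planted_set_genes = genes[i_set],
    unexpressed_genes = genes[i_floor],
    null_genes = genes[i_null],
    seed = cfg$seed)

  list(expression = expr, annotation = annotation, catalog = catalog,
       truth = truth)
}

#' Generate a synthetic qPCR Ct table
#'
#' Half the samples are a reference condition, half a treated
#' condition.  A declared true fold change per target gene is encoded
#' as `-log2(fold)` added to the treated samples' target Ct, so the
#' delta-delta-Ct arithmetic recovers it exactly at zero noise.
#'
#' @param n_samples Total samples (>= 2; split evenly, reference first).
#' @param target_genes Character vector of target gene names.
#' @param housekeeping Housekeeping gene name (default `"GAPDH"`); must
#'   not appear in `target_genes`.
#' @param fold_changes Named numeric vector of true linear folds
#'   (treated vs reference) per target; unnamed scalar recycles.
#'   Default 1 (no change).
#' @param noise_sd Per-well Gaussian Ct noise, cycles (default 0.15).
#' @param seed RNG seed.
#' @return data.frame of class `"ct_table"`.
#' @export
generate_ct_table <- function(n_samples, target_genes, housekeeping = "GAPDH",
                              fold_changes = 1, noise_sd = 0.15, seed = 1) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (housekeeping %in% target_genes)
    stop("housekeeping gene must not appear in target_genes")
  if (is.null(names(fold_changes)))
    fold_changes <- stats::setNames(rep_len(fold_changes, length(target_genes)),
                                    target_genes)
  if (!all(target_genes %in% names(fold_changes)))
    stop("fold_changes must cover every target gene")
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  n_ref <- floor(n_samples / 2)
  condition <- c(rep("reference", n_ref), rep("treated", n_samples - n_ref))
  with_seed(stage_seed(seed, "ct"), {
    hk_base <- 20
    tgt_base <- stats::setNames(stats::runif(length(target_genes), 24, 28),
                                target_genes)
    ct <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
                     condition = condition, stringsAsFactors = FALSE)
    ct[[housekeeping]] <- hk_base + stats::rnorm(n_samples, 0, noise_sd)
    for (g in target_genes) {
      shift <- ifelse(condition == "treated", -log2(fold_changes[[g]]), 0)
      ct[[g]] <- tgt_base[[g]] + shift + stats::rnorm(n_samples, 0, noise_sd)
    }
    ct[3:ncol(ct)] <- lapply(ct[3:ncol(ct)], function(v) pmin(pmax(v, 15), 35))
    validate_ct_table(ct)
  })
}
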