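# Per-gene two-group testing, fold-change gating, signature calling,
# and the directional intersection of two signatures into a core
# module.

#' Per-gene two-sample t statistics between two populations
#'
#' Computes, for every gene, a two-sided two-sample t-test between the
#' samples of `group_a` and `group_b`, group means on the log2 scale,
#' and the linear fold change `2^(mean_A - mean_B)` (a ratio of
#' geometric means on the raw scale).  The pooled-variance test is the
#' default; Welch's unequal-variance form is available via `variant`.
#' Genes with zero variance in both groups have no defined t statistic:
#' they are reported with `t = 0`, `p = 1` and `flagged = TRUE`, so
#' they can never enter a signature.
#'
#' @param matrix Genes x samples log2 matrix.
#' @param annotation Sample annotation data.frame (`sample_id`,
#'   `population`, ...).
#' @param group_a,group_b Population labels; fold changes and direction
#'   are expressed as `group_a` relative to `group_b`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return data.frame of class `"gene_stats"`: `gene`, `t_statistic`,
#'   `df`, `p_value`, `mean_log2_a`, `mean_log2_b`, `fold_change`,
#'   `direction`, `flagged`.
#' @export
two_group_stats <- function(matrix, annotation, group_a, group_b,
                            variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  validate_expression_matrix(matrix)
  for (g in c(group_a, group_b))
    if (!g %in% annotation$population)
      stop("population not present in annotation: ", g)
  if (group_a == group_b) stop("groups must be disjoint")
  sa <- annotation$sample_id[annotation$population == group_a]
  sb <- annotation$sample_id[annotation$population == group_b]
  sa <- intersect(colnames(matrix), sa)
  sb <- intersect(colnames(matrix), sb)
  if (length(sa) < 2 || length(sb) < 2)
    stop("each group needs at least 2 samples in the matrix")
  xa <- matrix[, sa, drop = FALSE]
  xb <- matrix[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- row_vars(xa); vb <- row_vars(xb)
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(matrix))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  flagged <- se == 0 | !is.finite(se)
  tstat <- ifelse(flagged, 0, (ma - mb) / se)
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), df))
  fc <- 2^(ma - mb)
  out <- data.frame(gene = rownames(matrix), t_statistic = tstat, df = df,
                    p_value = p, mean_log2_a = ma, mean_log2_b = mb,
                    fold_change = fc,
                    direction = ifelse(fc > 1, "up", "down"),
                    flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "variant") <- variant
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Call a differential-expression signature
#'
#' A gene enters the signature when `p < p_threshold` and the
#' two-sided fold change `max(fch, 1/fch) > fch_threshold` (both gates
#' strict, matching "p-value < 0.05 and fold change > 1.5").
#' Direction is the sign of the log2 fold change.  Optionally, a
#' Benjamini-Hochberg q-value column is computed and reported but is
#' never used for gating unless `use_adjusted = TRUE`.
#'
#' @param stats A `gene_stats` table.
#' @param p_threshold Raw p-value gate (default 0.05).
#' @param fch_threshold Linear fold-change gate (default 1.5, must be
#'   >= 1).
#' @param use_adjusted Gate on BH-adjusted p-values instead of raw.
#' @param contrast Optional contrast label stored on the signature.
#' @return Object of class `"gene_signature"`: list with `contrast`,
#'   `up_genes`, `down_genes`, `thresholds`.
#' @export
call_signature <- function(stats, p_threshold = 0.05, fch_threshold = 1.5,
                           use_adjusted = FALSE, contrast = NULL) {
  if (p_threshold <= 0) stop("p_threshold must be positive")
  if (fch_threshold < 1) stop("fch_threshold must be >= 1")
  p <- if (use_adjusted) stats::p.adjust(stats$p_value, "BH") else stats$p_value
  fch2 <- pmax(stats$fold_change, 1 / stats$fold_change)
  hit <- p < p_threshold & fch2 > fch_threshold & !stats$flagged
  if (is.null(contrast)) {
    ga <- attr(stats, "group_a"); gb <- attr(stats, "group_b")
    contrast <- if (!is.null(ga)) paste(ga, "vs", gb) else "unnamed contrast"
  }
  structure(list(contrast = contrast,
                 up_genes = stats$gene[hit & stats$fold_change > 1],
                 down_genes = stats$gene[hit & stats$fold_change < 1],
                 thresholds = list(p = p_threshold, fch = fch_threshold,
                                   adjusted = use_adjusted)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature [", x$contrast, "]: ",
      length(x$up_genes) + length(x$down_genes), " genes (",
      length(x$up_genes), " up, ", length(x$down_genes), " down) at p<",
      x$thresholds$p, ", fch>", x$thresholds$fch, "\n", sep = "")
  invisible(x)
}

#' Number of genes in a signature
#' @param sig A `gene_signature`.
#' @return Integer count of up plus down genes.
#' @export
signature_size <- function(sig) length(sig$up_genes) + length(sig$down_genes)

#' Intersect two signatures into a shared core module
#'
#' The core module is the set of genes differential in both contrasts
#' with agreeing direction: `(upA & upB) | (downA & downB)`.  Genes
#' differential in both but with opposite directions are reported in
#' the `discordant` element, never in the core.
#'
#' @param sig_a,sig_b `gene_signature` objects over a shared gene
#'   universe.
#' @return Object of class `"core_module"`: list with `up_genes`,
#'   `down_genes`, `discordant`, `contrasts`.
#' @export
intersect_signatures <- function(sig_a, sig_b) {
  up <- intersect(sig_a$up_genes, sig_b$up_genes)
  down <- intersect(sig_a$down_genes, sig_b$down_genes)
  disc <- union(intersect(sig_a$up_genes, sig_b$down_genes),
                intersect(sig_a$down_genes, sig_b$up_genes))
  structure(list(up_genes = sort(up), down_genes = sort(down),
                 discordant = sort(disc),
                 contrasts = c(sig_a$contrast, sig_b$contrast)),
            class = "core_module")
}

#' @export
print.core_module <- function(x, ...) {
  cat("Core module across [", x$contrasts[1], "] and [", x$contrasts[2],
      "]: ", length(x$up_genes) + length(x$down_genes), " genes (",
      length(x$up_genes), " up, ", length(x$down_genes), " down); ",
      length(x$discordant), " discordant\n", sep = "")
  invisible(x)
}

#' Genes of a core module
#' @param core A `core_module`.
#' @return Character vector of concordant core genes.
#' @export
core_genes <- function(core) c(core$up_genes, core$down_genes)
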