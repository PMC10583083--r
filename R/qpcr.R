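# Delta-delta-Ct relative quantification: housekeeping normalisation,
# reference-condition anchoring, and 2^-ddCt fold changes with the
# classic assumption of perfect amplification efficiency.

#' Housekeeping-normalised delta-Ct values
#'
#' `dCt = Ct_target - Ct_housekeeping`, per sample and target gene.
#'
#' @param ct A `ct_table` (wide: `sample_id`, `condition`, gene
#'   columns).
#' @param housekeeping Housekeeping gene column (default `"GAPDH"`).
#' @return Long data.frame: `sample_id`, `condition`, `gene`,
#'   `delta_ct`.
#' @export
delta_ct <- function(ct, housekeeping = "GAPDH") {
  ct <- validate_ct_table(ct)
  if (!housekeeping %in% colnames(ct))
    stop("housekeeping gene '", housekeeping, "' missing from Ct table")
  hk <- ct[[housekeeping]]
  bad <- ct$sample_id[is.na(hk)]
  if (length(bad) > 0)
    stop("missing housekeeping Ct for sample(s): ", paste(bad, collapse = ", "))
  targets <- setdiff(colnames(ct), c("sample_id", "condition", housekeeping))
  if (length(targets) == 0) stop("no target genes in Ct table")
  out <- do.call(rbind, lapply(targets, function(g)
    data.frame(sample_id = ct$sample_id, condition = ct$condition,
               gene = g, delta_ct = ct[[g]] - hk,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Fold changes by the delta-delta-Ct method
#'
#' `ddCt = dCt_sample - mean(dCt_reference)` per gene, where the
#' reference baseline is the arithmetic mean delta-Ct over the
#' reference condition's samples; `fold = 2^-ddCt` (amplification
#' efficiency fixed at 2 per cycle).  With a single reference sample
#' its fold is exactly 1.
#'
#' @param dct Long delta-Ct table from [delta_ct()].
#' @param reference_condition Condition label anchoring the baseline
#'   (>= 1 sample).
#' @return Long data.frame: `sample_id`, `condition`, `gene`,
#'   `delta_ct`, `ddct`, `fold_change`; attribute
#'   `condition_means` (gene x condition mean folds).
#' @export
ddct_fold_change <- function(dct, reference_condition) {
  if (!all(c("sample_id", "condition", "gene", "delta_ct") %in% colnames(dct)))
    stop("dct must be a delta_ct() output")
  if (!reference_condition %in% dct$condition)
    stop("reference condition has no samples: ", reference_condition)
  ref_mean <- tapply(dct$delta_ct[dct$condition == reference_condition],
                     dct$gene[dct$condition == reference_condition], mean)
  missing <- setdiff(unique(dct$gene), names(ref_mean))
  if (length(missing) > 0)
    stop("no reference measurement for gene(s): ",
         paste(missing, collapse = ", "))
  out <- dct
  out$ddct <- dct$delta_ct - as.numeric(ref_mean[dct$gene])
  out$fold_change <- 2^(-out$ddct)
  cm <- tapply(out$fold_change, list(out$gene, out$condition), mean)
  attr(out, "condition_means") <- cm
  attr(out, "reference_condition") <- reference_condition
  out
}
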