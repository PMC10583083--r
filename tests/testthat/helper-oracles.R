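# Independent brute-force oracles.  These deliberately avoid the code
# paths (and the libraries) they check.

# Naive O(n^3) agglomerative clustering: cluster-to-cluster distances
# are recomputed from the original pairwise matrix at every step.
naive_hclust_heights <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  link <- switch(linkage, average = mean, complete = max, single = min)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- link(dm[clusters[[i]], clusters[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Brute-force signature scan: row-by-row gate check, no vectorisation.
brute_signature <- function(stats, p_thr, fch_thr) {
  up <- character(0); down <- character(0)
  for (i in seq_len(nrow(stats))) {
    r <- stats[i, ]
    if (r$flagged) next
    fch2 <- max(r$fold_change, 1 / r$fold_change)
    if (r$p_value < p_thr && fch2 > fch_thr) {
      if (r$fold_change > 1) up <- c(up, r$gene) else down <- c(down, r$gene)
    }
  }
  list(up = up, down = down)
}

# Brute-force pathway activity: explicit per-sample loops.
brute_activity <- function(z, genes) {
  k <- length(genes)
  vapply(seq_len(ncol(z)), function(j) {
    s <- 0
    for (g in genes) s <- s + z[g, j]
    s / sqrt(k)
  }, numeric(1))
}
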