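# Small in-code fixtures shared across test files.

tiny_matrix <- function(genes = 6, samples = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples, 8, 1), genes, samples,
              dimnames = list(sprintf("G%02d", seq_len(genes)),
                              sprintf("S%02d", seq_len(samples))))
  attr(m, "is_log2") <- TRUE
  m
}

two_group_annotation <- function(pops = c("CD141+DDC", "CD1c+DDC"), n = 3) {
  data.frame(sample_id = paste0(rep(pops, each = n), "_r", seq_len(n)),
             population = rep(pops, each = n),
             donor_id = paste0("D", seq_len(n)),
             replicate = rep(seq_len(n), times = length(pops)),
             stringsAsFactors = FALSE)
}

# matrix with two fixed groups laid out in columns
grouped_matrix <- function(values_a, values_b, gene = "G1") {
  n <- length(values_a)
  m <- rbind(c(values_a, values_b))
  dimnames(m) <- list(gene, c(paste0("A", seq_len(n)),
                              paste0("B", seq_len(length(values_b)))))
  attr(m, "is_log2") <- TRUE
  m
}

grouped_annotation <- function(na, nb, pops = c("CD141+DDC", "CD1c+DDC")) {
  data.frame(sample_id = c(paste0("A", seq_len(na)), paste0("B", seq_len(nb))),
             population = rep(pops, c(na, nb)),
             donor_id = paste0("D", c(seq_len(na), seq_len(nb))),
             replicate = c(seq_len(na), seq_len(nb)),
             stringsAsFactors = FALSE)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

make_catalog <- function(...) {
  sets <- list(...)
  out <- lapply(names(sets), function(nm)
    list(name = nm, description = "test", genes = sets[[nm]]))
  names(out) <- names(sets)
  structure(out, class = "gene_set_catalog")
}
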