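test_that("pooled t on {1,2,3} vs {4,5,6} matches the closed form", {
  m <- grouped_matrix(c(1, 2, 3), c(4, 5, 6))
  st <- two_group_stats(m, grouped_annotation(3, 3), "CD141+DDC", "CD1c+DDC")
  expect_equal(st$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(st$df, 4)
  expect_equal(st$p_value, 2 * pt(-3.674235, 4), tolerance = 1e-6)
  expect_equal(st$fold_change, 2^(2 - 5), tolerance = 1e-12)
  expect_identical(st$direction, "down")
})

test_that("both variants agree with t.test on seeded data", {
  set.seed(17)
  m <- tiny_matrix(30, 10, seed = 17)
  ann <- grouped_annotation(5, 5)
  colnames(m) <- ann$sample_id
  for (v in c("pooled", "welch")) {
    st <- two_group_stats(m, ann, "CD141+DDC", "CD1c+DDC", variant = v)
    for (i in c(1, 13, 30)) {
      tt <- t.test(m[i, 1:5], m[i, 6:10], var.equal = (v == "pooled"))
      expect_equal(st$t_statistic[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(st$p_value[i], tt$p.value, tolerance = 1e-10)
      expect_equal(st$df[i], unname(tt$parameter), tolerance = 1e-8)
    }
  }
})

test_that("identical groups give t=0, p=1, fold 1; swapping groups mirrors stats", {
  m <- grouped_matrix(c(2, 4, 6), c(2, 4, 6))
  st <- two_group_stats(m, grouped_annotation(3, 3), "CD141+DDC", "CD1c+DDC")
  expect_equal(st$t_statistic, 0)
  expect_equal(st$p_value, 1)
  expect_equal(st$fold_change, 1)

  m2 <- tiny_matrix(10, 8, seed = 3)
  ann <- grouped_annotation(4, 4)
  colnames(m2) <- ann$sample_id
  ab <- two_group_stats(m2, ann, "CD141+DDC", "CD1c+DDC")
  ba <- two_group_stats(m2, ann, "CD1c+DDC", "CD141+DDC")
  expect_equal(ba$t_statistic, -ab$t_statistic, tolerance = 1e-12)
  expect_equal(ba$fold_change, 1 / ab$fold_change, tolerance = 1e-12)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
})

test_that("zero-variance-in-both-groups genes are flagged, never significant", {
  m <- rbind(flat = rep(5, 6), real = c(1, 2, 3, 9, 10, 11))
  colnames(m) <- grouped_annotation(3, 3)$sample_id
  attr(m, "is_log2") <- TRUE
  st <- two_group_stats(m, grouped_annotation(3, 3), "CD141+DDC", "CD1c+DDC")
  expect_true(st$flagged[1]); expect_false(st$flagged[2])
  expect_equal(st$p_value[1], 1)
  sig <- call_signature(st, p_threshold = 0.99, fch_threshold = 1)
  expect_false("flat" %in% c(sig$up_genes, sig$down_genes))
})

test_that("group size and membership preconditions are enforced", {
  m <- grouped_matrix(c(1, 2), c(3, 4))
  expect_error(two_group_stats(m, grouped_annotation(2, 2), "CD141+DDC", "moDC"),
               "not present")
  ann1 <- grouped_annotation(1, 3)
  m1 <- grouped_matrix(1, c(3, 4, 5))
  expect_error(two_group_stats(m1, ann1, "CD141+DDC", "CD1c+DDC"),
               "at least 2 samples")
})

test_that("single-gate failures are excluded; both-gate passes keep direction", {
  st <- data.frame(gene = c("pass_up", "weak_fch", "weak_p", "pass_down"),
                   t_statistic = c(3, 3, 1, -3), df = 10,
                   p_value = c(0.04, 0.04, 0.06, 0.01),
                   mean_log2_a = 0, mean_log2_b = 0,
                   fold_change = c(1.6, 1.4, 3, 1 / 2.2),
                   direction = c("up", "up", "up", "down"),
                   flagged = FALSE, stringsAsFactors = FALSE)
  sig <- call_signature(st)
  expect_identical(sig$up_genes, "pass_up")
  expect_identical(sig$down_genes, "pass_down")
})

test_that("signature calling equals an independent brute-force row scan (seeded)", {
  set.seed(53)
  n <- 500
  st <- data.frame(gene = sprintf("g%03d", 1:n),
                   t_statistic = rnorm(n), df = 10,
                   p_value = runif(n),
                   mean_log2_a = 0, mean_log2_b = 0,
                   fold_change = 2^rnorm(n, 0, 1),
                   flagged = runif(n) < 0.05, stringsAsFactors = FALSE)
  st$direction <- ifelse(st$fold_change > 1, "up", "down")
  for (thr in list(c(0.05, 1.5), c(0.01, 2), c(0.2, 1.1))) {
    sig <- call_signature(st, thr[1], thr[2])
    oracle <- brute_signature(st, thr[1], thr[2])
    expect_setequal(sig$up_genes, oracle$up)
    expect_setequal(sig$down_genes, oracle$down)
  }
})

test_that("signatures shrink monotonically as gates tighten", {
  ds <- generate_dataset(synthetic_config(n_genes = 300, seed = 61,
                                          n_gene_sets = 0,
                                          n_unexpressed_genes = 0))
  st <- two_group_stats(ds$expression, ds$annotation, "CD141+DDC", "CD1c+DDC")
  sizes_p <- sapply(c(0.2, 0.05, 0.01, 0.001),
                    function(p) signature_size(call_signature(st, p, 1.5)))
  sizes_f <- sapply(c(1, 1.5, 2, 4),
                    function(f) signature_size(call_signature(st, 0.05, f)))
  expect_true(all(diff(sizes_p) <= 0))
  expect_true(all(diff(sizes_f) <= 0))
})

test_that("every up gene has mean_log2_a above mean_log2_b", {
  ds <- generate_dataset(synthetic_config(n_genes = 400, seed = 71,
                                          n_gene_sets = 0,
                                          n_unexpressed_genes = 0))
  st <- two_group_stats(ds$expression, ds$annotation, "CD141+DDC", "CD1c+DDC")
  sig <- call_signature(st)
  up <- st[st$gene %in% sig$up_genes, ]
  down <- st[st$gene %in% sig$down_genes, ]
  expect_true(all(up$mean_log2_a > up$mean_log2_b))
  expect_true(all(down$mean_log2_a < down$mean_log2_b))
})

test_that("core module is the direction-consistent intersection", {
  sa <- structure(list(contrast = "c1", up_genes = c("A", "B", "C"),
                       down_genes = "D",
                       thresholds = list(p = 0.05, fch = 1.5)),
                  class = "gene_signature")
  sb <- structure(list(contrast = "c2", up_genes = c("B", "C", "E"),
                       down_genes = c("D", "F"),
                       thresholds = list(p = 0.05, fch = 1.5)),
                  class = "gene_signature")
  core <- intersect_signatures(sa, sb)
  expect_setequal(core$up_genes, c("B", "C"))
  expect_identical(core$down_genes, "D")
  expect_length(core$discordant, 0)

  # disjoint signatures -> empty core
  sb2 <- structure(list(contrast = "c2", up_genes = "X", down_genes = "Y",
                        thresholds = list(p = 0.05, fch = 1.5)),
                   class = "gene_signature")
  expect_length(core_genes(intersect_signatures(sa, sb2)), 0)

  # opposite directions land in the discordant report, not the core
  sb3 <- structure(list(contrast = "c2", up_genes = "D", down_genes = "A",
                        thresholds = list(p = 0.05, fch = 1.5)),
                   class = "gene_signature")
  core3 <- intersect_signatures(sa, sb3)
  expect_length(core_genes(core3), 0)
  expect_setequal(core3$discordant, c("A", "D"))
})
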