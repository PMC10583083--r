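test_that("z-transform standardises every gene row (mean 0, sd 1)", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(10, 20, 60))
  colnames(m) <- paste0("S", 1:3)
  attr(m, "is_log2") <- TRUE
  z <- zscore_genes(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-9)

  big <- tiny_matrix(50, 10, seed = 23)
  zb <- zscore_genes(big)
  for (i in c(1, 25, 50))    # independent per-row standardisation oracle
    expect_equal(unname(zb[i, ]), unname(scale(big[i, ])[, 1]),
                 tolerance = 1e-12)

  const <- rbind(c1 = rep(4, 3)); colnames(const) <- paste0("S", 1:3)
  expect_error(zscore_genes(const), "filter_low_variability")
})

test_that("pathway activity is sum(z)/sqrt(k), matching forced arithmetic", {
  z <- matrix(1, 4, 2, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  cat_ <- make_catalog(P4 = paste0("g", 1:4))
  act <- pathway_activity(z, cat_, min_genes = 1)
  expect_equal(unname(act["P4", ]), c(2, 2))    # 4/sqrt(4)

  z2 <- matrix(c(1, -1, 1, -1), 4, 1, dimnames = list(paste0("g", 1:4), "s"))
  expect_equal(unname(pathway_activity(z2, cat_, 1)["P4", ]), 0)

  # singleton pathway: activity is the gene's z row
  zs <- tiny_matrix(5, 4, seed = 3)
  zs <- zscore_genes(zs)
  act1 <- pathway_activity(zs, make_catalog(S1 = "G02"), min_genes = 1)
  expect_equal(unname(act1["S1", ]), unname(zs["G02", ]), tolerance = 1e-12)
})

test_that("activity equals the brute-force oracle and is mean-centred", {
  m <- tiny_matrix(40, 12, seed = 29)
  z <- zscore_genes(m)
  cat_ <- make_catalog(A = rownames(m)[1:7], B = rownames(m)[8:20],
                       C = rownames(m)[c(2, 5, 21:30)])
  act <- pathway_activity(z, cat_, min_genes = 5)
  for (p in rownames(act))
    expect_equal(unname(act[p, ]), brute_activity(z, cat_[[p]]$genes),
                 tolerance = 1e-12)
  expect_equal(unname(rowMeans(act)), rep(0, nrow(act)), tolerance = 1e-9)
})

test_that("pathways below min_genes are dropped with a log; missing genes shrink k", {
  z <- zscore_genes(tiny_matrix(10, 6, seed = 31))
  cat_ <- make_catalog(big = rownames(z)[1:6],
                       partial = c(rownames(z)[1:5], "ABSENT1", "ABSENT2"),
                       small = rownames(z)[1:2])
  expect_message(act <- pathway_activity(z, cat_, min_genes = 5), "dropped")
  expect_setequal(rownames(act), c("big", "partial"))
  expect_equal(attr(act, "k")[["partial"]], 5L)
})

test_that("duplicating a pathway's genes scales activity by sqrt(2)", {
  m <- tiny_matrix(20, 8, seed = 37)
  z <- zscore_genes(m)
  genes <- rownames(z)[1:6]
  z2 <- rbind(z, `copies` = NULL)
  dup <- z[genes, , drop = FALSE]
  rownames(dup) <- paste0(genes, "_dup")
  z2 <- rbind(z, dup)
  a1 <- pathway_activity(z, make_catalog(P = genes), 1)
  a2 <- pathway_activity(z2, make_catalog(P = c(genes, rownames(dup))), 1)
  expect_equal(unname(a2["P", ]), sqrt(2) * unname(a1["P", ]),
               tolerance = 1e-12)
})

test_that("subset Z-scores anchor the reference population at exactly zero", {
  ds <- generate_dataset(synthetic_config(seed = 43))
  z <- zscore_genes(filter_low_variability(
    filter_unexpressed(ds$expression)$matrix)$matrix)
  act <- pathway_activity(z, ds$catalog)
  sz <- subset_zscores(act, ds$annotation, "CD141+DDC")
  expect_equal(unname(sz[, "CD141+DDC"]), rep(0, nrow(sz)), tolerance = 1e-9)
  expect_identical(attr(sz, "reference"), "CD141+DDC")
})

test_that("populations drawn from the reference distribution stay near Z = 0", {
  # two populations, identical generating process, no planted signal
  cfg <- synthetic_config(n_genes = 400,
                          populations = c("CD141+DDC", "CD1c+DDC"),
                          n_replicates_per_population = 6,
                          n_de_genes_contrast1 = 0, n_de_genes_contrast2 = 0,
                          n_core_module = 0, de_effect_log2 = 0,
                          planted_set_shift_log2 = 0,
                          n_gene_sets = 20, genes_per_set = 10,
                          n_unexpressed_genes = 0, seed = 47)
  ds <- generate_dataset(cfg)
  act <- pathway_activity(zscore_genes(ds$expression), ds$catalog)
  sz <- subset_zscores(act, ds$annotation, "CD141+DDC")
  expect_lt(median(abs(sz[, "CD1c+DDC"])), 0.5)
})

test_that("a planted coherent shift gives the planted pathway the extreme Z", {
  ds <- generate_dataset(synthetic_config(seed = 53))
  act <- pathway_activity(zscore_genes(ds$expression), ds$catalog)
  sz <- subset_zscores(act, ds$annotation, "CD141+DDC")
  planted <- ds$truth$planted_set_name
  # moDC lacks the shift carried by the reference: largest |Z| divergence
  expect_identical(rownames(sz)[which.max(abs(sz[, "moDC"]))], planted)
  # CD141hi VitD3 moDC shares the shift: pathway looks reference-like
  expect_lt(abs(sz[planted, "CD141hi_VitD3_moDC"]),
            abs(sz[planted, "moDC"]) / 3)
})

test_that("SVM ranking is deterministic, complete, and tie-broken by name", {
  ds <- generate_dataset(synthetic_config(seed = 59))
  act <- pathway_activity(zscore_genes(ds$expression), ds$catalog)
  r1 <- svm_rank_pathways(act, ds$annotation, seed = 7)
  r2 <- svm_rank_pathways(act, ds$annotation, seed = 7)
  expect_identical(r1, r2)
  expect_identical(r1$rank, seq_len(nrow(r1)))
  expect_true(all(r1$score >= 0))
  expect_setequal(r1$pathway, rownames(act))

  # duplicated feature rows share a score and order lexicographically
  act2 <- act[c(1, 1, 2:10), ]
  rownames(act2)[1:2] <- c("ZZ_TWIN", "AA_TWIN")
  r3 <- svm_rank_pathways(act2, ds$annotation, seed = 7)
  s <- r3$score[match(c("AA_TWIN", "ZZ_TWIN"), r3$pathway)]
  expect_equal(s[1], s[2], tolerance = 1e-9)
  expect_lt(r3$rank[r3$pathway == "AA_TWIN"], r3$rank[r3$pathway == "ZZ_TWIN"])

  one_pop <- ds$annotation[ds$annotation$population == "moDC", ]
  expect_error(svm_rank_pathways(act[, one_pop$sample_id], one_pop, 1),
               "2 populations")
})

test_that("over-representation matches closed forms at the extremes", {
  universe <- sprintf("u%03d", 1:100)
  cat_ <- make_catalog(HIT = universe[1:10], MISS = universe[91:100])
  res <- overrepresentation(universe[1:10], cat_, universe)
  hit <- res[res$set == "HIT", ]
  expect_equal(hit$overlap, 10)
  expect_equal(hit$p_value, 1 / choose(100, 10), tolerance = 1e-10)
  miss <- res[res$set == "MISS", ]
  expect_equal(miss$overlap, 0)
  expect_lte(miss$p_value, 1)
  expect_error(overrepresentation(c(universe[1], "NOT_THERE"), cat_, universe),
               "outside the universe")
})

test_that("random signatures rarely reach q < 0.05 against random sets", {
  set.seed(67)
  universe <- sprintf("u%03d", 1:200)
  hits <- 0; trials <- 100
  for (i in seq_len(trials)) {
    sets <- lapply(1:40, function(k) sample(universe, 15))
    names(sets) <- sprintf("S%02d", 1:40)
    cat_ <- do.call(make_catalog, sets)
    sig <- sample(universe, 20)
    res <- overrepresentation(sig, cat_, universe)
    hits <- hits + (min(res$q_value) < 0.05)
  }
  expect_lte(hits, 10)   # q-gate false alarms in <= 10% of null trials
})
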