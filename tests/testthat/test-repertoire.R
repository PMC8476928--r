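test_that("clonotype keys ignore record order and respect V genes", {
  a <- toy_contig("cellA", c("IGH", "IGK"), c("Ighv1-1", "Igkv2-2"),
                  c("CARW", "CQQF"))
  b <- toy_contig("cellB", c("IGK", "IGH"), c("Igkv2-2", "Ighv1-1"),
                  c("CQQF", "CARW"))
  assign <- assign_clonotypes(rbind(a, b))
  expect_identical(assign$clonotype[1], assign$clonotype[2])
  expect_identical(assign$clone_size, c(2L, 2L))
  # same CDR3, different V gene -> different clonotype
  c2 <- toy_contig("cellC", c("IGH", "IGK"), c("Ighv9-9", "Igkv2-2"),
                   c("CARW", "CQQF"))
  assign2 <- assign_clonotypes(rbind(a, c2))
  expect_false(assign2$clonotype[1] == assign2$clonotype[2])
})

test_that("a five-cell toy table keys into sizes (2,1,1,1)", {
  pair <- function(bc, hv, hc, lv, lc)
    toy_contig(bc, c("IGH", "IGK"), c(hv, lv), c(hc, lc))
  contigs <- rbind(
    pair("c1", "Ighv1-1", "CAW", "Igkv1-1", "CLF"),
    pair("c2", "Ighv1-1", "CAW", "Igkv1-1", "CLF"),
    pair("c3", "Ighv2-1", "CBW", "Igkv1-1", "CLF"),
    pair("c4", "Ighv1-1", "CAW", "Igkv9-1", "CLF"),
    pair("c5", "Ighv1-1", "CDW", "Igkv1-1", "CLF"))
  assign <- assign_clonotypes(contigs)
  sizes <- sort(as.integer(table(assign$clonotype)), decreasing = TRUE)
  expect_identical(sizes, c(2L, 1L, 1L, 1L))
  expect_identical(length(unique(assign$clonotype)), 4L)
})

test_that("nt-level keys distinguish synonymous CDR3 variants", {
  a <- toy_contig("x", "IGH", "v", "CAW", cdr3_nt = "TGTGCTTGG")
  b <- toy_contig("y", "IGH", "v", "CAW", cdr3_nt = "TGCGCATGG")
  both <- rbind(a, b)
  expect_identical(assign_clonotypes(both, key_mode = "aa")$clonotype[1],
                   assign_clonotypes(both, key_mode = "aa")$clonotype[2])
  nt <- assign_clonotypes(both, key_mode = "nt")
  expect_false(nt$clonotype[1] == nt$clonotype[2])
})

test_that("pairwise sharing counts clonotypes and union cells by hand", {
  assign <- toy_assign(
    clonotype = c("x", "x", "y", "y", "y", "y", "z"),
    organ = c("A", "A", "A", "B", "B", "B", "B"))
  sh <- pairwise_sharing(assign)
  # organ A holds {x(2), y(1)}, B holds {y(3), z(1)}: one shared clonotype,
  # shared cells = 1 + 3 = 4 over the union
  expect_identical(sh$clonotypes["A", "B"], 1L)
  expect_identical(sh$cells["A", "B"], 4L)
  expect_identical(sh$clonotypes, t(sh$clonotypes))
  expect_identical(unname(diag(sh$cells)), c(0L, 0L))
  # disjoint repertoires -> zero matrices
  dis <- pairwise_sharing(toy_assign(c("p", "q"), organ = c("A", "B")))
  expect_true(all(dis$clonotypes == 0) && all(dis$cells == 0))
})

test_that("expansion index matches closed forms and conventions", {
  expect_identical(expansion_index(toy_assign(letters[1:4], cluster = "k"), "k"), 0)
  expect_identical(expansion_index(toy_assign(rep("a", 4), cluster = "k"), "k"), 1)
  expect_equal(expansion_index(toy_assign(c("a", "a", "b"), cluster = "k"), "k"),
               1 - (-(2/3) * log2(2/3) - (1/3) * log2(1/3)), tolerance = 1e-12)
  # ~0.0817
  expect_identical(expansion_index(toy_assign("a", cluster = "k"), "k"), 0)
  expect_error(expansion_index(toy_assign("a", cluster = "k"), "missing"),
               "empty")
})

test_that("migration index matches weighted-entropy arithmetic", {
  one_tissue <- toy_assign(c("a", "a", "b"), cluster = "k",
                           organ = rep("PC", 3))
  expect_identical(migration_index(one_tissue, "k"), 0)
  split22 <- toy_assign(rep("a", 4), cluster = "k",
                        organ = c("PC", "PC", "liver", "liver"))
  expect_identical(migration_index(split22, "k"), 1)
  mixed <- toy_assign(c("A", "A", "A", "B"), cluster = "k",
                      organ = c("PC", "PC", "liver", "PC"))
  h_a <- -(2/3) * log2(2/3) - (1/3) * log2(1/3)
  expect_equal(migration_index(mixed, "k"), 0.75 * h_a, tolerance = 1e-12)
})

test_that("transition index matches split-entropy arithmetic", {
  disjoint <- toy_assign(c("a", "b"), cluster = c("k1", "k2"))
  expect_identical(transition_index(disjoint, "k1", "k2"), 0)
  split50 <- toy_assign(rep("a", 4), cluster = c("k1", "k1", "k2", "k2"))
  expect_identical(transition_index(split50, "k1", "k2"), 1)
  mixed <- toy_assign(c("s", "s", "t", "t"),
                      cluster = c("k1", "k2", "k1", "k1"))
  expect_equal(transition_index(mixed, "k1", "k2"), 0.5, tolerance = 1e-12)
  expect_equal(transition_index(mixed, "k1", "k2"),
               transition_index(mixed, "k2", "k1"), tolerance = 1e-15)
  expect_error(transition_index(mixed, "k1", "k1"), "distinct")
})

test_that("indices equal brute-force recomputation on random small instances", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    assign <- toy_assign(
      clonotype = sample(letters[1:4], n, replace = TRUE),
      cluster = sample(c("k1", "k2"), n, replace = TRUE),
      organ = sample(c("PC", "liver", "BM"), n, replace = TRUE))
    for (cl in intersect(c("k1", "k2"), assign$cluster)) {
      rows <- assign[assign$cluster == cl, ]
      expect_equal(expansion_index(assign, cl),
                   brute_expansion(rows$clonotype), tolerance = 1e-12)
      expect_equal(migration_index(assign, cl),
                   brute_weighted_entropy(rows$clonotype, rows$organ),
                   tolerance = 1e-12)
    }
    if (all(c("k1", "k2") %in% assign$cluster)) {
      expect_equal(transition_index(assign, "k1", "k2"),
                   brute_weighted_entropy(assign$clonotype, assign$cluster),
                   tolerance = 1e-12)
    }
  }
})

test_that("indices are invariant to record ordering and stay in bounds", {
  set.seed(56)
  assign <- toy_assign(
    clonotype = sample(letters[1:3], 8, replace = TRUE),
    cluster = rep("k", 8),
    organ = sample(c("PC", "BM"), 8, replace = TRUE))
  perm <- assign[sample(8), ]
  expect_equal(expansion_index(assign, "k"), expansion_index(perm, "k"))
  expect_equal(migration_index(assign, "k"), migration_index(perm, "k"))
  e <- expansion_index(assign, "k")
  expect_gte(e, 0); expect_lte(e, 1)
  expect_lte(migration_index(assign, "k"), log2(2))
  # merging two singletons into one clone never decreases expansion
  grown <- assign; grown$clonotype <- "a"
  expect_gte(expansion_index(grown, "k"), e)
})

test_that("top clonotypes rank by size with deterministic ties", {
  assign <- toy_assign(c(rep("m", 5), rep("b", 3), rep("a", 3), "z"))
  top2 <- top_clonotypes(assign, n = 2)
  expect_identical(top2$clonotype, c("m", "a"))  # tie 3-3 broken to "a"
  expect_identical(top2$n_cells, c(5L, 3L))
  all_of_them <- top_clonotypes(assign, n = 99)
  expect_identical(nrow(all_of_them), 4L)
})

test_that("planted expanded clones occupy the top ranks with organ counts", {
  ds <- generate_dataset(small_sim_config(seed = 57))
  assign <- assign_clonotypes(
    ds$contigs[!ds$contigs$barcode %in%
                 ds$cell_truth$barcode[ds$cell_truth$is_multichain_doublet], ],
    cells = ds$cell_truth)
  top <- top_clonotypes(assign, n = 2)
  expect_identical(top$n_cells, c(10L, 10L))
  expect_identical(top$organ_PC, c(10L, 10L))
})
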