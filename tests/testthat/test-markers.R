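test_that("rank-sum p-values agree with the reference implementation", {
  set.seed(12)
  # tie-free small samples: exact route vs wilcox.test exact
  for (rep in 1:10) {
    x <- stats::rnorm(sample(3:8, 1)); y <- stats::rnorm(sample(3:8, 1))
    ours <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
  # large tied samples: normal approximation with continuity correction
  x <- sample(0:4, 80, replace = TRUE); y <- sample(0:5, 90, replace = TRUE)
  ours <- rank_sum_test(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("complete separation of two tied 4-vs-4 groups gives p = 2/70", {
  res <- rank_sum_test(c(5, 5, 5, 5), c(0, 0, 0, 0))
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)  # 0.0286
})

test_that("permuted identical groups produce no discoveries", {
  set.seed(33)
  sim <- generate_expression(small_sim_config(seed = 33, signature_effect = 1,
                                              b10_effect = 1))
  norm <- lognormalize(sim$counts)
  # random labels on exchangeable cells within one organ
  spleen <- sim$cell_truth$barcode[sim$cell_truth$organ == "spleen"]
  calls <- call_breg(stats::setNames(
    ifelse(seq_along(spleen) %% 4 == 0, 1, 0), spleen), 0.16)
  organs <- stats::setNames(rep("spleen", length(spleen)), spleen)
  tab <- rank_genes_breg(norm[spleen, ], calls, "spleen", organs)
  expect_lte(sum(tab$p_adj < 0.05), 2)
})

test_that("a planted fold-change gene is detected at n = 100 per group", {
  set.seed(44)
  n <- 200
  counts <- matrix(stats::rnbinom(n * 50, mu = 2, size = 10), n, 50,
                   dimnames = list(sprintf("c%03d", 1:n), sprintf("g%02d", 1:50)))
  breg <- seq_len(100)
  counts[breg, "g01"] <- stats::rnbinom(100, mu = 6, size = 10)  # 3-fold
  counts <- toy_counts(counts, rownames(counts), colnames(counts))
  norm <- lognormalize(counts)
  s <- stats::setNames(as.numeric(seq_len(n) %in% breg), rownames(counts))
  calls <- call_breg(s, 0.5)
  organs <- stats::setNames(rep("PC", n), rownames(counts))
  tab <- rank_genes_breg(norm, calls, "PC", organs)
  g1 <- tab[tab$gene == "g01", ]
  expect_lt(g1$p_adj, 0.05)
  expect_gt(g1$log2fc, 0.25)
  expect_equal(g1$p_adj, stats::p.adjust(tab$p_value, "BH")[tab$gene == "g01"])
})

test_that("group-size preconditions fail with informative errors", {
  m <- toy_counts(matrix(1:12, 4, 3))
  s <- stats::setNames(c(1, 1, 1, 1), rownames(m))
  calls <- call_breg(s, 0.16)  # everyone Breg -> empty non-Breg group
  organs <- stats::setNames(rep("liver", 4), rownames(m))
  expect_error(rank_genes_breg(lognormalize(m), calls, "liver", organs),
               "liver.*non-Breg")
})

test_that("BH adjustment equals a reference step-up computation", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # step-up: p_(i) * m / i, cumulative minimum from the largest rank down
  m <- length(p)
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
  ref <- pmin(1, stepup)[order(o)]
  expect_equal(stats::p.adjust(p, "BH"), ref, tolerance = 1e-15)
})

test_that("cross-organ intersection follows set arithmetic", {
  mk <- function(organ, genes_sig, genes_null = "zz") {
    data.frame(gene = c(genes_sig, genes_null), organ = organ,
               log2fc = c(rep(1, length(genes_sig)), 0),
               pct_breg = 1, pct_other = 1,
               p_value = c(rep(1e-6, length(genes_sig)), 0.9),
               p_adj = c(rep(1e-5, length(genes_sig)), 0.95))
  }
  res <- intersect_common_markers(list(mk("spleen", c("a", "b", "c")),
                                       mk("liver", c("b", "c")),
                                       mk("PC", c("b", "c", "d"))))
  expect_identical(res$common, c("b", "c"))
  expect_identical(res$venn$common, 2L)
  expect_identical(res$venn$pairwise[["spleen&liver"]], 2L)
  # single organ: intersection is that organ's set
  one <- intersect_common_markers(list(mk("BM", c("x", "y"))))
  expect_identical(one$common, c("x", "y"))
  # disjoint sets: empty intersection
  dis <- intersect_common_markers(list(mk("BM", "x"), mk("PC", "y")))
  expect_identical(dis$common, character(0))
  # monotone non-increasing in the number of organs
  two <- intersect_common_markers(list(mk("spleen", c("a", "b", "c")),
                                       mk("liver", c("b", "c"))))
  expect_gte(length(two$common), length(res$common))
})
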