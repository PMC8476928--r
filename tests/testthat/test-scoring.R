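# naive two-loop oracle, deliberately plain
naive_module_score <- function(scaled, genes, cells) {
  out <- numeric(length(cells))
  for (i in seq_along(cells)) {
    total <- 0
    for (g in genes) total <- total + scaled[cells[i], g]
    m <- total / length(genes)
    out[i] <- if (m > -1) log(1 + m) else -Inf
  }
  names(out) <- cells
  out
}

test_that("module score matches hand arithmetic on worked examples", {
  z <- matrix(c(0.5, 0.3, -0.2), 1, 3,
              dimnames = list("c1", c("a", "b", "c")))
  s <- compute_module_score(z, gene_signature(c("a", "b", "c")))
  expect_equal(as.numeric(s), log(1.2), tolerance = 1e-12)  # ~0.1823

  z0 <- matrix(0, 2, 3, dimnames = list(c("x", "y"), c("a", "b", "c")))
  expect_equal(as.numeric(compute_module_score(z0, gene_signature(c("a", "b")))),
               c(0, 0))

  zneg <- matrix(-1.2, 1, 2, dimnames = list("c1", c("a", "b")))
  s <- compute_module_score(zneg, gene_signature(c("a", "b")))
  expect_identical(as.numeric(s), -Inf)
  expect_false(call_breg(s, threshold = -1e6)$is_breg)
})

test_that("missing signature genes are dropped with a warning, none is fatal", {
  z <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("a", "b")))
  expect_warning(s <- compute_module_score(z, gene_signature(c("a", "b", "zz"))),
                 "zz")
  expect_identical(attr(s, "n_genes_used"), 2L)
  expect_error(compute_module_score(z, gene_signature("nope", "mysig")),
               "mysig")
})

test_that("score equals the naive two-loop oracle on random matrices", {
  set.seed(100)
  for (rep in 1:20) {
    nc <- sample(2:20, 1); ng <- sample(2:20, 1)
    z <- matrix(stats::rnorm(nc * ng), nc, ng,
                dimnames = list(sprintf("c%02d", 1:nc), sprintf("g%02d", 1:ng)))
    genes <- sample(colnames(z), sample(ng, 1))
    s <- compute_module_score(z, gene_signature(genes))
    expect_equal(s, naive_module_score(z, genes, rownames(z)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("score ignores gene order and genes outside the signature", {
  set.seed(4)
  z <- matrix(stats::rnorm(50), 5, 10,
              dimnames = list(sprintf("c%d", 1:5), sprintf("g%02d", 1:10)))
  sig <- c("g03", "g07", "g01")
  s1 <- compute_module_score(z, gene_signature(sig))
  s2 <- compute_module_score(z[, sample(10)], gene_signature(rev(sig)))
  expect_equal(s1, s2, ignore_attr = TRUE, tolerance = 1e-12)
  # raising a signature gene never lowers a cell's score
  z2 <- z; z2["c1", "g03"] <- z2["c1", "g03"] + 1
  s3 <- compute_module_score(z2, gene_signature(sig))
  expect_gte(s3["c1"], s1["c1"])
})

test_that("Breg calling is strictly greater-than the threshold", {
  s <- c(a = 0.16, b = 0.1823, c = 0.1599)
  calls <- call_breg(s, threshold = 0.16)
  expect_identical(calls$is_breg, c(FALSE, TRUE, FALSE))
  # limit: every finite score is Breg at threshold -Inf
  expect_true(all(call_breg(s, threshold = -Inf)$is_breg))
})

test_that("B10 partition applies only to Breg cells", {
  s <- c(a = 0.5, b = 0.5, c = 0.1)
  calls <- call_breg(s, threshold = 0.16)
  b10 <- c(a = 0.2, b = -0.1)
  calls <- call_b10(calls, b10, threshold = 0)
  expect_identical(calls$is_b10, c(TRUE, FALSE, FALSE))
  expect_identical(calls$is_breg & calls$is_b10, calls$is_b10)  # b10 => breg
  # degenerate: one shared value above the cut -> 100% B10
  all_same <- call_b10(call_breg(s, 0.16), c(a = 0.3, b = 0.3), 0)
  expect_true(all(all_same$is_b10[all_same$is_breg]))
  # +Inf threshold -> 0% B10
  none <- call_b10(call_breg(s, 0.16), b10, Inf)
  expect_false(any(none$is_b10[none$is_breg]))
  expect_error(call_b10(calls, c(c = 1)), "non-Breg")
})

test_that("composition proportions match hand counts", {
  s <- stats::setNames(c(rep(1, 3), rep(0, 3), 1, rep(0, 3)),
                       sprintf("c%02d", 1:10))
  calls <- call_breg(s, threshold = 0.16)
  organs <- stats::setNames(rep(c("PC", "spleen"), c(6, 4)), names(s))
  comp <- composition_table(calls, organs)
  expect_equal(comp$organ$breg_fraction[comp$organ$organ == "PC"], 0.5)
  expect_equal(comp$organ$breg_fraction[comp$organ$organ == "spleen"], 0.25)
  # single organ, all Breg
  one <- composition_table(call_breg(stats::setNames(rep(1, 4), letters[1:4]), 0),
                           stats::setNames(rep("PC", 4), letters[1:4]))
  expect_equal(one$organ$breg_fraction, 1)
  # cluster blocks sum to one
  cl <- stats::setNames(rep(c("1", "2"), 2), names(s)[c(1, 2, 3, 7)])
  calls2 <- call_b10(calls, stats::setNames(c(1, -1, 1, -1), names(cl)), 0)
  comp2 <- composition_table(calls2, organs, clusters = cl)
  sums <- tapply(comp2$cluster_by_organ$Freq, comp2$cluster_by_organ$cluster, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-12)
})

test_that("empty organs are omitted with a message", {
  s <- stats::setNames(c(1, 0), c("a", "b"))
  calls <- call_breg(s, 0.16)
  organs <- factor(c("PC", "PC"), levels = c("PC", "BM"))
  expect_message(comp <- composition_table(calls, organs), "BM")
  expect_identical(comp$organ$organ, "PC")
})

test_that("two-means calibration recovers a planted bimodal cut", {
  set.seed(8)
  x <- c(stats::rnorm(60, 0, 0.1), stats::rnorm(40, 1, 0.1))
  thr <- calibrate_threshold(x)
  expect_gt(thr, 0.3); expect_lt(thr, 0.7)
  expect_equal(mean(x > thr), 0.4, tolerance = 0.02)
})
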