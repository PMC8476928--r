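## Per-organ Breg vs non-Breg differential expression (Wilcoxon rank-sum,
## Benjamini-Hochberg) and the cross-organ intersection of upregulated
## genes.

#' Two-sided Wilcoxon rank-sum test with exact small-sample handling
#'
#' Ties are midranked. When the number of group assignments
#' `choose(n1 + n2, n1)` is at most `exact_limit`, the p-value is the
#' exact permutation tail of the rank-sum statistic (valid under ties,
#' where the classical exact distribution is not); otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used, matching [stats::wilcox.test()].
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest assignment count enumerated exactly.
#' @return A list: `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `method` ("exact" or "normal").
#' @export
rank_sum_test <- function(x, y, exact_limit = 20000) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (choose(n, n1) <= exact_limit) {
    e <- n1 * (n + 1) / 2
    combos <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(ws - e) >= abs(w - e) - 1e-9)
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1, method = "normal"))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Differential expression of Breg vs non-Breg cells within one organ
#'
#' For each gene expressed in at least `min_pct` of either group, runs a
#' two-sided Wilcoxon rank-sum test ([rank_sum_test()]) on log-normalized
#' values, adjusts p-values with Benjamini-Hochberg across the tested
#' genes, and reports the log2 fold-change of `expm1`-means with a
#' pseudocount of 1.
#'
#' @param norm Cells x genes log-normalized matrix.
#' @param calls Calls data frame from [call_breg()].
#' @param organ Organ to test.
#' @param organs Organ label per cell (named by barcode, or aligned with
#'   `calls$barcode`).
#' @param min_pct Minimum expressing fraction in either group.
#' @param min_group_size Minimum cells per group.
#' @return Data frame: gene, organ, log2fc, pct_breg, pct_other, p_value,
#'   p_adj, ordered by p then decreasing log2fc.
#' @export
rank_genes_breg <- function(norm, calls, organ, organs,
                            min_pct = 0.1, min_group_size = 3) {
  org <- if (!is.null(names(organs))) organs[calls$barcode] else organs
  in_org <- calls$barcode[!is.na(org) & org == organ]
  in_org <- intersect(in_org, rownames(norm))
  is_breg <- calls$is_breg[match(in_org, calls$barcode)]
  breg_cells <- in_org[is_breg]
  other_cells <- in_org[!is_breg]
  if (!length(breg_cells))
    stop("organ ", organ, ": Breg group is empty")
  if (!length(other_cells))
    stop("organ ", organ, ": non-Breg group is empty")
  if (length(breg_cells) < min_group_size || length(other_cells) < min_group_size)
    stop("organ ", organ, ": fewer than ", min_group_size, " cells in a group")

  xb <- norm[breg_cells, , drop = FALSE]
  xo <- norm[other_cells, , drop = FALSE]
  pct_b <- Matrix::colSums(xb > 0) / nrow(xb)
  pct_o <- Matrix::colSums(xo > 0) / nrow(xo)
  test_genes <- colnames(norm)[pct_b >= min_pct | pct_o >= min_pct]

  xb <- as.matrix(xb[, test_genes, drop = FALSE])
  xo <- as.matrix(xo[, test_genes, drop = FALSE])
  p <- vapply(seq_along(test_genes), function(j)
    rank_sum_test(xb[, j], xo[, j])$p_value, numeric(1))
  l2fc <- log2((colMeans(expm1(xb)) + 1) / (colMeans(expm1(xo)) + 1))
  res <- data.frame(
    gene = test_genes, organ = organ, log2fc = as.numeric(l2fc),
    pct_breg = as.numeric(pct_b[test_genes]),
    pct_other = as.numeric(pct_o[test_genes]),
    p_value = p, p_adj = stats::p.adjust(p, "BH"),
    stringsAsFactors = FALSE)
  res[order(res$p_value, -res$log2fc), ]
}

#' Intersect per-organ upregulated genes into a common marker set
#'
#' A gene is a common marker iff it is significantly upregulated
#' (`p_adj < fdr` and `log2fc > min_log2fc`) in every organ table. Also
#' returns the per-organ upregulated sets and all intersection sizes
#' needed to rebuild a Venn diagram.
#'
#' @param tables List of per-organ data frames from [rank_genes_breg()].
#' @param fdr Adjusted-p cut-off (strict `<`).
#' @param min_log2fc Fold-change cut-off (strict `>`).
#' @return A list: `common` (character), `per_organ` (named list of
#'   upregulated sets), `venn` (list: per-organ sizes, pairwise
#'   intersection sizes, common size).
#' @export
intersect_common_markers <- function(tables, fdr = 0.05, min_log2fc = 0.25) {
  stopifnot(length(tables) >= 1)
  up <- lapply(tables, function(t)
    sort(t$gene[t$p_adj < fdr & t$log2fc > min_log2fc]))
  names(up) <- vapply(tables, function(t) t$organ[1], "")
  common <- sort(Reduce(intersect, up))
  organs <- names(up)
  pair <- list()
  if (length(organs) > 1) {
    for (i in seq_len(length(organs) - 1)) for (j in (i + 1):length(organs))
      pair[[paste(organs[i], organs[j], sep = "&")]] <-
        length(intersect(up[[i]], up[[j]]))
  }
  list(common = common, per_organ = up,
       venn = list(sizes = vapply(up, length, 0L),
                   pairwise = pair, common = length(common)))
}
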