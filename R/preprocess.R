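## Normalization and scaling conventions the module score depends on:
## natural-log library-size normalization to a fixed scale factor, then
## per-gene standardization (sample sd) with an upper clip. Embedding and
## clustering are plumbing used only to subdivide Breg cells into subsets.

#' Library-size log-normalize a count matrix
#'
#' `value(c, g) = ln(1 + count(c, g) / total(c) * scale_factor)` with the
#' conventional scale factor 10,000. Requires every cell total to be
#' positive (zero-total cells should have been removed by QC).
#'
#' @param counts Cells x genes count matrix (sparse or dense).
#' @param scale_factor Target per-cell total before `log1p`.
#' @return A cells x genes `dgCMatrix` of normalized values.
#' @examples
#' m <- Matrix::Matrix(c(1, 1, 2), 1, 3, sparse = TRUE,
#'                     dimnames = list("c1", c("g1", "g2", "g3")))
#' lognormalize(m)  # gene 3: ln(1 + 2/4 * 10000) = ln(5001)
#' @export
lognormalize <- function(counts, scale_factor = 10000) {
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0))
    stop("zero-total cell(s): ",
         paste(utils::head(rownames(counts)[totals <= 0], 5), collapse = ", "))
  norm <- methods::as(counts, "CsparseMatrix")
  norm <- Matrix::Diagonal(x = scale_factor / totals) %*% norm
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "scale_factor") <- scale_factor
  norm
}

#' Per-gene z-score scaling with an upper clip
#'
#' Standardizes each gene over cells to mean 0 and unit variance, then
#' clips values above `clip_max` (default 10, no lower clip). Constant
#' genes map to all-zero columns. The standard-deviation convention
#' (sample, `n - 1`, the default, or population, `n`) is switchable
#' because it shifts module scores and hence the Breg operating point.
#'
#' @param norm Cells x genes normalized matrix.
#' @param clip_max Upper clip applied after standardization.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Dense cells x genes matrix of clipped z-scores.
#' @export
zscore_scale <- function(norm, clip_max = 10, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(norm)
  if (nrow(x) < 2) stop("scaling needs at least 2 cells")
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  v <- pmax(v, 0)
  if (sd_type == "sample") v <- v * nrow(x) / (nrow(x) - 1)
  s <- sqrt(v)
  s[s < 1e-12] <- Inf  # constant genes -> all zeros
  z <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
  z[z > clip_max] <- clip_max
  attr(z, "clip_max") <- clip_max
  attr(z, "sd_type") <- sd_type
  z
}

#' Embed and cluster cells (plumbing)
#'
#' PCA on the (optionally HVG-restricted) scaled matrix, a shared
#' nearest-neighbour graph, and Leiden community detection. Used
#' downstream only to subdivide Breg cells into subsets; none of its
#' parameters are promised to reproduce any particular subset count. The
#' 2-D embedding returned is the first two principal components.
#'
#' Because the scaled matrix has unit variance per gene by construction,
#' highly variable genes cannot be ranked from it; pass the per-gene
#' variances of the log-normalized matrix via `hvg_variances` to restrict
#' to the top `n_hvg`, or leave `NULL` to use all genes.
#'
#' @param scaled Cells x genes scaled matrix.
#' @param n_hvg Number of highly variable genes to keep (ignored when
#'   `hvg_variances` is `NULL`).
#' @param n_pcs Number of principal components.
#' @param resolution Leiden resolution; larger gives more clusters.
#' @param seed Seed for the stochastic graph clustering.
#' @param hvg_variances Optional named per-gene variances used to rank
#'   genes.
#' @param k Neighbours for the kNN graph.
#' @return A list: `cluster` (factor, one label per cell), `embedding`
#'   (cells x 2 matrix), `pca` (cells x n_pcs), `parameters`.
#' @export
embed_cluster <- function(scaled, n_hvg = 500, n_pcs = 30, resolution = 0.5,
                          seed = 1L, hvg_variances = NULL, k = 15) {
  x <- scaled
  if (!is.null(hvg_variances)) {
    hv <- names(sort(hvg_variances, decreasing = TRUE))
    hv <- intersect(hv, colnames(x))[seq_len(min(n_hvg, ncol(x)))]
    x <- x[, hv, drop = FALSE]
  }
  if (n_pcs > min(nrow(x) - 1L, ncol(x)))
    stop("n_pcs exceeds the rank of the scaled matrix")
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  k <- min(k, nrow(x) - 1L)
  d <- as.matrix(stats::dist(pca))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1L)]))
  edges <- cbind(rep(seq_len(nrow(x)), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  cl <- factor(igraph::membership(comm))
  names(cl) <- rownames(x)
  emb <- pca[, seq_len(min(2L, ncol(pca))), drop = FALSE]
  list(cluster = cl, embedding = emb, pca = pca,
       parameters = list(n_hvg = n_hvg, n_pcs = n_pcs,
                         resolution = resolution, seed = seed, k = k))
}
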