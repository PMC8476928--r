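## Module scoring of gene signatures on z-scored expression and the
## thresholded Breg / B10 calls. The score of a cell is log1p of the mean
## scaled value over the signature genes; cells score as Breg when the
## Breg-signature score is strictly above the threshold (default 0.16),
## and Breg cells as B10 when the B10-signature score is strictly above
## the B10 threshold.

#' Construct a gene signature
#'
#' @param genes Character vector of gene symbols, non-empty, no
#'   duplicates.
#' @param name Signature name used in messages and outputs.
#' @return A `gene_signature` (character vector with `name` attribute).
#' @export
gene_signature <- function(genes, name = "signature") {
  genes <- as.character(genes)
  if (!length(genes)) stop("signature '", name, "' is empty")
  if (anyDuplicated(genes))
    stop("signature '", name, "' has duplicate genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(genes, name = name, class = "gene_signature")
}

#' Read a gene signature from a plain-text list
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @param name Signature name; defaults to the file name.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_signature(lines, name %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score cells against a gene signature
#'
#' For each cell, `m` = mean of its scaled values over the signature genes
#' present in the matrix; the score is `ln(1 + m)` when `m > -1` and a
#' `-Inf` sentinel otherwise (pathological but possible on clipped
#' z-scores; such cells fall below any finite threshold). Signature genes
#' missing from the matrix are dropped with a warning and reflected in the
#' `n_genes_used` attribute.
#'
#' @param scaled Cells x genes scaled matrix.
#' @param signature A [gene_signature()] (or plain character vector).
#' @param cells Optional subset of cell barcodes to score (default all).
#' @return Named numeric vector of per-cell scores with attributes
#'   `signature` and `n_genes_used`.
#' @examples
#' z <- matrix(c(0.5, 0.3, -0.2), 1, 3,
#'             dimnames = list("c1", c("a", "b", "c")))
#' compute_module_score(z, gene_signature(c("a", "b", "c")))  # ln(1.2)
#' @export
compute_module_score <- function(scaled, signature, cells = NULL) {
  sig_name <- attr(signature, "name") %||% "signature"
  present <- intersect(as.character(signature), colnames(scaled))
  if (!length(present))
    stop("no genes of signature '", sig_name, "' are present in the matrix")
  missing <- setdiff(as.character(signature), present)
  if (length(missing))
    warning(length(missing), " gene(s) of signature '", sig_name,
            "' absent from the matrix and dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(cells)) cells <- rownames(scaled)
  if (!all(cells %in% rownames(scaled)))
    stop("requested cells absent from the matrix")
  m <- rowMeans(scaled[cells, present, drop = FALSE])
  score <- rep(-Inf, length(m))
  ok <- m > -1
  score[ok] <- log1p(m[ok])
  names(score) <- cells
  attr(score, "signature") <- sig_name
  attr(score, "n_genes_used") <- length(present)
  score
}

#' Call Breg cells from signature scores
#'
#' A cell is Breg iff its Breg-signature score is strictly greater than
#' the threshold ("higher than 0.16"); a score of exactly 0.16 is
#' non-Breg.
#'
#' @param scores Per-cell scores from [compute_module_score()].
#' @param threshold Breg score threshold.
#' @return Data frame: barcode, breg_score, is_breg; columns `b10_score`,
#'   `is_b10` initialized `NA` until [call_b10()]. Thresholds kept as
#'   attributes.
#' @export
call_breg <- function(scores, threshold = 0.16) {
  calls <- data.frame(
    barcode = names(scores), breg_score = as.numeric(scores),
    is_breg = as.numeric(scores) > threshold,
    b10_score = NA_real_, is_b10 = NA, stringsAsFactors = FALSE)
  attr(calls, "breg_threshold") <- threshold
  calls
}

#' Partition Breg cells into B10 and non-B10
#'
#' Applies the B10-signature score to Breg cells only: a Breg cell is B10
#' iff its B10 score is strictly above the threshold; non-B10 Breg cells
#' are Breg and not B10. The default threshold 0 is the signature-neutral
#' point of the z-scored mean (score of an average cell); it is exposed
#' because the operating point behind "high B10 signature score" is a
#' tunable.
#'
#' @param calls Data frame from [call_breg()].
#' @param b10_scores Scores from [compute_module_score()] computed on the
#'   Breg cells (scoring any non-Breg cell is an error).
#' @param threshold B10 score threshold.
#' @return The updated calls data frame.
#' @export
call_b10 <- function(calls, b10_scores, threshold = 0) {
  breg <- calls$barcode[calls$is_breg]
  extra <- setdiff(names(b10_scores), breg)
  if (length(extra))
    stop("B10 scores supplied for non-Breg cells: ",
         paste(utils::head(extra, 5), collapse = ", "))
  idx <- match(names(b10_scores), calls$barcode)
  calls$b10_score[idx] <- as.numeric(b10_scores)
  calls$is_b10[idx] <- as.numeric(b10_scores) > threshold
  calls$is_b10[!calls$is_breg] <- FALSE
  attr(calls, "b10_threshold") <- threshold
  calls
}

#' Calibrate a score threshold by a two-means split
#'
#' Unsupervised operating point for a bimodal score: a deterministic 1-D
#' 2-means clustering (centers initialized at the lower and upper
#' quartiles) and the midpoint of the two final centers as the threshold.
#' Used to place the B10 cut when no externally given operating point
#' exists; falls back to the median for degenerate (constant) scores.
#'
#' @param scores Numeric scores (finite values used).
#' @return A single threshold value.
#' @export
calibrate_threshold <- function(scores) {
  x <- scores[is.finite(scores)]
  if (length(unique(x)) < 3) return(stats::median(x))
  init <- sort(stats::quantile(x, c(0.25, 0.75)))
  if (diff(init) < 1e-12) return(stats::median(x))
  km <- stats::kmeans(x, centers = init)
  mean(km$centers)
}

#' Composition tables of Breg and B10 calls
#'
#' Per organ: the fraction of B cells called Breg. Per cluster (when
#' cluster labels are given): the distribution of the cluster's cells over
#' organs and its B10 / non-B10 split. Organs or clusters with zero cells
#' are omitted with a message. Each proportion block sums to one.
#'
#' @param calls Calls data frame ([call_breg()] / [call_b10()]).
#' @param organs Named organ per barcode (names = barcodes) or a vector
#'   aligned with `calls$barcode`.
#' @param clusters Optional per-Breg-cell cluster labels (named by
#'   barcode).
#' @return A list of data frames: `organ` (n_cells, n_breg,
#'   breg_fraction), and when clusters are given `cluster_by_organ` and
#'   `cluster_b10` proportion tables.
#' @export
composition_table <- function(calls, organs, clusters = NULL) {
  org <- if (!is.null(names(organs))) organs[calls$barcode] else organs
  stopifnot(length(org) == nrow(calls))
  declared <- if (is.factor(organs)) levels(organs) else
    unique(as.character(organs[!is.na(organs)]))
  org <- as.character(org)
  keep <- !is.na(org)
  empty <- setdiff(declared, org[keep])
  if (length(empty))
    message("omitting organ(s) with zero cells: ", paste(empty, collapse = ", "))
  n <- table(org[keep])
  nb <- table(factor(org[keep], names(n)), calls$is_breg[keep])
  n_breg <- if ("TRUE" %in% colnames(nb)) nb[, "TRUE"] else rep(0L, length(n))
  organ_tab <- data.frame(organ = names(n), n_cells = as.integer(n),
                          n_breg = as.integer(n_breg),
                          breg_fraction = as.numeric(n_breg / n))
  out <- list(organ = organ_tab)
  if (!is.null(clusters)) {
    cl_bc <- names(clusters)
    cl_org <- org[match(cl_bc, calls$barcode)]
    tab <- table(cluster = as.character(clusters), organ = cl_org)
    out$cluster_by_organ <- as.data.frame(prop.table(tab, 1))
    b10 <- calls$is_b10[match(cl_bc, calls$barcode)]
    tb <- table(cluster = as.character(clusters),
                b10 = ifelse(b10, "B10", "non-B10"))
    out$cluster_b10 <- as.data.frame(prop.table(tb, 1))
  }
  out
}
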