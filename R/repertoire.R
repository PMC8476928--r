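## Clonotype assignment from contig annotations, pairwise organ sharing,
## and entropy-based clonal indices (bits, base 2):
##   expansion(cluster)   = 1 - H(clonotype freqs) / log2 K
##   migration(cluster)   = sum_i w_i * H(tissue split of clone i)
##   transition(a, b)     = sum_i w_i * H(two-cluster split of clone i)
## with w_i the clone-size share. Base 2 makes the two-group transition
## index naturally bounded by 1.

.entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Assign clonotypes from BCR contig records
#'
#' The clonotype key of a cell is the lexicographically sorted set of its
#' productive chain sub-keys `chain:v_gene:cdr3` (amino-acid CDR3 by
#' default, nucleotide with `key_mode = "nt"`), joined with `";"`. Two
#' cells belong to one clonotype iff their canonical keys are
#' string-equal; record order never matters. Cells with no productive
#' chains are excluded. Unmatched (orphan) contigs are excluded when a
#' `matched` column is present.
#'
#' @param contigs Contig data frame (barcode, chain, v_gene, cdr3,
#'   cdr3_nt, optionally productive/matched).
#' @param cells Optional data frame with `barcode` plus `organ` and/or
#'   `cluster` columns to merge onto the assignment.
#' @param key_mode `"aa"` (default) or `"nt"` CDR3 level.
#' @return Data frame: barcode, clonotype (canonical key), clone_size,
#'   and any merged organ/cluster columns.
#' @export
assign_clonotypes <- function(contigs, cells = NULL, key_mode = c("aa", "nt")) {
  key_mode <- match.arg(key_mode)
  use <- contigs
  if (!is.null(use$matched)) use <- use[use$matched, , drop = FALSE]
  if (!is.null(use$productive))
    use <- use[use$productive %in% c("True", "TRUE", TRUE), , drop = FALSE]
  if (!nrow(use))
    return(data.frame(barcode = character(0), clonotype = character(0),
                      clone_size = integer(0)))
  cdr3 <- if (key_mode == "aa") use$cdr3 else use$cdr3_nt
  sub <- paste(use$chain, use$v_gene, cdr3, sep = ":")
  key <- vapply(split(sub, use$barcode),
                function(s) paste(sort(unique(s)), collapse = ";"), "")
  assign <- data.frame(barcode = names(key), clonotype = unname(key),
                       stringsAsFactors = FALSE)
  sizes <- table(assign$clonotype)
  assign$clone_size <- as.integer(sizes[assign$clonotype])
  if (!is.null(cells)) {
    idx <- match(assign$barcode, cells$barcode)
    for (col in intersect(c("organ", "cluster"), names(cells)))
      assign[[col]] <- cells[[col]][idx]
  }
  rownames(assign) <- NULL
  attr(assign, "key_mode") <- key_mode
  assign
}

#' Pairwise organ sharing of clonotypes and cells
#'
#' For every organ pair (A, B): the shared-clonotype count is the number
#' of clonotypes present in both organs; the shared-cell count is the
#' number of cells of A and B together that carry a clonotype shared by
#' the pair (both sides counted). Matrices are symmetric with zero
#' diagonal by convention.
#'
#' @param assign Assignment from [assign_clonotypes()] with an `organ`
#'   column.
#' @param scope Optional barcodes restricting the analysis (e.g. Breg
#'   cells).
#' @return A list of two organ x organ matrices: `clonotypes`, `cells`.
#' @export
pairwise_sharing <- function(assign, scope = NULL) {
  a <- assign
  if (!is.null(scope)) a <- a[a$barcode %in% scope, , drop = FALSE]
  if (!nrow(a)) stop("no cells in scope")
  stopifnot(!is.null(a$organ))
  organs <- sort(unique(a$organ))
  k <- length(organs)
  shared_ct <- matrix(0L, k, k, dimnames = list(organs, organs))
  shared_cells <- matrix(0L, k, k, dimnames = list(organs, organs))
  by_organ <- split(a$clonotype, a$organ)
  if (k > 1) for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    common <- intersect(unique(by_organ[[organs[i]]]),
                        unique(by_organ[[organs[j]]]))
    shared_ct[i, j] <- shared_ct[j, i] <- length(common)
    n_cells <- sum(a$organ %in% organs[c(i, j)] & a$clonotype %in% common)
    shared_cells[i, j] <- shared_cells[j, i] <- n_cells
  }
  list(clonotypes = shared_ct, cells = shared_cells)
}

.cluster_rows <- function(assign, cluster) {
  stopifnot(!is.null(assign$cluster))
  rows <- assign[!is.na(assign$cluster) & assign$cluster == cluster, , drop = FALSE]
  if (!nrow(rows)) stop("cluster ", cluster, " is empty")
  rows
}

#' Clonal expansion index of a cluster
#'
#' One minus the normalized Shannon entropy (base 2) of clonotype
#' frequencies among the cluster's cells: 0 when every clonotype is a
#' singleton, 1 for a multi-cell monoclonal cluster. A single-cell
#' cluster returns 0 by convention (a singleton carries no evidence of
#' expansion).
#'
#' @param assign Assignment from [assign_clonotypes()] with a `cluster`
#'   column.
#' @param cluster Cluster label.
#' @return A number in \[0, 1\].
#' @export
expansion_index <- function(assign, cluster) {
  rows <- .cluster_rows(assign, cluster)
  sizes <- table(rows$clonotype)
  k <- length(sizes)
  if (k == 1) return(if (sum(sizes) >= 2) 1 else 0)
  1 - .entropy_bits(as.numeric(sizes)) / log2(k)
}

#' Clonal migration index of a cluster
#'
#' Clone-size-weighted mean of each clonotype's tissue entropy (base 2)
#' among the cluster's cells: 0 when every clone sits in one tissue,
#' log2(number of tissues) at most.
#'
#' @param assign Assignment with `cluster` and `organ` columns (organ =
#'   tissue label).
#' @param cluster Cluster label.
#' @return A non-negative number.
#' @export
migration_index <- function(assign, cluster) {
  rows <- .cluster_rows(assign, cluster)
  stopifnot(!is.null(rows$organ))
  h <- vapply(split(rows$organ, rows$clonotype),
              function(org) .entropy_bits(as.numeric(table(org))), numeric(1))
  w <- as.numeric(table(rows$clonotype)[names(h)]) / nrow(rows)
  sum(w * h)
}

#' Clonal transition index between two clusters
#'
#' Restricting to the cells of the two clusters, the clone-size-weighted
#' mean of each clonotype's entropy of split between them (base 2,
#' bounded by 1). Clones confined to one cluster contribute 0; disjoint
#' repertoires give 0; a clone split evenly gives 1. Symmetric in its
#' arguments.
#'
#' @param assign Assignment with a `cluster` column.
#' @param cluster_a,cluster_b Distinct cluster labels.
#' @return A number in \[0, 1\].
#' @export
transition_index <- function(assign, cluster_a, cluster_b) {
  if (identical(cluster_a, cluster_b))
    stop("transition index needs two distinct clusters")
  rows <- rbind(.cluster_rows(assign, cluster_a),
                .cluster_rows(assign, cluster_b))
  h <- vapply(split(rows$cluster, rows$clonotype),
              function(cl) .entropy_bits(as.numeric(table(cl))), numeric(1))
  w <- as.numeric(table(rows$clonotype)[names(h)]) / nrow(rows)
  sum(w * h)
}

#' Clonal index table over all clusters
#'
#' Expansion and migration per cluster plus the full pairwise transition
#' matrix.
#'
#' @param assign Assignment with `cluster` (and `organ` for migration)
#'   columns.
#' @return A list: `per_cluster` data frame (cluster, n_cells,
#'   n_clonotypes, expansion, migration) and `transition` matrix.
#' @export
clonal_index_table <- function(assign) {
  cl <- sort(unique(assign$cluster[!is.na(assign$cluster)]))
  per <- do.call(rbind, lapply(cl, function(c) {
    rows <- assign[!is.na(assign$cluster) & assign$cluster == c, ]
    data.frame(cluster = c, n_cells = nrow(rows),
               n_clonotypes = length(unique(rows$clonotype)),
               expansion = expansion_index(assign, c),
               migration = if (is.null(assign$organ)) NA_real_
                           else migration_index(assign, c))
  }))
  trans <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
  if (length(cl) > 1) for (i in seq_len(length(cl) - 1))
    for (j in (i + 1):length(cl))
      trans[i, j] <- trans[j, i] <- transition_index(assign, cl[i], cl[j])
  list(per_cluster = per, transition = trans)
}

#' Most expanded clonotypes
#'
#' Clonotypes ranked by cell count, ties broken lexicographically by key
#' for determinism, with per-organ (and per-cluster when present) cell
#' counts.
#'
#' @param assign Assignment from [assign_clonotypes()].
#' @param n Number of clonotypes to return (all if fewer exist).
#' @return Data frame: rank, clonotype, n_cells, then one count column
#'   per organ/cluster level.
#' @export
top_clonotypes <- function(assign, n = 10) {
  stopifnot(nrow(assign) >= 1)
  sizes <- table(assign$clonotype)
  ord <- order(-as.numeric(sizes), names(sizes))
  keys <- names(sizes)[ord][seq_len(min(n, length(sizes)))]
  out <- data.frame(rank = seq_along(keys), clonotype = keys,
                    n_cells = as.integer(sizes[keys]),
                    stringsAsFactors = FALSE)
  for (col in intersect(c("organ", "cluster"), names(assign))) {
    tab <- table(assign$clonotype, assign[[col]])
    cnt <- as.data.frame.matrix(tab[keys, , drop = FALSE])
    names(cnt) <- paste(col, names(cnt), sep = "_")
    out <- cbind(out, cnt)
  }
  rownames(out) <- NULL
  out
}

#' Export clonotype assignments as an AIRR-style rearrangement TSV
#'
#' One row per contig record with its cell's clonotype key, using AIRR
#' Rearrangement column names (`cell_id`, `locus`, `v_call`,
#' `junction_aa`, `junction`, `clone_id`).
#'
#' @param contigs Contig data frame.
#' @param assign Assignment from [assign_clonotypes()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_airr <- function(contigs, assign, path) {
  idx <- match(contigs$barcode, assign$barcode)
  airr <- data.frame(
    cell_id = contigs$barcode, locus = contigs$chain,
    v_call = contigs$v_gene, junction_aa = contigs$cdr3,
    junction = contigs$cdr3_nt,
    productive = if (is.null(contigs$productive)) "T" else contigs$productive,
    clone_id = assign$clonotype[idx], stringsAsFactors = FALSE)
  utils::write.table(airr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
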