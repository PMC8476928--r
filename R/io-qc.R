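## Reading the 10x-style bundle and the cell/gene/BCR quality-control
## filters. All QC boundaries are strict inequalities: a cell is removed
## only when it exceeds a bound ("more than" / "less than"), never when it
## sits exactly on it.

#' Quality-control thresholds
#'
#' @param min_genes Cells with fewer unique genes are removed (strict:
#'   exactly `min_genes` is kept).
#' @param max_genes Cells with more unique genes are removed (strict).
#' @param max_pct_mito Cells with a higher mitochondrial percentage
#'   (0-100) are removed (strict).
#' @param min_complexity Cells with lower `log10(genes)/log10(UMIs)` are
#'   removed (strict).
#' @param min_cells_per_gene Genes expressed in fewer cells are removed
#'   (a gene seen in exactly this many cells is kept).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 300, max_genes = 8000,
                          max_pct_mito = 10, min_complexity = 0.8,
                          min_cells_per_gene = 10) {
  stopifnot(min_genes < max_genes,
            min_genes > 0, max_pct_mito > 0, min_complexity > 0,
            min_cells_per_gene > 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_pct_mito = max_pct_mito,
                 min_complexity = min_complexity,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

.validate_counts <- function(counts) {
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell barcodes: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene symbols: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts@x < 0)) stop("negative counts")
  invisible(counts)
}

#' Read a 10x-style bundle written by [write_tenx_bundle()]
#'
#' Reads the Matrix Market counts (stored genes x cells, returned
#' cells x genes), the barcode and feature lists, the per-cell organ
#' table and the BCR contig annotations. Contigs whose barcode is absent
#' from the matrix are retained but flagged (`matched = FALSE`); they are
#' excluded from multichain doublet flagging but kept for repertoire
#' export.
#'
#' @param directory Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv`, and optionally `cell_metadata.csv` and `contigs.csv`.
#' @return A list: `counts` (cells x genes `dgCMatrix`), `cells`
#'   (data frame with barcode and organ), `contigs` (data frame or `NULL`).
#' @export
read_tenx_bundle <- function(directory) {
  need <- file.path(directory, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  if (!all(file.exists(need)))
    stop("missing bundle files: ",
         paste(basename(need[!file.exists(need)]), collapse = ", "))
  m <- Matrix::readMM(need[1])
  barcodes <- readLines(need[2])
  feat <- utils::read.table(need[3], sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  symbols <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  if (anyDuplicated(symbols))
    stop("duplicated gene symbol in features file: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  if (nrow(m) != length(symbols) || ncol(m) != length(barcodes))
    stop("matrix dimensions disagree with barcodes/features files")
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(barcodes, symbols)
  .validate_counts(counts)

  meta_path <- file.path(directory, "cell_metadata.csv")
  cells <- if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    missing <- setdiff(meta$barcode, barcodes)
    if (length(missing))
      stop("cells present in organ table but absent from the matrix: ",
           paste(utils::head(missing, 5), collapse = ", "))
    meta[match(barcodes, meta$barcode), , drop = FALSE]
  } else {
    data.frame(barcode = barcodes, organ = NA_character_,
               stringsAsFactors = FALSE)
  }
  rownames(cells) <- NULL

  contig_path <- file.path(directory, "contigs.csv")
  contigs <- NULL
  if (file.exists(contig_path)) {
    contigs <- utils::read.csv(contig_path, stringsAsFactors = FALSE)
    if (nrow(contigs)) contigs$matched <- contigs$barcode %in% barcodes
  }
  list(counts = counts, cells = cells, contigs = contigs)
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell: the number of detected genes (`n_genes`),
#' total UMI count (`n_umi`), mitochondrial percentage (`pct_mito`, genes
#' matched by a case-insensitive symbol prefix) and transcriptome
#' complexity `log10(n_genes)/log10(n_umi)`. Complexity is undefined
#' (`NA`) when `n_umi <= 1`; such cells fail QC.
#'
#' @param counts Cells x genes count matrix.
#' @param mito_prefix Prefix identifying mitochondrial gene symbols
#'   (mouse convention `"mt-"`), matched case-insensitively.
#' @return Data frame: barcode, n_genes, n_umi, pct_mito, complexity.
#' @examples
#' m <- Matrix::Matrix(c(0, 3, 7, 0), 2, 2, sparse = TRUE,
#'                     dimnames = list(c("c1", "c2"), c("mt-Co1", "GeneA")))
#' compute_cell_metrics(m)
#' @export
compute_cell_metrics <- function(counts, mito_prefix = "mt-") {
  .validate_counts(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  n_umi <- Matrix::rowSums(counts)
  mito <- startsWith(tolower(colnames(counts)), tolower(mito_prefix))
  mito_umi <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) else 0
  pct_mito <- ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0)
  complexity <- ifelse(n_umi > 1, log10(pmax(n_genes, 1)) / log10(n_umi), NA_real_)
  data.frame(barcode = rownames(counts), n_genes = as.integer(n_genes),
             n_umi = as.numeric(n_umi), pct_mito = as.numeric(pct_mito),
             complexity = as.numeric(complexity), stringsAsFactors = FALSE)
}

#' Apply the per-cell quality-control filters
#'
#' A cell is removed iff `n_genes > max_genes` OR `n_genes < min_genes` OR
#' `pct_mito > max_pct_mito` OR `complexity < min_complexity` (undefined
#' complexity counts as failing). All comparisons are strict, so boundary
#' cells (exactly 300 or 8000 genes, exactly 10% mitochondrial, complexity
#' exactly 0.8) are kept. Each removed cell carries every reason that
#' applies.
#'
#' @param metrics Data frame from [compute_cell_metrics()].
#' @param thresholds A [qc_thresholds()].
#' @return A list: `kept` (character barcodes) and `report` (metrics plus
#'   `kept` flag and comma-separated `reasons`).
#' @export
apply_cell_filters <- function(metrics, thresholds = qc_thresholds()) {
  t <- thresholds
  fail <- cbind(
    min_genes = metrics$n_genes < t$min_genes,
    max_genes = metrics$n_genes > t$max_genes,
    max_pct_mito = metrics$pct_mito > t$max_pct_mito,
    min_complexity = is.na(metrics$complexity) |
      metrics$complexity < t$min_complexity)
  reasons <- apply(fail, 1, function(f)
    paste(colnames(fail)[f], collapse = ","))
  report <- metrics
  report$kept <- !apply(fail, 1, any)
  report$reasons <- reasons
  list(kept = metrics$barcode[report$kept], report = report)
}

#' Filter genes by the number of expressing cells
#'
#' A gene is kept iff it has a positive count in at least `min_cells`
#' cells ("10 or more"); a gene seen in exactly `min_cells` cells is kept,
#' one seen in `min_cells - 1` is removed. Intended to run after cell
#' filtering, on the retained cells.
#'
#' @param counts Cells x genes count matrix (post cell-QC).
#' @param min_cells Minimum number of expressing cells.
#' @return Character vector of kept gene symbols.
#' @export
apply_gene_filter <- function(counts, min_cells = 10) {
  n_cells_expr <- Matrix::colSums(counts > 0)
  colnames(counts)[n_cells_expr >= min_cells]
}

#' Flag BCR multichain doublet cells
#'
#' A cell is flagged iff it carries at least two distinct heavy-chain
#' identities AND at least two distinct light-chain identities (the
#' default reading of "two different heavy chains and two different light
#' chains"); `rule = "or"` flags on either chain class alone.
#' Distinctness uses the clonotype chain key (`chain:v_gene:cdr3`). Cells
#' with no BCR records are never flagged. Contigs flagged unmatched (no
#' expression barcode) are ignored here.
#'
#' @param contigs Contig data frame with columns barcode, chain, v_gene,
#'   cdr3 (and optionally `matched`, `productive`).
#' @param rule `"and"` (default) or `"or"` over the two chain classes.
#' @return Character vector of flagged barcodes.
#' @export
flag_multichain_cells <- function(contigs, rule = c("and", "or")) {
  rule <- match.arg(rule)
  if (is.null(contigs) || !nrow(contigs)) return(character(0))
  bad <- setdiff(unique(contigs$chain), c("IGH", "IGK", "IGL"))
  if (length(bad))
    stop("invalid BCR chain class: ", paste(bad, collapse = ", "))
  use <- contigs
  if (!is.null(use$matched)) use <- use[use$matched, , drop = FALSE]
  if (!is.null(use$productive))
    use <- use[use$productive %in% c("True", "TRUE", TRUE), , drop = FALSE]
  if (!nrow(use)) return(character(0))
  key <- paste(use$chain, use$v_gene, use$cdr3, sep = ":")
  heavy <- use$chain == "IGH"
  n_h <- tapply(key[heavy], use$barcode[heavy], function(k) length(unique(k)))
  n_l <- tapply(key[!heavy], use$barcode[!heavy], function(k) length(unique(k)))
  cells <- unique(use$barcode)
  nh <- ifelse(is.na(n_h[cells]), 0L, n_h[cells])
  nl <- ifelse(is.na(n_l[cells]), 0L, n_l[cells])
  flagged <- if (rule == "and") nh >= 2 & nl >= 2 else nh >= 2 | nl >= 2
  sort(cells[flagged])
}

#' Run the full QC stage in the fixed order
#'
#' Applies the filters in the documented order: per-cell metric filters,
#' then the minimum-cells gene filter on the retained cells, then BCR
#' multichain doublet removal. Returns the filtered matrix, a QC report
#' and a per-rule removal summary.
#'
#' @param counts Cells x genes count matrix.
#' @param contigs Contig data frame (or `NULL` to skip the BCR rule).
#' @param thresholds A [qc_thresholds()].
#' @param mito_prefix Mitochondrial symbol prefix.
#' @param multichain_rule Passed to [flag_multichain_cells()].
#' @return A list: `counts` (filtered), `report` (per-cell QC report with
#'   a `multichain` column), `summary` (data frame of removals per rule in
#'   application order), `kept_genes`, `removed_multichain`.
#' @export
run_qc <- function(counts, contigs = NULL, thresholds = qc_thresholds(),
                   mito_prefix = "mt-", multichain_rule = "and") {
  metrics <- compute_cell_metrics(counts, mito_prefix)
  cellf <- apply_cell_filters(metrics, thresholds)
  kept <- counts[cellf$kept, , drop = FALSE]
  genes <- apply_gene_filter(kept, thresholds$min_cells_per_gene)
  kept <- kept[, genes, drop = FALSE]
  multi <- if (is.null(contigs)) character(0) else
    flag_multichain_cells(contigs, multichain_rule)
  multi <- intersect(multi, rownames(kept))
  kept <- kept[setdiff(rownames(kept), multi), , drop = FALSE]

  report <- cellf$report
  report$multichain <- report$barcode %in% multi
  report$kept <- report$kept & !report$multichain
  report$reasons <- ifelse(
    report$multichain,
    ifelse(report$reasons == "", "multichain",
           paste(report$reasons, "multichain", sep = ",")),
    report$reasons)
  summary <- data.frame(
    rule = c("cell_metrics", "gene_min_cells", "bcr_multichain"),
    removed = c(nrow(counts) - length(cellf$kept),
                ncol(counts) - length(genes), length(multi)),
    unit = c("cells", "genes", "cells"))
  list(counts = kept, report = report, summary = summary,
       kept_genes = genes, removed_multichain = multi)
}
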