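## Multi-organ synthetic dataset generator with planted Breg/B10 truth.
## Expression model: per-gene relative abundances are log-normal, per-cell
## library-size factors gamma, counts negative-binomial. Planted Breg cells
## have signature-gene means multiplied by signature_effect; planted B10
## cells additionally have B10-signature gene means multiplied by b10_effect.

.mouse_mito_symbols <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8",
                         "mt-Atp6", "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4",
                         "mt-Nd5", "mt-Nd6", "mt-Cytb")

.sim_gene_table <- function(config) {
  n <- config$n_genes
  n_mito <- config$n_mito_genes
  n_sig <- config$n_signature_genes
  n_b10 <- config$n_b10_signature_genes
  mito <- if (n_mito <= length(.mouse_mito_symbols)) {
    .mouse_mito_symbols[seq_len(n_mito)]
  } else {
    c(.mouse_mito_symbols,
      sprintf("mt-G%d", seq_len(n_mito - length(.mouse_mito_symbols))))
  }
  sig <- sprintf("Bregsig%03d", seq_len(n_sig))
  b10 <- sprintf("B10sig%02d", seq_len(n_b10))
  other <- sprintf("Gene%04d", seq_len(n - n_mito - n_sig - n_b10))
  data.frame(
    gene = c(mito, sig, b10, other),
    is_mito = rep(c(TRUE, FALSE), c(n_mito, n - n_mito)),
    is_signature = rep(c(FALSE, TRUE, FALSE), c(n_mito, n_sig, n - n_mito - n_sig)),
    is_b10_signature = rep(c(FALSE, TRUE, FALSE),
                           c(n_mito + n_sig, n_b10, n - n_mito - n_sig - n_b10)),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-organ cell-by-gene count matrix with planted truth
#'
#' Draws unique-molecule counts from a negative-binomial model: gene
#' relative abundances are log-normal (mitochondrial genes boosted so the
#' average mitochondrial fraction is a realistic few percent), per-cell
#' library-size factors follow a gamma law, and counts are
#' `NB(mu, dispersion)`. Cells planted as Breg get their Breg-signature
#' gene means multiplied by `signature_effect`; planted B10 cells (a subset
#' of Breg) additionally get `b10_effect` on the B10-signature genes.
#' Multichain-doublet status is drawn here so the expression and repertoire
#' layers agree on which cells are doublets.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{counts}{sparse `dgCMatrix`, cells x genes, barcodes as row
#'       names and gene symbols as column names.}
#'     \item{cell_truth}{data frame: barcode, organ, is_breg, is_b10,
#'       is_multichain_doublet, library_factor.}
#'     \item{gene_truth}{data frame: gene, is_mito, is_signature,
#'       is_b10_signature.}
#'   }
#' @examples
#' sim <- generate_expression(sim_config(seed = 1, cells_per_organ = 40,
#'                                       n_genes = 300))
#' dim(sim$counts)
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- .sim_gene_table(config)
  n_genes <- config$n_genes
  n_cells <- config$cells_per_organ * length(config$organs)

  ## relative abundance: heavy-tailed background, moderately expressed
  ## signature genes (so scores are informative), high mito weight
  w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  sig_idx <- which(genes$is_signature | genes$is_b10_signature)
  w[sig_idx] <- stats::rlnorm(length(sig_idx), meanlog = 0.5, sdlog = 0.8)
  ## mitochondrial reads are a fixed ~5% share of the transcriptome,
  ## independent of panel size
  if (any(genes$is_mito)) {
    wm <- stats::rlnorm(sum(genes$is_mito), meanlog = 0, sdlog = 0.4)
    w[genes$is_mito] <- wm / sum(wm) * 0.05 / 0.95 * sum(w[!genes$is_mito])
  }
  w <- w / sum(w)

  organ <- rep(config$organs, each = config$cells_per_organ)
  barcode <- sprintf("%s-%05d", organ, seq_len(n_cells))
  is_breg <- stats::runif(n_cells) < config$breg_fraction[organ]
  is_b10 <- is_breg & stats::runif(n_cells) < config$b10_fraction_of_breg
  is_doublet <- stats::runif(n_cells) < config$doublet_multichain_rate

  lib <- stats::rgamma(n_cells, shape = config$library_size_shape,
                       rate = config$library_size_shape / config$library_size_mean)

  size <- 1 / config$nb_dispersion
  sig_cols <- which(genes$is_signature)
  b10_cols <- which(genes$is_b10_signature)
  counts <- matrix(0L, n_cells, n_genes,
                   dimnames = list(barcode, genes$gene))
  for (i in seq_len(n_cells)) {
    mu <- w
    if (is_breg[i]) mu[sig_cols] <- mu[sig_cols] * config$signature_effect
    if (is_b10[i]) mu[b10_cols] <- mu[b10_cols] * config$b10_effect
    counts[i, ] <- stats::rnbinom(n_genes, mu = lib[i] * mu, size = size)
  }
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  cell_truth <- data.frame(
    barcode = barcode, organ = organ, is_breg = is_breg, is_b10 = is_b10,
    is_multichain_doublet = is_doublet, library_factor = lib,
    stringsAsFactors = FALSE)
  list(counts = counts, cell_truth = cell_truth, gene_truth = genes)
}

## ---- repertoire ------------------------------------------------------------

.aa_alphabet <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))

.codon_table <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

.random_cdr3 <- function() {
  len <- sample(6:13, 1L)
  paste0("C", paste(sample(.aa_alphabet, len, replace = TRUE), collapse = ""),
         sample(c("W", "F"), 1L))
}

.backtranslate <- function(aa) {
  paste(vapply(strsplit(aa, "")[[1]],
               function(a) sample(.codon_table[[a]], 1L), ""), collapse = "")
}

## One clonotype = paired heavy + light chain identity (V gene + CDR3).
.new_clonotype <- function() {
  h_cdr3 <- .random_cdr3()
  light_chain <- sample(c("IGK", "IGL"), 1L, prob = c(0.9, 0.1))
  l_cdr3 <- .random_cdr3()
  list(
    h_v = sprintf("Ighv%d-%d", sample(1:14, 1L), sample(1:80, 1L)),
    h_cdr3 = h_cdr3, h_nt = .backtranslate(h_cdr3),
    l_chain = light_chain,
    l_v = sprintf("%sv%d-%d", ifelse(light_chain == "IGK", "Igk", "Igl"),
                  sample(1:20, 1L), sample(1:130, 1L)),
    l_cdr3 = l_cdr3, l_nt = .backtranslate(l_cdr3))
}

.contig_rows <- function(barcode, ct, suffix) {
  data.frame(
    barcode = barcode, is_cell = "True",
    contig_id = paste0(barcode, "_contig_", suffix, c("H", "L")),
    high_confidence = "True",
    length = nchar(c(ct$h_nt, ct$l_nt)) + 300L,
    chain = c("IGH", ct$l_chain),
    v_gene = c(ct$h_v, ct$l_v), d_gene = c("IGHD1-1", "None"),
    j_gene = c("IGHJ2", ifelse(ct$l_chain == "IGK", "IGKJ1", "IGLJ1")),
    c_gene = c("IGHM", ifelse(ct$l_chain == "IGK", "IGKC", "IGLC1")),
    full_length = "True", productive = "True",
    cdr3 = c(ct$h_cdr3, ct$l_cdr3), cdr3_nt = c(ct$h_nt, ct$l_nt),
    reads = sample(500:5000, 2L), umis = sample(2:40, 2L),
    stringsAsFactors = FALSE)
}

#' Simulate the paired BCR contig table for a generated dataset
#'
#' Every non-doublet cell receives one productive heavy (IGH) and one light
#' (IGK/IGL) chain. Clonotype identities are planted so that
#' `expanded_clone_count` clones reach `expanded_clone_size` cells (in the
#' expanded-clone organ, PC by default), each row of `shared_clone_pairs`
#' contributes clones spanning its organ pair (two cells per organ), and
#' every remaining cell is a singleton clonotype. Multichain-doublet cells
#' receive two heavy plus two light chains drawn from two fresh clonotypes
#' that never re-use a planted identity, so planted sharing and expansion
#' counts stay exact. CDR3 amino-acid strings start with "C" and end with
#' "W" or "F"; nucleotide strings are random in-frame back-translations.
#'
#' @param config The [sim_config()] used for [generate_expression()].
#' @param truth The `cell_truth` data frame (or the full list) returned by
#'   [generate_expression()] under the same config.
#' @return A list with
#'   \describe{
#'     \item{contigs}{data frame in 10x `filtered_contig_annotations.csv`
#'       layout (barcode, chain, v_gene, cdr3, cdr3_nt, ...).}
#'     \item{clone_truth}{data frame: barcode, clonotype id (`NA` for
#'       doublets), clone class (`"expanded"`, `"shared"`, `"singleton"`).}
#'   }
#' @export
generate_repertoire <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$cell_truth))
    truth <- truth$cell_truth
  stopifnot(all(c("barcode", "organ", "is_multichain_doublet") %in% names(truth)))
  set.seed((config$seed %% 2147483646L) + 1L)  # distinct stream, no overflow

  singlet <- truth[!truth$is_multichain_doublet, ]
  pool <- split(singlet$barcode, singlet$organ)
  take <- function(organ, k) {
    avail <- pool[[organ]]
    if (length(avail) < k)
      stop(sprintf("organ %s has %d unassigned cells, %d requested",
                   organ, length(avail), k))
    picked <- avail[seq_len(k)]
    pool[[organ]] <<- avail[-seq_len(k)]
    picked
  }

  assign_tab <- list()
  clone_id <- 0L
  plant <- function(barcodes, class) {
    clone_id <<- clone_id + 1L
    assign_tab[[length(assign_tab) + 1L]] <<- data.frame(
      barcode = barcodes, clonotype_id = sprintf("clone%05d", clone_id),
      clone_class = class, stringsAsFactors = FALSE)
  }

  for (i in seq_len(config$expanded_clone_count))
    plant(take(config$expanded_clone_organ, config$expanded_clone_size),
          "expanded")
  sp <- config$shared_clone_pairs
  if (nrow(sp)) for (i in seq_len(nrow(sp))) for (j in seq_len(sp$n[i]))
    plant(c(take(sp$organ_a[i], 2L), take(sp$organ_b[i], 2L)), "shared")
  for (org in names(pool)) for (bc in pool[[org]]) plant(bc, "singleton")

  assign_tab <- do.call(rbind, assign_tab)
  if (!is.null(config$n_clonotypes) && config$n_clonotypes < clone_id)
    stop(sprintf("n_clonotypes = %d but the planted structure needs %d",
                 config$n_clonotypes, clone_id))

  ## one chain-pair identity per clonotype, unique by construction check
  ids <- unique(assign_tab$clonotype_id)
  cts <- replicate(length(ids), .new_clonotype(), simplify = FALSE)
  names(cts) <- ids
  keys <- vapply(cts, function(ct) paste(ct$h_v, ct$h_cdr3, ct$l_v, ct$l_cdr3), "")
  while (anyDuplicated(keys)) {
    dup <- which(duplicated(keys))
    cts[dup] <- replicate(length(dup), .new_clonotype(), simplify = FALSE)
    keys <- vapply(cts, function(ct) paste(ct$h_v, ct$h_cdr3, ct$l_v, ct$l_cdr3), "")
  }

  rows <- vector("list", nrow(assign_tab) + 2L * sum(truth$is_multichain_doublet))
  k <- 0L
  for (i in seq_len(nrow(assign_tab))) {
    k <- k + 1L
    rows[[k]] <- .contig_rows(assign_tab$barcode[i],
                              cts[[assign_tab$clonotype_id[i]]], "1")
  }
  for (bc in truth$barcode[truth$is_multichain_doublet]) {
    for (s in c("1", "2")) {
      k <- k + 1L
      rows[[k]] <- .contig_rows(bc, .new_clonotype(), s)
    }
  }
  contigs <- do.call(rbind, rows)
  rownames(contigs) <- NULL

  doublet_bc <- truth$barcode[truth$is_multichain_doublet]
  doublet_truth <- data.frame(
    barcode = doublet_bc,
    clonotype_id = rep(NA_character_, length(doublet_bc)),
    clone_class = rep("doublet", length(doublet_bc)),
    stringsAsFactors = FALSE)
  clone_truth <- rbind(assign_tab, doublet_truth)
  clone_truth <- clone_truth[match(truth$barcode, clone_truth$barcode), ]
  rownames(clone_truth) <- NULL
  list(contigs = contigs, clone_truth = clone_truth)
}

#' Generate a complete synthetic dataset (expression + repertoire)
#'
#' Convenience wrapper running [generate_expression()] then
#' [generate_repertoire()] under one config.
#'
#' @param config A [sim_config()].
#' @return A list: `counts`, `cell_truth` (with clonotype columns merged
#'   in), `gene_truth`, `contigs`.
#' @export
generate_dataset <- function(config) {
  sim <- generate_expression(config)
  rep <- generate_repertoire(config, sim$cell_truth)
  sim$cell_truth$clonotype_id <- rep$clone_truth$clonotype_id
  sim$cell_truth$clone_class <- rep$clone_truth$clone_class
  sim$contigs <- rep$contigs
  sim
}

#' Write a synthetic dataset as a 10x-style text bundle
#'
#' Writes `matrix.mtx` (Matrix Market, genes as rows and cells as columns,
#' 10x convention), `barcodes.tsv`, `features.tsv`, `cell_metadata.csv`
#' (barcode, organ), `contigs.csv` (10x filtered-contig column names),
#' `truth.csv` (per-cell planted labels) and `gene_truth.csv`. A round-trip
#' through [read_tenx_bundle()] reproduces the in-memory objects exactly.
#'
#' @param dataset A list as returned by [generate_dataset()] (or the
#'   matching pieces assembled by hand).
#' @param directory Output directory; created if absent.
#' @return The directory, invisibly.
#' @export
write_tenx_bundle <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  counts <- dataset$counts
  stopifnot(inherits(counts, "Matrix"))
  if (!is.null(dataset$cell_truth) &&
      !identical(rownames(counts), dataset$cell_truth$barcode))
    stop("barcodes of counts and cell_truth disagree")
  Matrix::writeMM(Matrix::t(counts), file.path(directory, "matrix.mtx"))
  writeLines(rownames(counts), file.path(directory, "barcodes.tsv"))
  feat <- data.frame(id = colnames(counts), symbol = colnames(counts),
                     type = "Gene Expression")
  utils::write.table(feat, file.path(directory, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- data.frame(barcode = rownames(counts),
                     organ = dataset$cell_truth$organ)
  utils::write.csv(meta, file.path(directory, "cell_metadata.csv"),
                   row.names = FALSE)
  contigs <- dataset$contigs
  if (is.null(contigs))
    contigs <- .contig_rows("x", .new_clonotype(), "1")[0, ]
  utils::write.csv(contigs, file.path(directory, "contigs.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$cell_truth))
    utils::write.csv(dataset$cell_truth, file.path(directory, "truth.csv"),
                     row.names = FALSE)
  if (!is.null(dataset$gene_truth))
    utils::write.csv(dataset$gene_truth, file.path(directory, "gene_truth.csv"),
                     row.names = FALSE)
  invisible(directory)
}
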