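# Shared fixtures: a small simulator configuration sized for fast tests,
# and builders for hand-written toy objects.

small_sim_config <- function(seed = 11, ...) {
  args <- list(seed = seed, cells_per_organ = 100L, n_genes = 400L,
               n_signature_genes = 40L, n_b10_signature_genes = 15L,
               library_size_mean = 400)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# QC thresholds scaled to small gene panels (the defaults assume a
# transcriptome-wide panel where 300+ detected genes is attainable)
small_qc_thresholds <- function() {
  qc_thresholds(min_genes = 30, max_genes = 8000, max_pct_mito = 10,
                min_complexity = 0.8, min_cells_per_gene = 3)
}

toy_counts <- function(values, barcodes = NULL, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- barcodes %||% sprintf("cell%02d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%02d", seq_len(ncol(m)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one contig record per chain; defaults give a productive matched record
toy_contig <- function(barcode, chain, v_gene, cdr3,
                       cdr3_nt = NULL, productive = "True") {
  data.frame(barcode = barcode, chain = chain, v_gene = v_gene,
             cdr3 = cdr3,
             cdr3_nt = cdr3_nt %||% strrep("ACG", nchar(cdr3)),
             productive = productive, stringsAsFactors = FALSE)
}

# clonotype assignment table written by hand for index tests
toy_assign <- function(clonotype, cluster = NULL, organ = NULL,
                       barcode = NULL) {
  df <- data.frame(
    barcode = barcode %||% sprintf("bc%02d", seq_along(clonotype)),
    clonotype = clonotype, stringsAsFactors = FALSE)
  sizes <- table(df$clonotype)
  df$clone_size <- as.integer(sizes[df$clonotype])
  if (!is.null(cluster)) df$cluster <- cluster
  if (!is.null(organ)) df$organ <- organ
  df
}

# independent brute-force entropy oracles: explicit probability tables,
# no shared code with the implementation
brute_entropy <- function(labels) {
  h <- 0
  for (lv in unique(labels)) {
    p <- sum(labels == lv) / length(labels)
    h <- h - p * log(p, base = 2)
  }
  h
}

brute_expansion <- function(clonotypes) {
  k <- length(unique(clonotypes))
  if (k == 1) return(if (length(clonotypes) >= 2) 1 else 0)
  1 - brute_entropy(clonotypes) / log(k, base = 2)
}

brute_weighted_entropy <- function(clonotypes, labels) {
  total <- 0
  for (ct in unique(clonotypes)) {
    in_ct <- clonotypes == ct
    total <- total + sum(in_ct) / length(clonotypes) *
      brute_entropy(labels[in_ct])
  }
  total
}
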