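## End-to-end orchestration: simulate (or read) -> QC -> normalize/scale ->
## signature scores and Breg/B10 calls -> Breg subset clustering ->
## per-organ DE + cross-organ markers -> repertoire indices. Every stage
## writes plain-text artifacts into the run directory and logs its
## in/out counts; the effective configuration is echoed verbatim.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score against binary labels; ties
#' midranked. Used to measure how well a signature score separates
#' planted truth.
#'
#' @param score Numeric scores.
#' @param label Logical (or 0/1) truth.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), any(label), any(!label))
  r <- rank(score)
  n1 <- sum(label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * sum(!label))
}

#' Pipeline run configuration
#'
#' Collects every parameter of [run_pipeline()]. Exactly one of `sim` or
#' `input_dir` must be given. All parameters affecting results are echoed
#' into `effective_config.yaml` in the run directory.
#'
#' @param out_dir Output directory for run artifacts.
#' @param sim A [sim_config()] to simulate inputs, or `NULL`.
#' @param input_dir Directory with a 10x-style bundle, or `NULL`.
#' @param breg_signature,b10_signature [gene_signature()] objects or
#'   plain-text list paths; `NULL` in simulation mode derives them from
#'   the generator's planted gene truth.
#' @param thresholds A [qc_thresholds()].
#' @param breg_threshold Breg score cut-off (strict `>`).
#' @param b10_threshold B10 score cut-off (strict `>`), or `"auto"`
#'   (default) to calibrate it from the B10 score distribution of Breg
#'   cells with [calibrate_threshold()].
#' @param sd_type,clip_max Scaling convention, see [zscore_scale()].
#' @param min_pct,fdr,min_log2fc Differential-expression parameters.
#' @param key_mode Clonotype CDR3 level, `"aa"` or `"nt"`.
#' @param multichain_rule `"and"` or `"or"`, see
#'   [flag_multichain_cells()].
#' @param n_hvg,n_pcs,resolution Breg subset clustering parameters.
#' @param seed Seed for clustering (and simulation when `sim` carries no
#'   explicit one).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, sim = NULL, input_dir = NULL,
                       breg_signature = NULL, b10_signature = NULL,
                       thresholds = qc_thresholds(),
                       breg_threshold = 0.16, b10_threshold = "auto",
                       sd_type = "sample", clip_max = 10,
                       min_pct = 0.1, fdr = 0.05, min_log2fc = 0.25,
                       key_mode = "aa", multichain_rule = "and",
                       n_hvg = 500, n_pcs = 30, resolution = 0.5,
                       seed = 1L) {
  if (is.null(sim) == is.null(input_dir))
    stop("exactly one of 'sim' or 'input_dir' must be given")
  if (!is.null(input_dir)) {
    if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
    if (is.null(breg_signature))
      stop("breg_signature is required when reading external input")
    if (is.null(b10_signature))
      stop("b10_signature is required when reading external input")
  }
  as_sig <- function(s, nm) {
    if (is.null(s) || inherits(s, "gene_signature")) s
    else if (is.character(s) && length(s) == 1 && file.exists(s))
      read_signature(s, nm)
    else gene_signature(s, nm)
  }
  cfg <- list(out_dir = out_dir, sim = sim, input_dir = input_dir,
              breg_signature = as_sig(breg_signature, "breg"),
              b10_signature = as_sig(b10_signature, "b10"),
              thresholds = thresholds,
              breg_threshold = breg_threshold, b10_threshold = b10_threshold,
              sd_type = sd_type, clip_max = clip_max,
              min_pct = min_pct, fdr = fdr, min_log2fc = min_log2fc,
              key_mode = key_mode, multichain_rule = multichain_rule,
              n_hvg = n_hvg, n_pcs = n_pcs, resolution = resolution,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

.echo_config <- function(config, path) {
  flat <- config
  class(flat) <- NULL
  flat$thresholds <- unclass(flat$thresholds)
  if (!is.null(flat$sim)) {
    s <- unclass(flat$sim)
    s$breg_fraction <- as.list(s$breg_fraction)
    s$shared_clone_pairs <- if (nrow(s$shared_clone_pairs))
      lapply(seq_len(nrow(s$shared_clone_pairs)), function(i)
        as.list(s$shared_clone_pairs[i, ])) else list()
    flat$sim <- s
  }
  for (f in c("breg_signature", "b10_signature"))
    if (!is.null(flat[[f]])) flat[[f]] <- as.character(flat[[f]])
  yaml::write_yaml(flat, path)
}

#' Run the full Breg identification pipeline
#'
#' Executes, in order: input (simulation or bundle read), QC (cell
#' filters, gene filter, BCR multichain removal), log-normalization and
#' z-score scaling, Breg module scoring and calling, B10 partition of
#' Breg cells, per-organ composition, Breg subset clustering, per-organ
#' Breg vs non-Breg differential expression with cross-organ
#' intersection, clonotype assignment, pairwise organ sharing (Breg
#' scope), clonal expansion/migration/transition indices, and — when
#' planted truth is available — a recovery report against it. All outputs
#' are plain CSV/TSV/JSON under `out_dir`; a rerun with an identical
#' config writes byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @return A `breg_run` object (list of all stage results), invisibly
#'   printable with `print()`/`summary()`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0("[", paste(...), "]")
    cat(paste0(paste(...), "\n"), file = log_path, append = TRUE)
    message(paste(...))
    invisible(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logmsg(sprintf("stage %-12s done in %.1fs", name,
                   proc.time()[["elapsed"]] - t0))
    res
  }
  .echo_config(config, file.path(out, "effective_config.yaml"))

  ## ---- input ----
  truth <- NULL
  input <- stage("input", {
    if (!is.null(config$sim)) {
      ds <- generate_dataset(config$sim)
      truth <- ds$cell_truth
      list(counts = ds$counts, cells = ds$cell_truth[, c("barcode", "organ")],
           contigs = ds$contigs, gene_truth = ds$gene_truth,
           cell_truth = ds$cell_truth)
    } else {
      read_tenx_bundle(config$input_dir)
    }
  })
  truth <- input$cell_truth
  breg_sig <- config$breg_signature
  b10_sig <- config$b10_signature
  if (is.null(breg_sig))
    breg_sig <- gene_signature(
      input$gene_truth$gene[input$gene_truth$is_signature], "breg")
  if (is.null(b10_sig))
    b10_sig <- gene_signature(
      input$gene_truth$gene[input$gene_truth$is_b10_signature], "b10")
  writeLines(as.character(breg_sig), file.path(out, "breg_signature.txt"))
  writeLines(as.character(b10_sig), file.path(out, "b10_signature.txt"))
  organs <- stats::setNames(input$cells$organ, input$cells$barcode)
  logmsg(sprintf("input: %d cells x %d genes, %d contig records",
                 nrow(input$counts), ncol(input$counts),
                 if (is.null(input$contigs)) 0L else nrow(input$contigs)))

  ## ---- QC ----
  qc <- stage("qc", run_qc(input$counts, input$contigs, config$thresholds,
                           multichain_rule = config$multichain_rule))
  utils::write.csv(qc$report, file.path(out, "qc_report.csv"), row.names = FALSE)
  utils::write.table(qc$summary, file.path(out, "filter_summary.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg(sprintf("qc: kept %d/%d cells, %d/%d genes",
                 nrow(qc$counts), nrow(input$counts),
                 ncol(qc$counts), ncol(input$counts)))

  ## ---- normalize / scale / score ----
  norm <- stage("normalize", lognormalize(qc$counts))
  scaled <- stage("scale", zscore_scale(norm, clip_max = config$clip_max,
                                        sd_type = config$sd_type))
  breg_scores <- stage("score", suppressWarnings(
    compute_module_score(scaled, breg_sig)))
  calls <- call_breg(breg_scores, config$breg_threshold)
  breg_cells <- calls$barcode[calls$is_breg]
  if (length(breg_cells)) {
    b10_scores <- suppressWarnings(
      compute_module_score(scaled, b10_sig, cells = breg_cells))
    b10_thr <- config$b10_threshold
    if (identical(b10_thr, "auto")) {
      b10_thr <- calibrate_threshold(b10_scores)
      logmsg(sprintf("score: calibrated B10 threshold %.4f", b10_thr))
    }
    calls <- call_b10(calls, b10_scores, b10_thr)
  }
  logmsg(sprintf("score: %d/%d Breg (%.1f%%), %d B10 among Breg",
                 length(breg_cells), nrow(calls),
                 100 * mean(calls$is_breg),
                 sum(calls$is_b10, na.rm = TRUE)))

  ## ---- Breg subset clustering (plumbing) ----
  clusters <- NULL
  if (length(breg_cells) >= 20) {
    clusters <- stage("cluster", {
      gv <- apply(as.matrix(norm[breg_cells, , drop = FALSE]), 2, stats::var)
      ec <- embed_cluster(scaled[breg_cells, , drop = FALSE],
                          n_hvg = config$n_hvg,
                          n_pcs = min(config$n_pcs, length(breg_cells) - 1L),
                          resolution = config$resolution,
                          seed = config$seed, hvg_variances = gv)
      ec$cluster
    })
    logmsg(sprintf("cluster: %d Breg subsets", nlevels(clusters)))
  } else logmsg("cluster: skipped (fewer than 20 Breg cells)")

  ## ---- composition ----
  comp <- stage("composition",
                composition_table(calls, organs, clusters))
  utils::write.csv(comp$organ, file.path(out, "composition_organ.csv"),
                   row.names = FALSE)
  if (!is.null(comp$cluster_by_organ)) {
    utils::write.csv(comp$cluster_by_organ,
                     file.path(out, "composition_cluster_organ.csv"),
                     row.names = FALSE)
    utils::write.csv(comp$cluster_b10,
                     file.path(out, "composition_cluster_b10.csv"),
                     row.names = FALSE)
  }
  score_out <- calls
  score_out$organ <- organs[score_out$barcode]
  if (!is.null(clusters))
    score_out$cluster <- as.character(clusters[score_out$barcode])
  utils::write.csv(score_out, file.path(out, "scores.csv"), row.names = FALSE)

  ## ---- differential expression ----
  de <- stage("markers", {
    tables <- list()
    for (org in unique(stats::na.omit(organs[rownames(norm)]))) {
      tab <- tryCatch(
        rank_genes_breg(norm, calls, org, organs,
                        min_pct = config$min_pct),
        error = function(e) {
          logmsg(sprintf("markers: organ %s skipped (%s)", org,
                         conditionMessage(e)))
          NULL
        })
      if (!is.null(tab)) tables[[org]] <- tab
    }
    tables
  })
  for (org in names(de))
    utils::write.csv(de[[org]], file.path(out, paste0("deg_", org, ".csv")),
                     row.names = FALSE)
  markers <- NULL
  if (length(de)) {
    markers <- intersect_common_markers(de, config$fdr, config$min_log2fc)
    writeLines(markers$common, file.path(out, "common_markers.txt"))
    jsonlite::write_json(markers$venn, file.path(out, "venn_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    logmsg(sprintf("markers: %d common genes across %d organs",
                   length(markers$common), length(de)))
  }

  ## ---- repertoire ----
  repertoire <- NULL
  if (!is.null(input$contigs) && nrow(input$contigs)) {
    repertoire <- stage("repertoire", {
      cell_info <- data.frame(barcode = calls$barcode,
                              organ = unname(organs[calls$barcode]),
                              stringsAsFactors = FALSE)
      if (!is.null(clusters))
        cell_info$cluster <- as.character(clusters[cell_info$barcode])
      assign <- assign_clonotypes(input$contigs, cell_info,
                                  key_mode = config$key_mode)
      assign <- assign[assign$barcode %in% rownames(qc$counts), , drop = FALSE]
      sharing <- pairwise_sharing(assign, scope = breg_cells)
      indices <- if (!is.null(assign$cluster) &&
                     any(!is.na(assign$cluster)))
        clonal_index_table(assign) else NULL
      top <- top_clonotypes(assign)
      list(assign = assign, sharing = sharing, indices = indices, top = top)
    })
    utils::write.csv(as.data.frame(repertoire$sharing$clonotypes),
                     file.path(out, "sharing_clonotypes.csv"))
    utils::write.csv(as.data.frame(repertoire$sharing$cells),
                     file.path(out, "sharing_cells.csv"))
    utils::write.csv(repertoire$top, file.path(out, "top_clonotypes.csv"),
                     row.names = FALSE)
    if (!is.null(repertoire$indices)) {
      utils::write.csv(repertoire$indices$per_cluster,
                       file.path(out, "clonal_indices.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(repertoire$indices$transition),
                       file.path(out, "transition_matrix.csv"))
    }
    write_airr(input$contigs[input$contigs$barcode %in% repertoire$assign$barcode, ],
               repertoire$assign, file.path(out, "repertoire_airr.tsv"))
  }

  ## ---- recovery against planted truth ----
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- stage("recovery", {
      t_kept <- truth[match(calls$barcode, truth$barcode), ]
      planted_doublets <- truth$barcode[truth$is_multichain_doublet]
      flagged <- qc$removed_multichain
      rec <- data.frame(
        metric = c("breg_auroc", "breg_precision", "breg_recall",
                   "b10_fraction_called", "b10_fraction_planted",
                   "doublets_planted_in_qc_cells", "doublets_flagged",
                   "doublets_correctly_flagged"),
        value = c(
          auroc(calls$breg_score, t_kept$is_breg),
          sum(calls$is_breg & t_kept$is_breg) / max(1, sum(calls$is_breg)),
          sum(calls$is_breg & t_kept$is_breg) / max(1, sum(t_kept$is_breg)),
          mean(calls$is_b10[calls$is_breg], na.rm = TRUE),
          mean(t_kept$is_b10[t_kept$is_breg]),
          length(intersect(planted_doublets,
                           c(rownames(qc$counts), flagged))),
          length(flagged),
          length(intersect(flagged, planted_doublets))))
      rec
    })
    utils::write.csv(recovery, file.path(out, "recovery_report.csv"),
                     row.names = FALSE)
  }

  res <- list(config = config, qc = qc, norm = norm, scaled = scaled,
              calls = calls, clusters = clusters, composition = comp,
              de = de, markers = markers, repertoire = repertoire,
              recovery = recovery, truth = truth, out_dir = out)
  class(res) <- "breg_run"
  invisible(res)
}

#' @export
print.breg_run <- function(x, ...) {
  cat("breg_run:", nrow(x$calls), "QC-passing cells,",
      ncol(x$qc$counts), "genes;",
      sum(x$calls$is_breg), "Breg cells called\n")
  invisible(x)
}

#' @export
summary.breg_run <- function(object, ...) {
  x <- object
  cat("Breg identification run\n")
  cat(sprintf("  cells (post-QC): %d, genes: %d\n",
              nrow(x$calls), ncol(x$qc$counts)))
  cat(sprintf("  Breg: %d (%.1f%%), B10 among Breg: %.1f%%\n",
              sum(x$calls$is_breg), 100 * mean(x$calls$is_breg),
              100 * mean(x$calls$is_b10[x$calls$is_breg], na.rm = TRUE)))
  if (!is.null(x$markers))
    cat(sprintf("  common markers across %d organs: %d\n",
                length(x$de), length(x$markers$common)))
  if (!is.null(x$recovery)) {
    v <- stats::setNames(x$recovery$value, x$recovery$metric)
    cat(sprintf("  recovery: Breg AUROC %.3f, doublets flagged %d/%d\n",
                v["breg_auroc"], v["doublets_correctly_flagged"],
                v["doublets_flagged"]))
  }
  invisible(x)
}
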