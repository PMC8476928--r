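#' Configuration for the multi-organ synthetic dataset generator
#'
#' Bundles every parameter of the planted-truth simulator: organ layout,
#' negative-binomial expression model, signature effect sizes, and the
#' clonal structure of the paired BCR repertoire. All randomness downstream
#' of a `sim_config` is governed by its single `seed` field, so an identical
#' configuration reproduces identical data.
#'
#' @param seed Integer seed controlling all random draws.
#' @param organs Character vector of organ names. Defaults to the five
#'   murine organs profiled in multi-organ B-cell atlases: spleen, liver,
#'   mesenteric lymph node (mLN), peritoneal cavity (PC) and bone marrow
#'   (BM).
#' @param cells_per_organ Cells simulated per organ.
#' @param n_genes Total number of genes, including mitochondrial and
#'   signature genes.
#' @param n_mito_genes Number of mitochondrial genes; these receive mouse
#'   "mt-" prefixed symbols so QC can find them by prefix.
#' @param breg_fraction Fraction of cells planted as Breg per organ; a
#'   scalar (recycled) or a vector named by organ. The default is
#'   PC-enriched, mirroring the higher regulatory B-cell proportion seen in
#'   the peritoneal cavity.
#' @param b10_fraction_of_breg Fraction of planted Breg cells additionally
#'   planted as B10.
#' @param n_signature_genes,n_b10_signature_genes Sizes of the (disjoint)
#'   Breg and B10 gene signatures carried by the simulated transcriptome.
#' @param signature_effect Multiplicative fold (>= 1) applied to
#'   Breg-signature gene means in planted Breg cells.
#' @param b10_effect Fold (>= 1) applied to B10-signature gene means in
#'   planted B10 cells.
#' @param library_size_mean,library_size_shape Mean and shape of the gamma
#'   law generating per-cell library-size factors.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param doublet_multichain_rate Fraction of cells emitted as multichain
#'   doublets carrying two heavy and two light chains of distinct
#'   clonotypes.
#' @param n_clonotypes Optional clonotype pool size; `NULL` (default)
#'   derives it so every cell not in an expanded or shared clone is a
#'   singleton clonotype.
#' @param expanded_clone_count,expanded_clone_size Number and cell count of
#'   planted expanded clones.
#' @param expanded_clone_organ Organ hosting the expanded clones (the
#'   peritoneal cavity by default, where clonal expansion concentrates).
#' @param shared_clone_pairs Data frame with columns `organ_a`, `organ_b`,
#'   `n`: how many clonotypes to plant spanning each organ pair. Each
#'   shared clone receives two cells in each organ of its pair.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, cells_per_organ = 50, n_genes = 300)
#' cfg$organs
#' @export
sim_config <- function(seed = 1L,
                       organs = c("spleen", "liver", "mLN", "PC", "BM"),
                       cells_per_organ = 1000L,
                       n_genes = 1500L,
                       n_mito_genes = 13L,
                       breg_fraction = c(spleen = 0.12, liver = 0.12,
                                         mLN = 0.10, PC = 0.30, BM = 0.08),
                       b10_fraction_of_breg = 0.6,
                       n_signature_genes = 134L,
                       n_b10_signature_genes = 30L,
                       signature_effect = 2.0,
                       b10_effect = 2.0,
                       library_size_mean = 1000,
                       library_size_shape = 10,
                       nb_dispersion = 0.1,
                       doublet_multichain_rate = 0.03,
                       n_clonotypes = NULL,
                       expanded_clone_count = 2L,
                       expanded_clone_size = 10L,
                       expanded_clone_organ = "PC",
                       shared_clone_pairs = data.frame(
                         organ_a = c("liver", "spleen"),
                         organ_b = c("PC", "PC"),
                         n = c(3L, 3L))) {
  organs <- as.character(organs)
  if (anyDuplicated(organs)) stop("duplicate organ names")
  n_org <- length(organs)
  if (length(breg_fraction) == 1L) {
    breg_fraction <- stats::setNames(rep(breg_fraction, n_org), organs)
  } else {
    if (is.null(names(breg_fraction)) || !all(organs %in% names(breg_fraction)))
      stop("breg_fraction must be scalar or named by organ")
    breg_fraction <- breg_fraction[organs]
  }
  fracs <- c(breg_fraction, b10_fraction_of_breg, doublet_multichain_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cells_per_organ < 1L || n_genes < 1L) stop("cells_per_organ and n_genes must be positive")
  if (n_mito_genes < 0L) stop("n_mito_genes must be non-negative")
  if (signature_effect < 1 || b10_effect < 1)
    stop("signature_effect and b10_effect are folds >= 1")
  if (library_size_mean <= 0 || library_size_shape <= 0 || nb_dispersion <= 0)
    stop("library size and dispersion parameters must be positive")
  if (n_genes < n_signature_genes + n_b10_signature_genes + n_mito_genes)
    stop(sprintf(
      "n_genes (%d) smaller than signature + B10 + mito genes (%d): short by %d",
      n_genes, n_signature_genes + n_b10_signature_genes + n_mito_genes,
      n_signature_genes + n_b10_signature_genes + n_mito_genes - n_genes))
  if (!expanded_clone_organ %in% organs) stop("expanded_clone_organ not in organs")
  shared_clone_pairs <- as.data.frame(shared_clone_pairs)
  if (nrow(shared_clone_pairs) &&
      !all(c(shared_clone_pairs$organ_a, shared_clone_pairs$organ_b) %in% organs))
    stop("shared_clone_pairs names an unknown organ")
  cfg <- list(
    seed = as.integer(seed), organs = organs,
    cells_per_organ = as.integer(cells_per_organ),
    n_genes = as.integer(n_genes), n_mito_genes = as.integer(n_mito_genes),
    breg_fraction = breg_fraction,
    b10_fraction_of_breg = b10_fraction_of_breg,
    n_signature_genes = as.integer(n_signature_genes),
    n_b10_signature_genes = as.integer(n_b10_signature_genes),
    signature_effect = signature_effect, b10_effect = b10_effect,
    library_size_mean = library_size_mean,
    library_size_shape = library_size_shape,
    nb_dispersion = nb_dispersion,
    doublet_multichain_rate = doublet_multichain_rate,
    n_clonotypes = if (is.null(n_clonotypes)) NULL else as.integer(n_clonotypes),
    expanded_clone_count = as.integer(expanded_clone_count),
    expanded_clone_size = as.integer(expanded_clone_size),
    expanded_clone_organ = expanded_clone_organ,
    shared_clone_pairs = shared_clone_pairs)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$organs), "organs x", x$cells_per_organ,
      "cells,", x$n_genes, "genes, seed", x$seed, "\n")
  cat("  Breg fractions:",
      paste(sprintf("%s=%.2f", names(x$breg_fraction), x$breg_fraction),
            collapse = " "), "\n")
  cat("  effects: signature x", x$signature_effect, ", B10 x", x$b10_effect,
      "; doublet rate", x$doublet_multichain_rate, "\n")
  invisible(x)
}

#' Read a simulator configuration from a YAML file
#'
#' Scalar fields map directly onto [sim_config()] arguments;
#' `shared_clone_pairs` is given as a list of `[organ_a, organ_b, n]`
#' triples.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$shared_clone_pairs)) {
    sp <- do.call(rbind, lapply(y$shared_clone_pairs, function(p)
      data.frame(organ_a = as.character(p[[1]]), organ_b = as.character(p[[2]]),
                 n = as.integer(p[[3]]))))
    y$shared_clone_pairs <- sp
  }
  if (!is.null(y$breg_fraction) && length(y$breg_fraction) > 1L)
    y$breg_fraction <- unlist(y$breg_fraction)
  do.call(sim_config, y)
}
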