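#' Filter for robustly expressed genes
#'
#' Keeps exactly the genes with TPM >= `min_tpm` in at least `min_libraries`
#' samples (boundary inclusive), preserving gene order. This is the standard
#' expression filter applied before all downstream analyses.
#'
#' @param tpm genes x samples TPM matrix.
#' @param min_tpm TPM threshold (default 1).
#' @param min_libraries minimum number of samples at or above the threshold
#'   (default 3).
#' @return the filtered matrix (possibly with zero rows).
#' @export
filter_expressed <- function(tpm, min_tpm = 1, min_libraries = 3) {
  abort_if(min_libraries > ncol(tpm),
           "min_libraries (", min_libraries, ") exceeds sample count (", ncol(tpm), ")")
  abort_if(min_libraries < 1, "min_libraries must be at least 1")
  keep <- rowSums(tpm >= min_tpm) >= min_libraries
  out <- tpm[keep, , drop = FALSE]
  attr(out, "design") <- attr(tpm, "design")
  out
}

#' Elementwise log2(x + 1)
#'
#' @param x non-negative numeric matrix or vector (TPM scale).
#' @return same shape, log2(x + 1).
#' @export
log2p1 <- function(x) {
  abort_if(any(x < 0, na.rm = TRUE), "log2p1 requires non-negative input")
  out <- log2(x + 1)
  attr(out, "design") <- attr(x, "design")
  out
}

#' Mean expression per cultivar-stage cell
#'
#' Averages replicates within each (cultivar, stage) cell, on either the TPM
#' or the log2(TPM+1) scale. The per-cell design is attached as attribute
#' `cells` (a data.frame with cultivar, stage, cr_group).
#'
#' @param x genes x samples matrix (TPM scale).
#' @param design validated sample design (defaults to the matrix's `design`
#'   attribute).
#' @param scale `"log2"` (log2(TPM+1) is applied before averaging) or
#'   `"tpm"`.
#' @return genes x cells matrix, columns ordered cultivar-major then stage.
#' @export
replicate_means <- function(x, design = attr(x, "design"),
                            scale = c("log2", "tpm")) {
  scale <- match.arg(scale)
  design <- validate_design(design)
  abort_if(ncol(x) != nrow(design), "matrix columns do not match design rows")
  if (scale == "log2") x <- log2p1(x)
  cultivars <- unique(design$cultivar)
  stages <- levels(design$stage)
  cells <- expand.grid(stage = stages, cultivar = cultivars,
                       stringsAsFactors = FALSE)[, c("cultivar", "stage")]
  out <- matrix(NA_real_, nrow = nrow(x), ncol = nrow(cells),
                dimnames = list(rownames(x),
                                paste(cells$cultivar, cells$stage, sep = ".")))
  for (i in seq_len(nrow(cells))) {
    idx <- which(design$cultivar == cells$cultivar[i] &
                   as.character(design$stage) == cells$stage[i])
    abort_if(length(idx) == 0, "empty cultivar-stage cell: ",
             cells$cultivar[i], "/", cells$stage[i])
    out[, i] <- rowMeans(x[, idx, drop = FALSE])
  }
  cr_map <- attr(design, "cr_map")
  cells$cr_group <- unname(cr_map[cells$cultivar])
  attr(out, "cells") <- cells
  attr(out, "stages") <- stages
  out
}

#' Sample-to-sample Pearson correlation structure
#'
#' @param logm genes x samples matrix on the log2(TPM+1) scale (>= 2 genes).
#' @param design validated design, used to compute the mean within
#'   (cultivar, stage) replicate-group correlation.
#' @return list with `matrix` (symmetric, unit diagonal), `group_means`
#'   (per-cell mean off-diagonal correlation) and `range` (min/max of the
#'   group means).
#' @export
sample_correlations <- function(logm, design = attr(logm, "design")) {
  abort_if(nrow(logm) < 2, "need at least two genes")
  sds <- apply(logm, 2, stats::sd)
  zero <- colnames(logm)[sds == 0]
  abort_if(length(zero) > 0, "zero-variance sample(s): ",
           paste(zero, collapse = ", "))
  cm <- stats::cor(logm)
  group_means <- NULL
  if (!is.null(design)) {
    design <- validate_design(design)
    key <- paste(design$cultivar, design$stage, sep = ".")
    group_means <- vapply(split(seq_len(nrow(design)), key), function(idx) {
      if (length(idx) < 2) return(NA_real_)
      sub <- cm[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
  }
  list(matrix = cm,
       group_means = group_means,
       range = if (!is.null(group_means)) range(group_means, na.rm = TRUE))
}

#' PCA summary over the most variable genes
#'
#' Ranks genes by variance of log2(TPM+1), retains the top `n_top_genes`,
#' centers each gene (no scaling, so dominance structure is preserved) and
#' computes sample-space principal components.
#'
#' @param logm genes x samples matrix, log2(TPM+1) scale.
#' @param n_top_genes number of most-variable genes used (default 2000).
#' @param design optional validated design attached to the scores.
#' @return list with `variance_fractions` (non-increasing, summing to <= 1),
#'   `scores` (samples x PCs), `n_genes_used`.
#' @export
pca_variance <- function(logm, n_top_genes = 2000, design = attr(logm, "design")) {
  abort_if(nrow(logm) < 2, "need at least two genes")
  abort_if(ncol(logm) < 3, "need at least three samples")
  abort_if(n_top_genes < 2, "n_top_genes must be at least 2")
  vars <- apply(logm, 1, stats::var)
  top <- order(vars, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(logm)))]
  x <- t(logm[top, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  list(variance_fractions = fr,
       scores = pc$x,
       n_genes_used = length(top),
       design = design)
}

#' Assemble a QC report
#'
#' @param tpm full TPM matrix (before filtering).
#' @param design validated design.
#' @param min_tpm,min_libraries expression-filter parameters.
#' @param n_top_genes PCA gene count.
#' @return list with counts, within-group correlation range and PC variance
#'   fractions.
#' @export
qc_report <- function(tpm, design = attr(tpm, "design"),
                      min_tpm = 1, min_libraries = 3, n_top_genes = 2000) {
  expressed <- filter_expressed(tpm, min_tpm, min_libraries)
  logm <- log2p1(expressed)
  cors <- sample_correlations(logm, design)
  pca <- pca_variance(logm, n_top_genes, design)
  list(n_genes_total = nrow(tpm),
       n_genes_expressed = nrow(expressed),
       within_group_correlation_range = cors$range,
       pc_variance_fractions = pca$variance_fractions,
       correlations = cors, pca = pca)
}
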