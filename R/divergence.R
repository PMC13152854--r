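#' Stagewise High-CR minus Low-CR group differences
#'
#' For every gene and stage, the High-CR group mean (over the high-CR
#' cultivars' replicate means, log2(TPM+1) scale) minus the Low-CR group mean,
#' treating cultivars as the independent units.
#'
#' @param log_rep_means genes x (cultivar, stage) matrix from
#'   [replicate_means()] on the log2 scale.
#' @return list with matrices `high`, `low` and `d` (genes x stages).
#' @export
stage_group_difference <- function(log_rep_means) {
  cells <- attr(log_rep_means, "cells")
  abort_if(is.null(cells), "input must carry a 'cells' attribute (use replicate_means)")
  stages <- attr(log_rep_means, "stages")
  for (grp in c("High", "Low")) {
    abort_if(!any(cells$cr_group == grp), "no cultivars in CR group '", grp, "'")
  }
  grp_mean <- function(grp) {
    m <- matrix(NA_real_, nrow(log_rep_means), length(stages),
                dimnames = list(rownames(log_rep_means), stages))
    for (s in stages) {
      idx <- which(cells$cr_group == grp & cells$stage == s)
      m[, s] <- rowMeans(log_rep_means[, idx, drop = FALSE])
    }
    m
  }
  high <- grp_mean("High")
  low <- grp_mean("Low")
  list(high = high, low = low, d = high - low, stages = stages)
}

#' Per-cluster, per-stage divergence
#'
#' D(c, s) = mean over the genes of cluster c of |d_s|, the absolute High-Low
#' difference at stage s. The peak stage is the argmax over stages, ties
#' broken toward the earliest stage.
#'
#' @param d genes x stages matrix of signed differences (the `d` element of
#'   [stage_group_difference()]).
#' @param assignment a `chill_clusters` object.
#' @return data.frame with one row per cluster: D at each stage and
#'   `peak_stage`.
#' @export
module_stage_divergence <- function(d, assignment) {
  stages <- colnames(d)
  rows <- lapply(names(assignment$sizes), function(cl) {
    genes <- names(assignment$cluster)[assignment$cluster == cl]
    abort_if(length(genes) == 0, "empty cluster: ", cl)
    D <- colMeans(abs(d[genes, , drop = FALSE]))
    peak <- stages[which.max(D)]   # which.max takes the first (earliest) tie
    cbind(data.frame(cluster = cl, n_genes = length(genes),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(D)), data.frame(peak_stage = peak))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("cluster", "n_genes", stages, "peak_stage")
  out
}

#' Directional discordance of the High-Low difference across stages
#'
#' A gene is discordant when the signs of its stagewise differences (ignoring
#' those with |d_s| < eps) are not all equal. Genes with every |d_s| below eps
#' are non-discordant.
#'
#' @param d genes x stages signed difference matrix.
#' @param eps minimum |d| (log2 units) for a sign call (default 0.05).
#' @return named logical vector.
#' @export
discordance_flag <- function(d, eps = 0.05) {
  s <- sign(d) * (abs(d) >= eps)
  has_pos <- rowSums(s > 0) > 0
  has_neg <- rowSums(s < 0) > 0
  stats::setNames(has_pos & has_neg, rownames(d))
}

#' Cross-cultivar concordance of the temporal trend
#'
#' For each cultivar, the trend sign is the sign of the last-stage minus
#' first-stage expression (0 when |delta| < eps); in `"majority"` mode it is
#' the sign of the majority of consecutive stage-step signs. The concordance
#' count is the size of the largest set of cultivars sharing the same nonzero
#' sign; the filter passes when the count reaches `k_of_n`.
#'
#' @param log_rep_means genes x (cultivar, stage) matrix, log2 scale.
#' @param eps minimum |delta| for a sign call (default 0.05).
#' @param k_of_n required number of agreeing cultivars (default 3).
#' @param mode `"endpoint"` (S1 -> S_last trend, default) or `"majority"`.
#' @return list with `trend` (genes x cultivars sign matrix), `count`
#'   (named integer) and `pass` (named logical).
#' @export
cultivar_concordance <- function(log_rep_means, eps = 0.05, k_of_n = 3,
                                 mode = c("endpoint", "majority")) {
  mode <- match.arg(mode)
  cells <- attr(log_rep_means, "cells")
  stages <- attr(log_rep_means, "stages")
  abort_if(length(stages) < 2, "need at least two stages")
  cultivars <- unique(cells$cultivar)
  abort_if(k_of_n > length(cultivars),
           "k_of_n (", k_of_n, ") exceeds the number of cultivars")
  trend <- matrix(0L, nrow(log_rep_means), length(cultivars),
                  dimnames = list(rownames(log_rep_means), cultivars))
  for (cv in cultivars) {
    idx <- which(cells$cultivar == cv)
    idx <- idx[match(stages, cells$stage[idx])]
    block <- log_rep_means[, idx, drop = FALSE]
    if (mode == "endpoint") {
      delta <- block[, length(stages)] - block[, 1]
      trend[, cv] <- as.integer(sign(delta) * (abs(delta) >= eps))
    } else {
      steps <- block[, -1, drop = FALSE] - block[, -length(stages), drop = FALSE]
      s <- sign(steps) * (abs(steps) >= eps)
      trend[, cv] <- as.integer(sign(rowSums(s)))
    }
  }
  pos <- rowSums(trend > 0)
  neg <- rowSums(trend < 0)
  count <- pmax(pos, neg)
  list(trend = trend,
       count = stats::setNames(as.integer(count), rownames(log_rep_means)),
       pass = stats::setNames(count >= k_of_n, rownames(log_rep_means)))
}

#' Basal transcript abundance gate
#'
#' Pass if and only if the gene's mean TPM over all samples is at least
#' `min_mean` and its maximum TPM is at least `min_max` (boundaries
#' inclusive).
#'
#' @param tpm genes x samples TPM matrix.
#' @param min_mean mean-TPM threshold (default 0.5).
#' @param min_max max-TPM threshold (default 1).
#' @return named logical vector.
#' @export
abundance_gate <- function(tpm, min_mean = 0.5, min_max = 1) {
  pass <- rowMeans(tpm) >= min_mean & apply(tpm, 1, max) >= min_max
  stats::setNames(pass, rownames(tpm))
}

#' Nominate candidate genes
#'
#' A gene is a candidate when it (i) belongs to a CR-divergent cluster,
#' (ii) is directionally discordant, (iii) passes the cross-cultivar
#' concordance filter, (iv) passes the abundance gate and (v) carries a
#' regulatorily plausible functional class.
#'
#' @param assignment a `chill_clusters` object.
#' @param divergent_clusters flagged cluster ids
#'   (from [flag_cr_divergent_clusters()]).
#' @param discordant,concordance_pass,abundance_pass named logical vectors.
#' @param classes named character vector of functional classes.
#' @param plausible_classes classes accepted as regulatorily plausible.
#' @return data.frame (gene, cluster, flags, candidate); per-cluster candidate
#'   counts attached as attribute `cluster_counts`.
#' @export
select_candidates <- function(assignment, divergent_clusters, discordant,
                              concordance_pass, abundance_pass, classes,
                              plausible_classes = PLAUSIBLE_CLASSES) {
  abort_if(length(plausible_classes) == 0, "plausibility class set is empty")
  genes <- names(assignment$cluster)
  out <- data.frame(
    gene = genes,
    cluster = unname(assignment$cluster),
    in_divergent_cluster = unname(assignment$cluster %in% divergent_clusters),
    discordant = unname(discordant[genes]),
    concordant = unname(concordance_pass[genes]),
    abundant = unname(abundance_pass[genes]),
    class = unname(classes[genes]),
    stringsAsFactors = FALSE)
  out$plausible <- out$class %in% plausible_classes
  out$candidate <- out$in_divergent_cluster & out$discordant &
    out$concordant & out$abundant & out$plausible
  counts <- table(factor(out$cluster[out$candidate],
                         levels = names(assignment$sizes)))
  attr(out, "cluster_counts") <- counts
  out
}
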