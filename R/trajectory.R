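#' Intra-cultivar z-score standardization of stage trajectories
#'
#' For each gene and each cultivar, the cultivar's stage profile is
#' standardized to mean 0 / sd 1 (denominator n-1) across stages. This removes
#' cultivar baseline and amplitude differences so that clustering reflects the
#' direction and timing of change. Genes with zero variance in any cultivar
#' are flagged invalid and excluded from clustering (zero-filling would create
#' an artifactual flat cluster).
#'
#' @param rep_means genes x (cultivar, stage) matrix from [replicate_means()].
#' @return matrix of z-scores with attributes `cells` (per-column design),
#'   `valid` (logical per gene) and `stages`.
#' @export
zscore_trajectories <- function(rep_means) {
  cells <- attr(rep_means, "cells")
  abort_if(is.null(cells), "rep_means must carry a 'cells' attribute (use replicate_means)")
  stages <- attr(rep_means, "stages")
  abort_if(length(stages) < 2, "need at least two stages")
  out <- rep_means
  valid <- rep(TRUE, nrow(rep_means))
  for (cv in unique(cells$cultivar)) {
    idx <- which(cells$cultivar == cv)
    block <- rep_means[, idx, drop = FALSE]
    mu <- rowMeans(block)
    sds <- row_sds(block)
    ok <- sds > 1e-12
    valid <- valid & ok
    z <- (block - mu) / sds
    z[!ok, ] <- NA_real_
    out[, idx] <- z
  }
  attr(out, "cells") <- cells
  attr(out, "stages") <- stages
  attr(out, "valid") <- stats::setNames(valid, rownames(rep_means))
  out
}

# Deterministic k-means++ seeding (indices of chosen rows).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
  for (j in seq_len(k)[-1]) {
    tot <- sum(d2)
    centers[j] <- if (tot <= 0) {
      sample(setdiff(seq_len(n), centers[seq_len(j - 1)]), 1)
    } else {
      sample.int(n, 1, prob = d2 / tot)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j], ], "-")^2))
  }
  centers
}

#' Partition standardized trajectories into k modules
#'
#' Runs Lloyd's k-means with k-means++ initialization, keeping the best of
#' `n_restarts` runs by total within-cluster sum of squares. Results are
#' deterministic given `seed`. Clusters are relabelled C1..Ck in decreasing
#' size (ties by first occurrence).
#'
#' @param traj matrix from [zscore_trajectories()].
#' @param k number of modules (default 8).
#' @param seed RNG seed for initialization.
#' @param n_restarts number of k-means++ restarts (default 25).
#' @param mode `"concatenate"` clusters the concatenated per-cultivar z-blocks
#'   (cross-cultivar shape agreement); `"pooled"` averages the blocks across
#'   cultivars first.
#' @return list of class `chill_clusters`: `cluster` (named character vector,
#'   valid genes only), `k`, `seed`, `centers`, `sizes`, `tot_withinss`,
#'   `mode`, plus the `cells`/`stages` bookkeeping of the feature matrix used.
#' @export
cluster_kmeans <- function(traj, k = 8, seed = 1, n_restarts = 25,
                           mode = c("concatenate", "pooled")) {
  mode <- match.arg(mode)
  abort_if(k < 2, "k must be at least 2")
  valid <- attr(traj, "valid")
  cells <- attr(traj, "cells")
  x <- traj[valid, , drop = FALSE]
  if (mode == "pooled") {
    stages <- attr(traj, "stages")
    pooled <- matrix(0, nrow(x), length(stages),
                     dimnames = list(rownames(x), stages))
    for (s in stages) {
      pooled[, s] <- rowMeans(x[, which(cells$stage == s), drop = FALSE])
    }
    x <- pooled
  }
  abort_if(nrow(x) < k, "fewer valid genes (", nrow(x), ") than k (", k, ")")

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        stats::kmeans(x, centers = x[init, , drop = FALSE],
                      iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          tryCatch(suppressWarnings(
            stats::kmeans(x, centers = x[init, , drop = FALSE],
                          iter.max = 200, algorithm = "Lloyd")),
            error = function(e) NULL)
        })
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  abort_if(is.null(best), "k-means failed for every restart (k too large?)")

  ord <- order(-tabulate(best$cluster, nbins = k), seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- paste0("C", relabel[best$cluster])
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- paste0("C", seq_len(k))
  structure(list(
    cluster = stats::setNames(labels, rownames(x)),
    k = k, seed = seed, mode = mode,
    centers = centers,
    sizes = stats::setNames(as.integer(table(factor(labels, paste0("C", seq_len(k))))),
                            paste0("C", seq_len(k))),
    tot_withinss = best$tot.withinss,
    cells = cells, stages = attr(traj, "stages")),
    class = "chill_clusters")
}

#' Cluster-average Low/High stage profiles
#'
#' For each cluster and stage, the mean standardized expression over the
#' cluster's genes and the cultivars of each CR group.
#'
#' @param assignment a `chill_clusters` object.
#' @param traj the z-score matrix the clustering was computed from.
#' @return data.frame (cluster, cr_group, stage, mean_z).
#' @export
cluster_group_profiles <- function(assignment, traj) {
  cells <- attr(traj, "cells")
  out <- list()
  for (cl in names(assignment$sizes)) {
    genes <- names(assignment$cluster)[assignment$cluster == cl]
    abort_if(length(genes) == 0, "empty cluster: ", cl)
    z <- traj[genes, , drop = FALSE]
    for (grp in unique(cells$cr_group)) {
      for (s in attr(traj, "stages")) {
        idx <- which(cells$cr_group == grp & cells$stage == s)
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, cr_group = grp, stage = s,
          mean_z = mean(z[, idx]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Flag clusters enriched in directionally discordant genes
#'
#' A cluster is CR-divergent when the fraction of its genes flagged as
#' directionally discordant (see [discordance_flag()]) reaches
#' `tau_discordant`.
#'
#' @param assignment a `chill_clusters` object.
#' @param discordant named logical vector (per gene).
#' @param tau_discordant flagging threshold on the discordant fraction
#'   (default 0.5).
#' @return character vector of flagged cluster ids; the per-cluster fractions
#'   are attached as attribute `fractions`.
#' @export
flag_cr_divergent_clusters <- function(assignment, discordant,
                                       tau_discordant = 0.5) {
  abort_if(length(assignment$cluster) == 0, "empty cluster assignment")
  genes <- names(assignment$cluster)
  fr <- vapply(names(assignment$sizes), function(cl) {
    g <- genes[assignment$cluster == cl]
    if (length(g) == 0) return(NA_real_)
    mean(discordant[g])
  }, numeric(1))
  flagged <- names(fr)[!is.na(fr) & fr >= tau_discordant]
  attr(flagged, "fractions") <- fr
  flagged
}
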