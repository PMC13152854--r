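#' Per-gene evidence components
#'
#' Normalizes the evidence layers to [0, 1] for every eligible gene:
#' * `div_score` — max over stages of |High-Low difference|, rescaled by the
#'   99th percentile across eligible genes and capped at 1;
#' * `hub_score` — degree / max degree in the candidate network (0 when the
#'   gene is absent from the network: such genes remain rankable);
#' * `bridge_score` — normalized betweenness centrality;
#' * `support_score` — concordance count / number of cultivars;
#' * `abundance` — abundance-gate indicator;
#' plus bookkeeping columns: trajectory cluster, stage of maximum divergence
#' and functional class.
#'
#' @param genes eligible gene ids (e.g. expressed genes in CR-divergent
#'   clusters).
#' @param d genes x stages signed difference matrix
#'   ([stage_group_difference()]).
#' @param centrality data.frame from [node_centrality()].
#' @param concordance_count named integer vector ([cultivar_concordance()]).
#' @param n_cultivars number of cultivars.
#' @param abundance_pass named logical vector ([abundance_gate()]).
#' @param classes named character vector of functional classes.
#' @param assignment optional `chill_clusters` object for cluster labels.
#' @return data.frame, one row per eligible gene.
#' @export
evidence_components <- function(genes, d, centrality, concordance_count,
                                n_cultivars, abundance_pass, classes,
                                assignment = NULL) {
  missing <- setdiff(genes, rownames(d))
  abort_if(length(missing) > 0, "gene(s) not eligible (no divergence data): ",
           paste(utils::head(missing, 5), collapse = ", "))
  dd <- abs(d[genes, , drop = FALSE])
  div_raw <- apply(dd, 1, max)
  peak <- colnames(d)[apply(dd, 1, which.max)]
  cap <- stats::quantile(div_raw, 0.99, names = FALSE)
  div_score <- if (cap > 0) pmin(div_raw / cap, 1) else rep(0, length(genes))
  deg <- stats::setNames(centrality$degree, centrality$gene)[genes]
  deg[is.na(deg)] <- 0L
  max_deg <- max(deg, 0)
  hub <- if (max_deg > 0) deg / max_deg else rep(0, length(genes))
  btw <- stats::setNames(centrality$betweenness, centrality$gene)[genes]
  btw[is.na(btw)] <- 0
  support <- concordance_count[genes] / n_cultivars
  data.frame(
    gene = genes,
    cluster = if (!is.null(assignment)) unname(assignment$cluster[genes]) else NA_character_,
    peak_stage = peak,
    div_score = unname(div_score),
    hub_score = unname(hub),
    bridge_score = unname(btw),
    support_score = unname(support),
    abundance = as.numeric(abundance_pass[genes]),
    class = unname(classes[genes]),
    stringsAsFactors = FALSE)
}

#' Default evidence weights
#' @export
default_weights <- function() {
  c(div = 0.4, hub = 0.2, bridge = 0.1, support = 0.2, abundance = 0.1)
}

#' Integrated evidence score
#'
#' Weighted sum of the five normalized evidence components. Weights must be
#' non-negative and sum to 1 so the score stays in [0, 1]. The functional
#' class does not enter the score (it gates candidacy upstream and labels the
#' output), avoiding double counting.
#'
#' @param components data.frame from [evidence_components()].
#' @param weights named numeric vector (div, hub, bridge, support, abundance).
#' @return the components with a `score` column appended.
#' @export
priority_score <- function(components, weights = default_weights()) {
  need <- c("div", "hub", "bridge", "support", "abundance")
  abort_if(!all(need %in% names(weights)),
           "weights must be named: ", paste(need, collapse = ", "))
  weights <- weights[need]
  abort_if(any(weights < 0), "weights must be non-negative")
  abort_if(abs(sum(weights) - 1) > 1e-9, "weights must sum to 1")
  m <- as.matrix(components[, c("div_score", "hub_score", "bridge_score",
                                "support_score", "abundance")])
  components$score <- as.numeric(m %*% weights)
  attr(components, "weights") <- weights
  components
}

#' Rank scored candidates
#'
#' Descending by score, ties broken by gene id (lexicographic), so ranks are
#' unique and deterministic.
#'
#' @param scored data.frame from [priority_score()].
#' @param top_n size of the focused top panel (default 30).
#' @return list with `table` (full ranked table with a `rank` column) and
#'   `top` (the top panel).
#' @export
rank_candidates <- function(scored, top_n = 30) {
  abort_if(top_n < 1, "top_n must be at least 1")
  ord <- order(-scored$score, scored$gene)
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(table = out, top = utils::head(out, top_n))
}

#' Stage-resolved Low/High expression profiles with s.e.m.
#'
#' For each gene, CR group and stage: the mean and standard error of the mean
#' of log2(TPM+1) over the group's libraries (6 in the reference design:
#' 2 cultivars x 3 replicates). Groups with fewer than 2 libraries get a
#' missing s.e.m.
#'
#' @param genes gene ids to report (typically the top panel).
#' @param logm genes x samples matrix, log2 scale.
#' @param design validated design.
#' @return data.frame (gene, cr_group, stage, mean, sem, n).
#' @export
stage_profiles_report <- function(genes, logm, design = attr(logm, "design")) {
  design <- validate_design(design)
  out <- list()
  for (g in genes) {
    for (grp in unique(design$cr_group)) {
      for (s in levels(design$stage)) {
        idx <- which(design$cr_group == grp & as.character(design$stage) == s)
        v <- logm[g, idx]
        sem <- if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          gene = g, cr_group = grp, stage = s,
          mean = mean(v), sem = sem, n = length(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
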