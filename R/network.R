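#' Residualize expression by stage
#'
#' Subtracts, per gene, the mean over all samples of the same stage. This
#' uncouples genotype-driven co-variation from the dominant developmental
#' stage effect before correlation-network inference; residual stage means are
#' exactly zero.
#'
#' @param logm genes x samples matrix (log2(TPM+1) scale).
#' @param design validated design (or a character/factor vector of per-sample
#'   stages).
#' @return residual matrix of the same shape.
#' @export
residualize_by_stage <- function(logm, design = attr(logm, "design")) {
  stage <- if (is.data.frame(design)) as.character(validate_design(design)$stage)
           else as.character(design)
  abort_if(length(stage) != ncol(logm), "stage vector does not match sample count")
  out <- logm
  for (s in unique(stage)) {
    idx <- which(stage == s)
    abort_if(length(idx) == 0, "stage with zero samples: ", s)
    out[, idx] <- logm[, idx, drop = FALSE] - rowMeans(logm[, idx, drop = FALSE])
  }
  attr(out, "design") <- if (is.data.frame(design)) design
  out
}

#' Thresholded Pearson co-expression network
#'
#' Computes all pairwise Pearson correlations (denominator n-1) and keeps
#' edges with |r| >= `min_abs_r`. Zero-variance genes are dropped with a
#' warning.
#'
#' @param mat genes x samples matrix (typically stage-residualized).
#' @param min_abs_r absolute-correlation edge threshold (default 0.8).
#' @return list of class `gene_network`: `edges` (gene1, gene2, r, sign),
#'   `degree` (named, includes isolated nodes), `nodes`.
#' @export
correlation_network <- function(mat, min_abs_r = 0.8) {
  abort_if(ncol(mat) < 3, "need at least three samples")
  sds <- apply(mat, 1, stats::sd)
  drop <- rownames(mat)[sds == 0]
  if (length(drop) > 0) {
    warning("dropping ", length(drop), " zero-variance gene(s)", call. = FALSE)
    mat <- mat[sds > 0, , drop = FALSE]
  }
  nodes <- rownames(mat)
  R <- stats::cor(t(mat))
  ut <- which(upper.tri(R) & abs(R) >= min_abs_r, arr.ind = TRUE)
  edges <- data.frame(gene1 = nodes[ut[, 1]], gene2 = nodes[ut[, 2]],
                      r = R[ut], sign = ifelse(R[ut] >= 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0) {
    tab <- table(c(edges$gene1, edges$gene2))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(edges = edges, degree = deg, nodes = nodes,
                 min_abs_r = min_abs_r),
            class = "gene_network")
}

#' Unsigned WGCNA-style adjacency from a correlation matrix
#'
#' @param R correlation matrix.
#' @param beta soft-threshold exponent (default 6, the unsigned WGCNA
#'   default).
#' @return adjacency |r|^beta with zero diagonal.
#' @export
adjacency_from_cor <- function(R, beta = 6) {
  abort_if(beta <= 0, "beta must be positive")
  a <- abs(R)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' TOM_ii = 1, where k is the adjacency row sum. Shared-neighbourhood
#' similarity used for module detection.
#'
#' @param adjacency symmetric matrix in [0, 1] with zero diagonal.
#' @return TOM matrix in [0, 1].
#' @export
tom_similarity <- function(adjacency) {
  abort_if(!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency),
           "adjacency must be a square matrix")
  abort_if(any(adjacency < 0) || any(adjacency > 1),
           "adjacency values must lie in [0, 1]")
  abort_if(any(diag(adjacency) != 0), "adjacency diagonal must be zero")
  abort_if(any(abs(adjacency - t(adjacency)) > 1e-12), "adjacency must be symmetric")
  L <- adjacency %*% adjacency
  k <- rowSums(adjacency)
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (L + adjacency) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# Size-ranked module colour order (WGCNA convention), then numbered fallbacks.
wgcna_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq_len(n - length(base)) + length(base)))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM with a
#' static tree cut at `cut_height`; clusters below `min_module_size` are
#' assigned to "grey". Modules are named in decreasing size by the standard
#' WGCNA colour order (turquoise, blue, ...).
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param min_module_size minimum module size (default 20).
#' @param cut_height static cut height on 1 - TOM (default 0.8).
#' @return named character vector gene -> module colour.
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = 0.8) {
  abort_if(min_module_size < 2, "min_module_size must be at least 2")
  abort_if(nrow(tom) < 2, "need at least two genes")
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  colors <- stats::setNames(rep("grey", length(raw)), rownames(tom))
  if (length(keep) > 0) {
    pal <- wgcna_colors(length(keep))
    for (i in seq_along(keep)) colors[raw == as.integer(keep[i])] <- pal[i]
  }
  colors
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix
#' (samples as observations), scaled to unit variance and sign-aligned so it
#' correlates positively with the module's mean standardized profile.
#'
#' @param logm genes x samples matrix (log2 scale).
#' @param module_genes gene ids of the module.
#' @return list with `eigengene` (named per-sample vector, sd 1),
#'   `var_explained` (PC1 variance fraction in (0, 1]).
#' @export
module_eigengene <- function(logm, module_genes) {
  abort_if(length(module_genes) == 0, "module is empty")
  x <- t(logm[module_genes, , drop = FALSE])      # samples x genes
  abort_if(nrow(x) < 2, "need at least two samples")
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  abort_if(ncol(x) == 0, "every module gene has zero variance")
  xs <- scale(x)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  eig <- pc$x[, 1]
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  eig <- eig / stats::sd(eig)
  mean_profile <- rowMeans(xs)
  if (stats::sd(mean_profile) > 0 && stats::cor(eig, mean_profile) < 0) {
    eig <- -eig
  }
  list(eigengene = stats::setNames(eig, rownames(x)), var_explained = ve)
}

#' Eigengenes for every (non-grey) module
#'
#' @param logm genes x samples matrix.
#' @param modules named vector gene -> module colour from [detect_modules()].
#' @return samples x modules matrix of unit-variance eigengenes (columns named
#'   `ME<colour>`).
#' @export
module_eigengenes <- function(logm, modules) {
  cols <- setdiff(unique(modules), "grey")
  abort_if(length(cols) == 0, "no non-grey modules")
  me <- vapply(cols, function(cl) {
    module_eigengene(logm, names(modules)[modules == cl])$eigengene
  }, numeric(ncol(logm)))
  colnames(me) <- paste0("ME", cols)
  rownames(me) <- colnames(logm)
  me
}

#' Module eigengene-trait associations
#'
#' (a) Pairwise Pearson correlations between each eigengene and each numeric
#' trait, with two-sided p-values from the exact t transform
#' t = r * sqrt((n-2) / (1-r^2)); (b) per-module ordinary least squares fits
#' `ME ~ Stage + Cultivar + CR_group + ABA + GA3 + GA7`. In the reference
#' design CR group is collinear with the cultivar dummies; the aliased
#' term is dropped by the fit and reported in `aliased`.
#'
#' @param me samples x modules eigengene matrix.
#' @param traits data.frame with per-sample traits: numeric columns enter the
#'   correlation surface; `cultivar` (factor/character) enters the linear
#'   model only.
#' @return list with `r`, `p` (modules x numeric traits), `n`, and `models`
#'   (per module: coefficient table and aliased term names).
#' @export
module_trait_association <- function(me, traits) {
  abort_if(nrow(traits) != nrow(me), "traits rows must match eigengene rows")
  num <- traits[, vapply(traits, is.numeric, logical(1)), drop = FALSE]
  abort_if(ncol(num) == 0, "no numeric traits supplied")
  n <- nrow(me)
  r <- stats::cor(me, as.matrix(num))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  models <- lapply(colnames(me), function(m) {
    dat <- data.frame(ME = me[, m], traits, stringsAsFactors = TRUE)
    fit <- stats::lm(ME ~ ., data = dat)
    co <- stats::coef(fit)
    aliased <- names(co)[is.na(co)]
    list(coefficients = summary(fit)$coefficients, aliased = aliased)
  })
  names(models) <- colnames(me)
  list(r = r, p = p, n = n, models = models)
}

#' Cross-cultivar consensus co-expression network
#'
#' An edge is retained iff at least `k_of_n` cultivars show the same
#' correlation sign with |r| >= `min_abs_r` in each supporting cultivar. The
#' consensus weight is the signed minimum |r| among the supporters; the
#' support count and the per-cultivar correlations are recorded per edge.
#'
#' @param per_cultivar_mats named list of genes x samples matrices, one per
#'   cultivar (stage-residualized within cultivar); identical gene sets
#'   required.
#' @param k_of_n required number of sign-concordant supporting cultivars
#'   (default 3).
#' @param min_abs_r per-cultivar support threshold on |r| (default 0.5).
#' @return `gene_network` list: `edges` (gene1, gene2, weight, sign, support,
#'   r.<cultivar> columns), `degree`, `nodes`.
#' @export
consensus_network <- function(per_cultivar_mats, k_of_n = 3, min_abs_r = 0.5) {
  nc <- length(per_cultivar_mats)
  abort_if(nc == 0, "no per-cultivar matrices supplied")
  abort_if(k_of_n > nc, "k_of_n (", k_of_n, ") exceeds the number of cultivars (", nc, ")")
  nodes <- rownames(per_cultivar_mats[[1]])
  for (m in per_cultivar_mats) {
    abort_if(!identical(rownames(m), nodes),
             "per-cultivar matrices must share an identical gene set")
  }
  if (is.null(names(per_cultivar_mats))) {
    names(per_cultivar_mats) <- paste0("cv", seq_len(nc))
  }
  Rs <- lapply(per_cultivar_mats, function(m) suppressWarnings(stats::cor(t(m))))
  ut <- upper.tri(Rs[[1]])
  rmat <- matrix(vapply(Rs, function(R) R[ut], numeric(sum(ut))),
                 nrow = sum(ut), ncol = nc)                # pairs x cultivars
  rmat[is.na(rmat)] <- 0
  sup_pos <- rowSums(rmat >= min_abs_r)
  sup_neg <- rowSums(rmat <= -min_abs_r)
  # sign with the larger support wins; exact ties are dropped (deterministic)
  retain <- pmax(sup_pos, sup_neg) >= k_of_n & sup_pos != sup_neg
  idx <- which(ut, arr.ind = TRUE)[retain, , drop = FALSE]
  rsel <- rmat[retain, , drop = FALSE]
  sgn <- ifelse(sup_pos[retain] >= sup_neg[retain], 1L, -1L)
  support <- as.integer(pmax(sup_pos, sup_neg)[retain])
  weight <- vapply(seq_len(nrow(rsel)), function(i) {
    rr <- rsel[i, ]
    supp <- if (sgn[i] > 0) rr[rr >= min_abs_r] else -rr[rr <= -min_abs_r]
    sgn[i] * min(supp)
  }, numeric(1))
  edges <- data.frame(gene1 = nodes[idx[, 1]], gene2 = nodes[idx[, 2]],
                      weight = weight, sign = sgn, support = support,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    percv <- as.data.frame(rsel)
  } else {
    percv <- as.data.frame(matrix(numeric(0), 0, nc))
  }
  names(percv) <- paste0("r.", names(per_cultivar_mats))
  edges <- cbind(edges, percv)
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0) {
    tab <- table(c(edges$gene1, edges$gene2))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(edges = edges, degree = deg, nodes = nodes,
                 k_of_n = k_of_n, min_abs_r = min_abs_r),
            class = "gene_network")
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, 1:2, drop = FALSE],
                                directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

#' Node degree and betweenness centrality
#'
#' Degree is the incident retained-edge count; the bridge score is the
#' betweenness centrality on unweighted shortest paths, normalized to [0, 1].
#'
#' @param network a `gene_network`.
#' @return data.frame (gene, degree, betweenness); the induced subgraph of
#'   degree > 0 nodes is attached as attribute `core_graph` (igraph object).
#' @export
node_centrality <- function(network) {
  if (length(network$nodes) == 0) {
    return(data.frame(gene = character(), degree = integer(),
                      betweenness = numeric(), stringsAsFactors = FALSE))
  }
  g <- network_graph(network)
  deg <- igraph::degree(g)
  btw <- if (igraph::vcount(g) > 2) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else {
    stats::setNames(rep(0, igraph::vcount(g)), igraph::V(g)$name)
  }
  out <- data.frame(gene = igraph::V(g)$name,
                    degree = as.integer(deg[igraph::V(g)$name]),
                    betweenness = as.numeric(btw[igraph::V(g)$name]),
                    stringsAsFactors = FALSE)
  attr(out, "core_graph") <- igraph::induced_subgraph(g, igraph::V(g)[deg > 0])
  out
}

#' Export a network to GraphML (Cytoscape-compatible)
#'
#' @param network a `gene_network`.
#' @param path output file.
#' @param node_attrs optional data.frame with a `gene` column plus node
#'   attributes (module colour, class, ...).
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(network, path, node_attrs = NULL) {
  verts <- data.frame(name = network$nodes, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    verts <- merge(verts, node_attrs, by.x = "name", by.y = "gene",
                   all.x = TRUE, sort = FALSE)
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network in SIF format (Cytoscape-compatible)
#'
#' One `gene1 <interaction> gene2` line per edge; the interaction label is
#' `pos`/`neg` by correlation sign.
#'
#' @param network a `gene_network`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_network_sif <- function(network, path) {
  e <- network$edges
  sgn <- if (nrow(e) > 0) ifelse(e$sign >= 0, "pos", "neg") else character(0)
  writeLines(if (nrow(e) > 0) paste(e$gene1, sgn, e$gene2, sep = "\t")
             else character(0), path)
  invisible(path)
}
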