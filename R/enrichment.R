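#' Hypergeometric upper-tail p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn from a universe of `N`
#' containing `K` annotated ones. Computed with log-gamma arithmetic
#' (numerically stable for N up to 1e6).
#'
#' @param N universe size.
#' @param K genes annotated with the term.
#' @param n size of the tested gene set.
#' @param k overlap between the set and the term.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  abort_if(any(vals < 0) || any(vals != round(vals)),
           "N, K, n, k must be non-negative integers")
  abort_if(K > N || n > N, "K and n must not exceed N")
  abort_if(k > min(K, n), "k must not exceed min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1,
#' returned in the input order.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return adjusted values (same length and order).
#' @export
bh_fdr <- function(pvalues) {
  abort_if(length(pvalues) == 0, "no p-values supplied")
  abort_if(any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1),
           "p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation of terms in a gene set
#'
#' Tests every term with at least one gene in the set (terms with zero
#' overlap are not tested, which reduces the BH family size). When the
#' annotation has multiple layers, BH is applied within each layer
#' separately.
#'
#' @param genes gene set (character); must be a subset of `universe`.
#' @param annotation data.frame with columns `gene`, `term` and optionally
#'   `layer`.
#' @param universe background gene ids (typically all expressed genes).
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame (term, layer, N, K, n, k, p, q, significant) sorted by
#'   q then p.
#' @export
enrich_geneset <- function(genes, annotation, universe, fdr = 0.05) {
  abort_if(length(universe) == 0, "empty universe")
  universe <- unique(universe)
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  abort_if(length(outside) > 0,
           "gene set contains ids outside the universe: ",
           paste(utils::head(outside, 5), collapse = ", "))
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  if (is.null(ann$layer)) ann$layer <- "default"
  ann <- unique(ann[, c("gene", "term", "layer")])
  N <- length(universe)
  n <- length(genes)
  in_set <- ann$gene %in% genes
  K_tab <- table(ann$term)
  k_tab <- table(ann$term[in_set])
  terms <- names(k_tab)[k_tab >= 1]
  if (length(terms) == 0) {
    return(data.frame(term = character(), layer = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  layer_of <- ann$layer[match(terms, ann$term)]
  K <- as.integer(K_tab[terms])
  k <- as.integer(k_tab[terms])
  p <- mapply(hypergeom_pvalue, N = N, K = K, n = n, k = k)
  out <- data.frame(term = terms, layer = layer_of, N = N, K = K, n = n,
                    k = k, p = p, stringsAsFactors = FALSE)
  out$q <- NA_real_
  for (ly in unique(out$layer)) {
    idx <- out$layer == ly
    out$q[idx] <- bh_fdr(out$p[idx])
  }
  out$significant <- out$q < fdr
  out[order(out$q, out$p, out$term), ]
}
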