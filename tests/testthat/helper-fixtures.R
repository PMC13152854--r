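# Shared fixtures and independent brute-force oracles.

# Reference 4-cultivar x 3-stage x 3-replicate design.
make_design <- function(cultivars = c(NG = "Low", NS = "Low", CM = "High", ZY = "High"),
                        stages = c("S1", "S2", "S3"), reps = 3) {
  grid <- expand.grid(replicate = seq_len(reps), stage = stages,
                      cultivar = names(cultivars), stringsAsFactors = FALSE)
  validate_design(data.frame(
    sample_id = paste0(grid$cultivar, "_", grid$stage, "_r", grid$replicate),
    cultivar = grid$cultivar, stage = grid$stage, replicate = grid$replicate,
    cr_group = unname(cultivars[grid$cultivar]), stringsAsFactors = FALSE))
}

# Replicate-mean matrix with the attributes replicate_means() attaches,
# built directly from a genes x (cultivar, stage) value matrix.
make_rep_means <- function(values, cultivars = c(NG = "Low", NS = "Low",
                                                 CM = "High", ZY = "High"),
                           stages = c("S1", "S2", "S3")) {
  cells <- expand.grid(stage = stages, cultivar = names(cultivars),
                       stringsAsFactors = FALSE)[, c("cultivar", "stage")]
  cells$cr_group <- unname(cultivars[cells$cultivar])
  stopifnot(ncol(values) == nrow(cells))
  colnames(values) <- paste(cells$cultivar, cells$stage, sep = ".")
  attr(values, "cells") <- cells
  attr(values, "stages") <- stages
  values
}

# Exact hypergeometric upper tail as a sum of choose() products -- an
# arithmetic route independent of phyper's algorithm (exact doubles for
# N <= 60 up to choose()'s 2^53 resolution).
brute_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Hand step-up BH adjustment.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# TOM by explicit triple loop.
brute_tom <- function(a) {
  n <- nrow(a)
  tom <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# Normalized betweenness by exhaustive shortest-path enumeration (n <= ~8).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    # BFS distance
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0 && !is.finite(dist[t])) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] > 0 & dist > dist[v] + 1)
        dist[nb] <- dist[v] + 1
        nxt <- union(nxt, nb)
      }
      frontier <- nxt
    }
    if (!is.finite(dist[t])) return(list())
    # DFS over shortest paths only
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
      for (w in which(adj[v, ] > 0)) {
        if (dist[w] == dist[v] + 1) walk(c(path, w))
      }
    }
    dist2 <- rep(Inf, n); dist2[t] <- 0  # distances to t for pruning
    walk(s)
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      btw[v] <- btw[v] + mean(vapply(ps, function(p) v %in% p, logical(1)))
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# Vector with prescribed Pearson correlation r to x (exact, for oracle edges).
corr_vector <- function(x, r) {
  x <- as.numeric(scale(x))
  z <- stats::rnorm(length(x))
  z <- as.numeric(scale(stats::residuals(stats::lm(z ~ x))))
  r * x + sqrt(1 - r^2) * z
}

skip_if_no_mclust <- function() testthat::skip_if_not_installed("mclust")

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
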