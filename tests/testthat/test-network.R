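test_that("stage residualization zeroes stage means and keeps cultivar offsets", {
  design <- make_design()
  set.seed(2)
  logm <- matrix(rnorm(30 * 36), nrow = 30,
                 dimnames = list(paste0("g", 1:30), design$sample_id))
  res <- residualize_by_stage(logm, design)
  for (s in c("S1", "S2", "S3")) {
    idx <- which(as.character(design$stage) == s)
    expect_true(all(abs(rowMeans(res[, idx])) < 1e-12))
  }
  # gene constant within each stage -> all residuals zero
  g <- as.numeric(factor(design$stage))
  resg <- residualize_by_stage(matrix(g, 1, 36), as.character(design$stage))
  expect_true(all(abs(resg) < 1e-12))
  # pure cultivar offsets survive up to a constant (2-cultivar toy)
  d2 <- make_design(cultivars = c(A = "Low", B = "High"))
  offs <- c(A = 2, B = 6)
  x <- matrix(offs[d2$cultivar], 1, nrow(d2))
  r2 <- residualize_by_stage(x, as.character(d2$stage))
  expect_equal(unname(r2[1, ]), unname(offs[d2$cultivar] - mean(offs)),
               tolerance = 1e-12)
  # residualization is invariant to adding a stage-constant vector
  shift <- c(S1 = 5, S2 = -2, S3 = 11)[as.character(design$stage)]
  res_shift <- residualize_by_stage(logm + rep(shift, each = nrow(logm)) * 0 +
                                      matrix(shift, nrow(logm), 36, byrow = TRUE),
                                    design)
  expect_equal(res_shift, res, tolerance = 1e-12)
  expect_error(residualize_by_stage(logm, rep("S1", 10)), "stage vector")
})

test_that("correlation networks threshold |r| and count degrees", {
  set.seed(7)
  x <- rnorm(36)
  mat <- rbind(a = x, b = x, c = rnorm(36))  # a and b identical
  colnames(mat) <- paste0("s", 1:36)
  net <- correlation_network(mat, min_abs_r = 0.8)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$r, 1)
  expect_equal(unname(net$degree[c("a", "b", "c")]), c(1L, 1L, 0L))
  # zero-variance gene dropped with a warning
  mat2 <- rbind(mat, flat = rep(1, 36))
  expect_warning(net2 <- correlation_network(mat2, 0.8), "zero-variance")
  expect_false("flat" %in% net2$nodes)
  # independent noise genes rarely reach |r| >= 0.8 at n = 36
  set.seed(8)
  hits <- replicate(20, {
    m <- matrix(rnorm(15 * 36), 15, dimnames = list(paste0("g", 1:15), NULL))
    nrow(correlation_network(m, 0.8)$edges)
  })
  expect_lt(mean(hits) / choose(15, 2), 0.01)
})

test_that("topological overlap matches its closed forms and brute force", {
  # two genes connected only to each other with a = 1 -> TOM = 1
  a2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(tom_similarity(a2), matrix(1, 2, 2))
  # empty adjacency -> identity
  a0 <- matrix(0, 4, 4)
  expect_equal(tom_similarity(a0), diag(4))
  # random adjacencies against the triple loop
  set.seed(10)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(tom_similarity(a), brute_tom(a), tolerance = 1e-12)
    tom <- tom_similarity(a)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(c(0, 2, 2, 0), 2, 2)), "\\[0, 1\\]")
  bad <- matrix(0.5, 2, 2)
  expect_error(tom_similarity(bad), "diagonal")
})

test_that("module detection resolves planted co-expression blocks", {
  set.seed(20)
  n_per <- 25; n_samp <- 36
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  block <- function(f, n) t(vapply(seq_len(n),
                                   function(i) f + rnorm(n_samp, 0, 0.35),
                                   numeric(n_samp)))
  mat <- rbind(block(f1, n_per), block(f2, n_per))
  rownames(mat) <- paste0("g", seq_len(2 * n_per))
  R <- cor(t(mat))
  modules <- detect_modules(tom_similarity(adjacency_from_cor(R, 6)),
                            min_module_size = 20, cut_height = 0.8)
  found <- setdiff(unique(modules), "grey")
  expect_equal(length(found), 2)
  expect_setequal(found, c("turquoise", "blue"))
  # block membership is recovered
  expect_equal(length(unique(modules[1:n_per])), 1)
  expect_equal(length(unique(modules[(n_per + 1):(2 * n_per)])), 1)
  # all-identical genes collapse into one module
  same <- matrix(rep(rnorm(10), each = 30), 30, 10,
                 dimnames = list(paste0("g", 1:30), NULL))
  R1 <- cor(t(same))
  m1 <- detect_modules(tom_similarity(adjacency_from_cor(R1, 6)),
                       min_module_size = 20, cut_height = 0.8)
  expect_equal(unname(unique(m1)), "turquoise")
  # below-size clusters go grey
  small <- matrix(rnorm(5 * 10), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  Rs <- suppressWarnings(cor(t(small)))
  ms <- detect_modules(tom_similarity(adjacency_from_cor(Rs, 6)),
                       min_module_size = 20, cut_height = 0.8)
  expect_true(all(ms == "grey"))
  expect_error(detect_modules(diag(3), min_module_size = 1), "at least 2")
})

test_that("module eigengenes are unit-variance and sign-aligned", {
  design <- make_design()
  profile <- sin(seq_len(36))
  logm <- t(vapply(1:10, function(i) 3 * profile + i, numeric(36)))
  dimnames(logm) <- list(paste0("g", 1:10), design$sample_id)
  me <- module_eigengene(logm, paste0("g", 1:10))
  expect_equal(sd(me$eigengene), 1, tolerance = 1e-12)
  expect_equal(me$var_explained, 1, tolerance = 1e-12)
  expect_equal(cor(me$eigengene, profile), 1, tolerance = 1e-10)
  # flipping all genes flips the mean profile, and alignment follows it
  me_fl <- module_eigengene(-logm, paste0("g", 1:10))
  expect_equal(cor(me_fl$eigengene, -profile), 1, tolerance = 1e-10)
  expect_error(module_eigengene(logm[, 1, drop = FALSE], "g1"), "two samples")
  expect_error(module_eigengene(logm, character(0)), "empty")
})

test_that("eigengene-trait statistics match the t closed form and flag aliasing", {
  design <- make_design()
  set.seed(4)
  logm <- matrix(rnorm(40 * 36), 40, 36,
                 dimnames = list(paste0("g", 1:40), design$sample_id))
  modules <- setNames(rep(c("turquoise", "blue"), each = 20), rownames(logm))
  me <- module_eigengenes(logm, modules)
  aba <- me[, "MEturquoise"]  # trait equal to an eigengene
  traits <- data.frame(stage_num = as.integer(design$stage),
                       cultivar = factor(design$cultivar),
                       cr_group_num = as.integer(design$cr_group == "High"),
                       ABA = aba, GA3 = rnorm(36), GA7 = rnorm(36))
  # (perfect-fit warning expected: ABA equals the eigengene by construction)
  assoc <- suppressWarnings(module_trait_association(me, traits))
  expect_equal(assoc$r["MEturquoise", "ABA"], 1, tolerance = 1e-12)
  expect_lt(assoc$p["MEturquoise", "ABA"], 1e-12)
  # p-values equal the closed form / cor.test oracle
  ct <- cor.test(me[, "MEblue"], traits$GA3)
  expect_equal(assoc$r["MEblue", "GA3"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(assoc$p["MEblue", "GA3"], ct$p.value, tolerance = 1e-10)
  # CR group is collinear with cultivar dummies: dropped and reported
  expect_true("cr_group_num" %in% assoc$models$MEturquoise$aliased)
})

test_that("consensus edges need k-of-n sign-concordant strong support", {
  set.seed(6)
  base <- rnorm(9)
  mk <- function(r) {
    m <- rbind(g1 = as.numeric(scale(base)), g2 = corr_vector(base, r))
    colnames(m) <- paste0("s", 1:9)
    m
  }
  # per-cultivar correlations (+0.9, +0.8, +0.7, -0.6): retained with
  # support 3 and weight +0.7
  mats <- list(cv1 = mk(0.9), cv2 = mk(0.8), cv3 = mk(0.7), cv4 = mk(-0.6))
  net <- consensus_network(mats, k_of_n = 3, min_abs_r = 0.5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$support, 3L)
  expect_equal(net$edges$weight, 0.7, tolerance = 1e-10)
  expect_equal(net$edges$sign, 1L)
  # (+0.9, +0.9, -0.9, -0.9): dropped
  mats2 <- list(mk(0.9), mk(0.9), mk(-0.9), mk(-0.9))
  expect_equal(nrow(consensus_network(mats2, 3, 0.5)$edges), 0)
  expect_error(consensus_network(mats, k_of_n = 5), "exceeds")
})

test_that("raising k_of_n or min_abs_r never adds consensus edges", {
  set.seed(30)
  design9 <- paste0("s", 1:9)
  mats <- lapply(1:4, function(i) {
    m <- matrix(rnorm(12 * 9), 12, 9,
                dimnames = list(paste0("g", 1:12), design9))
    # shared factor so some edges exist
    m[1:6, ] <- m[1:6, ] + matrix(rep(rnorm(9) * 1.5, each = 6), 6, 9)
    m
  })
  edge_key <- function(net) paste(net$edges$gene1, net$edges$gene2)
  for (thr in c(0.3, 0.5, 0.7)) {
    e2 <- edge_key(consensus_network(mats, 2, thr))
    e3 <- edge_key(consensus_network(mats, 3, thr))
    e4 <- edge_key(consensus_network(mats, 4, thr))
    expect_true(all(e3 %in% e2))
    expect_true(all(e4 %in% e3))
  }
  for (k in 2:4) {
    lo <- edge_key(consensus_network(mats, k, 0.3))
    hi <- edge_key(consensus_network(mats, k, 0.6))
    expect_true(all(hi %in% lo))
  }
})

test_that("centrality matches closed forms and brute-force enumeration", {
  star <- structure(list(
    edges = data.frame(gene1 = "hub", gene2 = paste0("leaf", 1:4),
                       sign = 1L, stringsAsFactors = FALSE),
    nodes = c("hub", paste0("leaf", 1:4))), class = "gene_network")
  cent <- node_centrality(star)
  expect_equal(cent$degree[cent$gene == "hub"], 4L)
  expect_true(all(cent$degree[cent$gene != "hub"] == 1L))
  # path a-b-c: normalized betweenness of b is 1
  path <- structure(list(
    edges = data.frame(gene1 = c("a", "b"), gene2 = c("b", "c"), sign = 1L),
    nodes = c("a", "b", "c")), class = "gene_network")
  cb <- node_centrality(path)
  expect_equal(cb$betweenness[cb$gene == "b"], 1)
  expect_equal(cb$betweenness[cb$gene == "a"], 0)
  # random graphs vs exhaustive shortest-path enumeration
  set.seed(12)
  for (i in 1:10) {
    n <- 6
    adj <- matrix(0, n, n)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- sample(nrow(pairs), sample(4:10, 1))
    for (e in on) adj[pairs[e, 1], pairs[e, 2]] <- adj[pairs[e, 2], pairs[e, 1]] <- 1
    nodes <- paste0("n", 1:n)
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    net <- structure(list(
      edges = data.frame(gene1 = nodes[idx[, 1]], gene2 = nodes[idx[, 2]],
                         sign = 1L, stringsAsFactors = FALSE),
      nodes = nodes), class = "gene_network")
    got <- node_centrality(net)
    expect_equal(got$betweenness[match(nodes, got$gene)],
                 brute_betweenness(adj), tolerance = 1e-12)
  }
  # empty network -> empty result
  empty <- structure(list(edges = data.frame(gene1 = character(),
                                             gene2 = character(),
                                             sign = integer()),
                          nodes = character()), class = "gene_network")
  expect_equal(nrow(node_centrality(empty)), 0)
})

test_that("network exports are Cytoscape-compatible text", {
  dir <- withr::local_tempdir()
  net <- structure(list(
    edges = data.frame(gene1 = c("a", "b"), gene2 = c("b", "c"),
                       weight = c(0.9, -0.7), sign = c(1L, -1L),
                       support = c(3L, 4L), stringsAsFactors = FALSE),
    nodes = c("a", "b", "c")), class = "gene_network")
  sif <- file.path(dir, "net.sif")
  write_network_sif(net, sif)
  expect_equal(readLines(sif), c("a\tpos\tb", "b\tneg\tc"))
  gml <- file.path(dir, "net.graphml")
  write_network_graphml(net, gml,
                        node_attrs = data.frame(gene = c("a", "b", "c"),
                                                module = "turquoise"))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})
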