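test_that("stage group differences are cultivar-level arithmetic", {
  # High cultivars (2.0, 3.0), Low (1.0, 2.0) at S1 -> d = 2.5 - 1.5 = 1.0
  vals <- matrix(0, 1, 12)
  vals[1, ] <- c(1, 0, 0,  2, 0, 0,  2, 0, 0,  3, 0, 0)  # NG,NS low; CM,ZY high
  rm <- make_rep_means(vals)
  sgd <- stage_group_difference(rm)
  expect_equal(unname(sgd$d[1, "S1"]), 1.0)
  expect_equal(unname(sgd$high[1, "S1"]), 2.5)
  expect_equal(unname(sgd$low[1, "S1"]), 1.5)
  # identical groups -> d = 0 everywhere
  same <- make_rep_means(matrix(rep(c(3, 5, 7), 4), nrow = 1))
  expect_equal(unname(stage_group_difference(same)$d[1, ]), c(0, 0, 0))
  # swapping group labels negates d
  flipped <- make_rep_means(vals, cultivars = c(NG = "High", NS = "High",
                                                CM = "Low", ZY = "Low"))
  expect_equal(stage_group_difference(flipped)$d, -sgd$d)
  # a CR group with zero cultivars is an error
  onegrp <- make_rep_means(vals, cultivars = c(NG = "Low", NS = "Low",
                                               CM = "Low", ZY = "Low"))
  expect_error(stage_group_difference(onegrp), "High")
})

test_that("module divergence averages |d| and breaks peak ties early", {
  d <- rbind(g1 = c(0.4, 0.1, 0.1), g2 = c(0.6, 0.1, 0.1))
  colnames(d) <- c("S1", "S2", "S3")
  cl <- structure(list(cluster = c(g1 = "C1", g2 = "C1"),
                       sizes = c(C1 = 2L)), class = "chill_clusters")
  md <- module_stage_divergence(d, cl)
  expect_equal(md$S1, 0.5)
  expect_equal(md$peak_stage, "S1")
  # all-zero differences: D = 0 everywhere, peak = S1 by the tie rule
  d0 <- rbind(g1 = c(0, 0, 0), g2 = c(0, 0, 0))
  colnames(d0) <- c("S1", "S2", "S3")
  md0 <- module_stage_divergence(d0, cl)
  expect_equal(unname(unlist(md0[, c("S1", "S2", "S3")])), c(0, 0, 0))
  expect_equal(md0$peak_stage, "S1")
  # invariant to gene order
  d_rev <- d[2:1, ]
  cl_rev <- structure(list(cluster = c(g2 = "C1", g1 = "C1"),
                           sizes = c(C1 = 2L)), class = "chill_clusters")
  expect_equal(module_stage_divergence(d_rev, cl_rev)$S1, md$S1)
})

test_that("discordance requires opposite significant signs", {
  d <- rbind(a = c(0.3, 0.2, 0.4),        # constant sign -> concordant
             b = c(0.3, -0.3, 0.1),       # sign change -> discordant
             c = c(0.01, -0.01, 0.02))    # all below eps -> not discordant
  colnames(d) <- c("S1", "S2", "S3")
  fl <- discordance_flag(d, eps = 0.05)
  expect_equal(unname(fl), c(FALSE, TRUE, FALSE))
})

test_that("cultivar concordance implements the k-of-n trend filter", {
  # trends per cultivar are sign(S3 - S1); rows engineered as (+,+,+,-),
  # (+,+,-,-), (+,+,+,+)
  vals <- rbind(
    c(0, 0, 1,  0, 0, 1,  0, 0, 1,  1, 0, 0),
    c(0, 0, 1,  0, 0, 1,  1, 0, 0,  1, 0, 0),
    c(0, 0, 1,  0, 0, 1,  0, 0, 1,  0, 0, 1))
  rownames(vals) <- c("pass3", "fail2", "pass4")
  rm <- make_rep_means(vals)
  cc <- cultivar_concordance(rm, eps = 0.05, k_of_n = 3)
  expect_equal(unname(cc$count), c(3L, 2L, 4L))
  expect_equal(unname(cc$pass), c(TRUE, FALSE, TRUE))
  # sub-eps deltas give sign 0 and do not count
  flat <- make_rep_means(matrix(c(0, 0, 0.01), 1, 12))
  expect_equal(unname(cultivar_concordance(flat)$count), 0L)
  expect_error(cultivar_concordance(rm, k_of_n = 5), "exceeds")
})

test_that("the abundance gate is boundary-inclusive", {
  m <- rbind(edge = c(1, rep(0.48611111, 35)),            # mean .5001, max 1
             pass_exact = c(1, rep((0.5 * 36 - 1) / 35, 35)),
             fail_mean = c(5, rep(0.26, 35)),
             zeros = rep(0, 36))
  colnames(m) <- paste0("s", 1:36)
  g <- abundance_gate(m)
  expect_true(g[["pass_exact"]])       # mean exactly 0.5, max exactly 1
  expect_false(g[["fail_mean"]])       # mean 0.39 despite max 5
  expect_false(g[["zeros"]])
})

test_that("candidate selection is the conjunction of all gates", {
  genes <- paste0("g", 1:6)
  cl <- structure(list(cluster = setNames(c("C1", "C1", "C1", "C1", "C1", "C2"),
                                          genes),
                       sizes = c(C1 = 5L, C2 = 1L)), class = "chill_clusters")
  disc <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE), genes)
  conc <- setNames(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE), genes)
  abund <- setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), genes)
  classes <- setNames(c("TF", "other", "kinase-related", "TF", "TF", "TF"), genes)
  cand <- select_candidates(cl, "C1", disc, conc, abund, classes)
  # g1, g3 pass everything; g2 fails only the class filter; g4 abundance;
  # g5 discordance; g6 is outside the flagged clusters
  expect_equal(cand$gene[cand$candidate], c("g1", "g3"))
  expect_false(cand$candidate[cand$gene == "g2"])
  expect_true(all(cand$cluster[cand$candidate] %in% "C1"))
  expect_equal(unname(attr(cand, "cluster_counts")["C1"]), 2)
  expect_error(select_candidates(cl, "C1", disc, conc, abund, classes,
                                 plausible_classes = character(0)), "empty")
})

test_that("planted candidates are fully recovered at zero noise", {
  spec <- truth_spec(n_genes = 500, seed = 31, noise_sd = 0, term_size = 10)
  ds <- generate_dataset(spec)
  expressed <- filter_expressed(ds$tpm)
  rm_log <- replicate_means(expressed, ds$design)
  traj <- zscore_trajectories(rm_log)
  a <- cluster_kmeans(traj, k = 8, seed = 3)
  sgd <- stage_group_difference(rm_log)
  disc <- discordance_flag(sgd$d)
  conc <- cultivar_concordance(rm_log)
  abund <- abundance_gate(expressed)
  flagged <- flag_cr_divergent_clusters(a, disc)
  classes <- gene_classes(ds$annotations, rownames(expressed))
  cand <- select_candidates(a, flagged, disc, conc$pass, abund, classes)

  # construction oracle: apply the planted rules to the truth table
  truth <- ds$truth
  truth <- truth[truth$gene %in% names(a$cluster), ]
  arch_cl <- table(a$cluster, setNames(truth$archetype, truth$gene)[names(a$cluster)])
  flagged_arch <- colnames(arch_cl)[apply(arch_cl[flagged, , drop = FALSE], 1,
                                          which.max)]
  expected <- truth$gene[
    truth$carrier &
      truth$archetype %in% flagged_arch &
      disc[truth$gene] & conc$pass[truth$gene] & abund[truth$gene] &
      truth$class != "other"]
  got <- cand$gene[cand$candidate]
  expect_setequal(got, expected)
  expect_gt(length(got), 0)
  # containment: candidates live inside the flagged-cluster gene union
  expect_true(all(a$cluster[got] %in% flagged))
})

test_that("doubling every TPM shifts d by less than one log2 unit", {
  ds <- generate_dataset(truth_spec(n_genes = 200, seed = 17, term_size = 5))
  rm1 <- replicate_means(ds$tpm, ds$design)
  tpm2 <- ds$tpm * 2
  attr(tpm2, "design") <- ds$design
  rm2 <- replicate_means(tpm2, ds$design)
  d1 <- stage_group_difference(rm1)$d
  d2 <- stage_group_difference(rm2)$d
  expect_lt(max(abs(d2 - d1)), log2(2))
  # sign-based flags are stable away from the eps boundary
  eps <- 0.05
  stable <- apply(abs(abs(d1) - eps) > 0.02, 1, all)
  f1 <- discordance_flag(d1, eps)
  f2 <- discordance_flag(d2, eps)
  expect_equal(f1[stable], f2[stable])
})
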