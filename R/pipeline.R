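#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline with its documented default. The
#' `simulate` block holds [truth_spec()] arguments used when no input paths
#' are given; the `input` block holds the four file paths otherwise.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    input = NULL,                 # list(expression=, samples=, hormones=, annotations=, classes=)
    simulate = list(),            # truth_spec() overrides
    min_tpm = 1,                  # expression filter: TPM threshold
    min_libraries = 3,            # expression filter: library count
    n_top_genes = 2000,           # PCA variable-gene count
    k = 8,                        # trajectory modules
    n_restarts = 25,              # k-means restarts
    cluster_mode = "concatenate", # or "pooled"
    tau_discordant = 0.5,         # cluster flagging threshold
    eps = 0.05,                   # sign-call threshold (log2 units)
    concordance_k = 3,            # k-of-n cultivar concordance
    concordance_mode = "endpoint",
    min_mean_tpm = 0.5,           # abundance gate
    min_max_tpm = 1,
    min_abs_r = 0.8,              # pooled correlation-network threshold
    beta = 6,                     # WGCNA soft threshold
    cut_height = 0.8,             # static tree cut on 1 - TOM
    min_module_size = 20,
    consensus_k_of_n = 3,
    consensus_min_abs_r = 0.5,
    weights = as.list(default_weights()),
    top_n = 30,
    plausible_classes = PLAUSIBLE_CLASSES)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and checks ranges. Accepts a list or a
#' YAML file path.
#'
#' @param config list of overrides, or path to a YAML config file, or `NULL`
#'   for all defaults.
#' @return normalized config list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  abort_if(length(unknown) > 0,
           "unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  abort_if(cfg$k < 2, "k must be at least 2")
  abort_if(cfg$min_libraries < 1, "min_libraries must be at least 1")
  abort_if(cfg$min_tpm < 0, "min_tpm must be non-negative")
  abort_if(cfg$eps < 0, "eps must be non-negative")
  abort_if(cfg$tau_discordant < 0 || cfg$tau_discordant > 1,
           "tau_discordant must lie in [0, 1]")
  abort_if(cfg$min_abs_r < 0 || cfg$min_abs_r > 1, "min_abs_r must lie in [0, 1]")
  abort_if(cfg$consensus_min_abs_r < 0 || cfg$consensus_min_abs_r > 1,
           "consensus_min_abs_r must lie in [0, 1]")
  abort_if(cfg$beta <= 0, "beta must be positive")
  abort_if(cfg$cut_height <= 0 || cfg$cut_height > 1,
           "cut_height must lie in (0, 1]")
  abort_if(cfg$min_module_size < 2, "min_module_size must be at least 2")
  abort_if(cfg$concordance_k < 1, "concordance_k must be at least 1")
  abort_if(cfg$top_n < 1, "top_n must be at least 1")
  w <- unlist(cfg$weights)
  abort_if(any(w < 0), "weights must be non-negative")
  abort_if(abs(sum(w) - 1) > 1e-9, "weights must sum to 1 (got ", sum(w), ")")
  abort_if(!cfg$cluster_mode %in% c("concatenate", "pooled"),
           "cluster_mode must be 'concatenate' or 'pooled'")
  abort_if(!cfg$concordance_mode %in% c("endpoint", "majority"),
           "concordance_mode must be 'endpoint' or 'majority'")
  cfg
}

pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$input)) {
    paths <- cfg$input
    design <- read_sample_table(paths$samples)
    tpm <- read_expression(paths$expression, design)
    hormones <- read_hormone_table(paths$hormones, design)
    annotations <- read_annotation_table(paths$annotations, paths$classes)
    list(tpm = tpm, design = design, hormones = hormones,
         annotations = annotations, truth = NULL)
  } else {
    spec <- do.call(truth_spec, utils::modifyList(list(seed = cfg$seed),
                                                  cfg$simulate))
    ds <- generate_dataset(spec)
    list(tpm = ds$tpm, design = ds$design, hormones = ds$hormones,
         annotations = ds$annotations, truth = ds$truth)
  }
}

run_header <- function(cfg, cfg_path) {
  hash <- unname(tools::md5sum(cfg_path))
  c(paste0("chilltraj ", as.character(utils::packageVersion("chilltraj"))),
    paste0("seed=", cfg$seed, " config_md5=", hash))
}

#' Run the full analysis pipeline
#'
#' Stages run in order: QC -> trajectory clustering -> divergence and
#' candidate selection -> enrichment -> networks -> prioritization. Every
#' output TSV carries a header comment with the package version, config hash
#' and seed; a rerun with the same config and seed is byte-identical.
#'
#' @param config config list or YAML path (see [validate_config()]).
#' @param outdir run directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the main in-memory results.
#' @export
run_pipeline <- function(config = NULL, outdir, quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[chilltraj] ", ...)

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  hdr <- run_header(cfg, cfg_path)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("loading inputs")
  inp <- run_stage("input", pipeline_inputs(cfg))
  design <- inp$design

  say("qc")
  qc <- run_stage("qc", {
    expressed <- filter_expressed(inp$tpm, cfg$min_tpm, cfg$min_libraries)
    logm <- log2p1(expressed)
    rep <- qc_report(inp$tpm, design, cfg$min_tpm, cfg$min_libraries,
                     cfg$n_top_genes)
    write_tsv(data.frame(metric = c("n_genes_total", "n_genes_expressed",
                                    "within_group_cor_min", "within_group_cor_max",
                                    paste0("PC", seq_len(min(5, length(rep$pc_variance_fractions))),
                                           "_variance_fraction")),
                         value = c(rep$n_genes_total, rep$n_genes_expressed,
                                   rep$within_group_correlation_range,
                                   rep$pc_variance_fractions[seq_len(min(5, length(rep$pc_variance_fractions)))])),
              file.path(outdir, "qc_report.tsv"), hdr)
    cm <- rep$correlations$matrix
    write_tsv(data.frame(sample_id = rownames(cm), cm, check.names = FALSE),
              file.path(outdir, "sample_correlations.tsv"), hdr)
    sc <- rep$pca$scores
    write_tsv(data.frame(sample_id = rownames(sc),
                         sc[, seq_len(min(5, ncol(sc))), drop = FALSE],
                         check.names = FALSE),
              file.path(outdir, "pca_scores.tsv"), hdr)
    list(expressed = expressed, logm = logm, report = rep)
  })
  expressed <- qc$expressed
  logm <- qc$logm

  say("trajectory clustering (k = ", cfg$k, ")")
  traj_res <- run_stage("trajectory", {
    rm_log <- replicate_means(expressed, design, scale = "log2")
    traj <- zscore_trajectories(rm_log)
    assignment <- cluster_kmeans(traj, k = cfg$k, seed = cfg$seed,
                                 n_restarts = cfg$n_restarts,
                                 mode = cfg$cluster_mode)
    profiles <- cluster_group_profiles(assignment, traj)
    valid <- attr(traj, "valid")
    write_tsv(data.frame(gene = rownames(traj), valid = unname(valid),
                         cluster = unname(assignment$cluster[rownames(traj)])),
              file.path(outdir, "clusters.tsv"), hdr)
    write_tsv(data.frame(cluster = rownames(assignment$centers),
                         assignment$centers, check.names = FALSE),
              file.path(outdir, "centroids.tsv"), hdr)
    write_tsv(profiles, file.path(outdir, "group_profiles.tsv"), hdr)
    list(rep_means = rm_log, traj = traj, assignment = assignment,
         profiles = profiles)
  })
  assignment <- traj_res$assignment

  say("divergence and candidate selection")
  div_res <- run_stage("divergence", {
    sgd <- stage_group_difference(traj_res$rep_means)
    mdiv <- module_stage_divergence(sgd$d, assignment)
    disc <- discordance_flag(sgd$d, eps = cfg$eps)
    conc <- cultivar_concordance(traj_res$rep_means, eps = cfg$eps,
                                 k_of_n = cfg$concordance_k,
                                 mode = cfg$concordance_mode)
    abund <- abundance_gate(expressed, cfg$min_mean_tpm, cfg$min_max_tpm)
    flagged <- flag_cr_divergent_clusters(assignment, disc, cfg$tau_discordant)
    classes <- gene_classes(inp$annotations, rownames(expressed))
    cand <- select_candidates(assignment, flagged, disc, conc$pass, abund,
                              classes, cfg$plausible_classes)
    write_tsv(cand, file.path(outdir, "divergence_genes.tsv"), hdr)
    write_tsv(mdiv, file.path(outdir, "divergence_clusters.tsv"), hdr)
    write_tsv(cand[cand$candidate, , drop = FALSE],
              file.path(outdir, "candidates.tsv"), hdr)
    list(sgd = sgd, module_divergence = mdiv, discordant = disc,
         concordance = conc, abundance = abund, flagged = flagged,
         candidates = cand, classes = classes)
  })

  say("enrichment")
  enr <- run_stage("enrichment", {
    universe <- rownames(expressed)
    res <- lapply(names(assignment$sizes), function(cl) {
      genes <- names(assignment$cluster)[assignment$cluster == cl]
      e <- enrich_geneset(genes, inp$annotations$terms, universe)
      if (nrow(e) > 0) cbind(data.frame(cluster = cl), e)
    })
    res <- do.call(rbind, res)
    if (is.null(res)) res <- data.frame()
    write_tsv(res, file.path(outdir, "enrichment.tsv"), hdr)
    res
  })

  say("co-expression networks")
  net_res <- run_stage("network", {
    cand_genes <- div_res$candidates$gene[div_res$candidates$candidate]
    empty <- list(network = NULL, centrality = data.frame(
      gene = character(), degree = integer(), betweenness = numeric()),
      modules = NULL, me = NULL, traits = NULL, consensus = NULL)
    if (length(cand_genes) < 3) {
      say("  fewer than 3 candidates; skipping network layer")
      write_tsv(data.frame(), file.path(outdir, "edges.tsv"), hdr)
      empty
    } else {
      resid <- residualize_by_stage(logm[cand_genes, , drop = FALSE], design)
      net <- correlation_network(resid, cfg$min_abs_r)
      cent <- node_centrality(net)
      kept <- net$nodes
      R <- stats::cor(t(resid[kept, , drop = FALSE]))
      modules <- if (length(kept) >= cfg$min_module_size) {
        detect_modules(tom_similarity(adjacency_from_cor(R, cfg$beta)),
                       cfg$min_module_size, cfg$cut_height)
      } else stats::setNames(rep("grey", length(kept)), kept)
      me <- NULL; assoc <- NULL
      if (any(modules != "grey")) {
        me <- module_eigengenes(logm[kept, , drop = FALSE], modules)
        hw <- hormones_wide(inp$hormones, design)
        traits <- data.frame(
          stage_num = as.integer(design$stage),
          cultivar = factor(design$cultivar),
          cr_group_num = as.integer(design$cr_group == "High"),
          hw, check.names = FALSE)
        assoc <- module_trait_association(me, traits)
        rmat <- assoc$r; pmat <- assoc$p
        write_tsv(data.frame(module = rownames(rmat),
                             do.call(cbind, list(rmat,
                               stats::setNames(as.data.frame(pmat),
                                               paste0("p.", colnames(pmat))))),
                             check.names = FALSE),
                  file.path(outdir, "module_trait.tsv"), hdr)
        write_tsv(data.frame(sample_id = rownames(me), me, check.names = FALSE),
                  file.path(outdir, "eigengenes.tsv"), hdr)
      }
      write_tsv(data.frame(gene = names(modules), module = unname(modules)),
                file.path(outdir, "modules.tsv"), hdr)
      # per-cultivar consensus network over the candidate pool
      mats <- lapply(split(seq_len(nrow(design)), design$cultivar), function(idx) {
        residualize_by_stage(logm[kept, idx, drop = FALSE],
                             as.character(design$stage)[idx])
      })
      cons <- consensus_network(mats, cfg$consensus_k_of_n,
                                cfg$consensus_min_abs_r)
      write_tsv(cons$edges, file.path(outdir, "edges.tsv"), hdr)
      node_attrs <- data.frame(gene = names(modules), module = unname(modules),
                               class = unname(div_res$classes[names(modules)]),
                               stringsAsFactors = FALSE)
      write_network_graphml(cons, file.path(outdir, "consensus.graphml"),
                            node_attrs)
      write_network_sif(cons, file.path(outdir, "consensus.sif"))
      list(network = net, centrality = cent, modules = modules, me = me,
           traits = assoc, consensus = cons)
    }
  })

  say("prioritization")
  pri <- run_stage("prioritize", {
    eligible <- names(assignment$cluster)[assignment$cluster %in% div_res$flagged]
    if (length(eligible) == 0) {
      say("  no genes in flagged clusters; skipping ranking")
      NULL
    } else {
      comp <- evidence_components(
        eligible, div_res$sgd$d, net_res$centrality,
        div_res$concordance$count, length(unique(design$cultivar)),
        div_res$abundance, div_res$classes, assignment)
      scored <- priority_score(comp, unlist(cfg$weights))
      ranked <- rank_candidates(scored, cfg$top_n)
      w <- attr(scored, "weights")
      whdr <- c(hdr, paste0("weights: ", paste(names(w), w, sep = "=",
                                               collapse = " ")))
      write_tsv(ranked$table, file.path(outdir, "priority_full.tsv"), whdr)
      write_tsv(ranked$top, file.path(outdir, "priority_top.tsv"), whdr)
      prof <- stage_profiles_report(ranked$top$gene, logm, design)
      write_tsv(prof, file.path(outdir, "stage_profiles_top.tsv"), hdr)
      list(ranked = ranked, profiles = prof)
    }
  })

  # machine-readable manifest: checksums of every file in the run directory
  files <- sort(setdiff(list.files(outdir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  say("done: ", outdir)

  invisible(list(config = cfg, inputs = inp, qc = qc$report,
                 trajectory = traj_res, divergence = div_res,
                 enrichment = enr, network = net_res, priority = pri,
                 outdir = outdir))
}
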