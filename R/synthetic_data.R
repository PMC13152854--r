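#' Default trajectory archetypes
#'
#' Builds `n` unit temporal patterns over the given stages: each archetype has
#' zero mean and unit standard deviation (denominator n-1) across stages. For
#' three stages the zero-mean/unit-sd constraint leaves a one-dimensional
#' circle of profiles, so archetypes are placed at fixed angles in the plane
#' spanned by the (sd-1 scaled) linear and quadratic orthogonal contrasts.
#'
#' The default angle order puts the six "trended" shapes (nonzero S1 -> S3
#' displacement) first and the two pure stage-2 shapes last: archetype A7
#' peaks at the middle stage (the shape that drives simulated ABA) and A8 dips
#' there.
#'
#' @param stages ordered stage labels (>= 3 for the default construction).
#' @param angles archetype angles in degrees.
#' @return matrix with one archetype per row, columns named by stage.
#' @export
default_archetypes <- function(stages = c("S1", "S2", "S3"),
                               angles = c(0, 45, 135, 180, 225, 315, 270, 90)) {
  S <- length(stages)
  abort_if(S < 3, "default archetypes need at least three stages")
  contrasts <- stats::poly(seq_len(S), degree = 2)     # orthonormal columns
  basis <- contrasts * sqrt(S - 1)                     # rescale to sd = 1
  th <- angles * pi / 180
  arch <- cos(th) %o% basis[, 1] + sin(th) %o% basis[, 2]
  dimnames(arch) <- list(paste0("A", seq_along(angles)), stages)
  arch
}

#' Specification of a planted synthetic dataset
#'
#' Describes the generative truth for a multi-cultivar, stage-resolved bud
#' transcriptome: per-gene log2(TPM+1) values are a cultivar baseline plus a
#' gene amplitude times the gene's archetype profile, plus (for offset-carrier
#' genes in High-CR cultivars) a signed divergence window, plus Normal noise.
#'
#' @param n_genes number of genes.
#' @param cultivars named character vector mapping cultivar id -> CR group
#'   ("Low"/"High"); the reference design has two of each.
#' @param stages ordered stage labels.
#' @param reps biological replicates per cultivar-stage cell.
#' @param archetypes archetype matrix (rows zero-mean, unit-sd over stages).
#' @param archetype_probs per-archetype gene membership probabilities. The
#'   default overweights the two monotone shapes so that a single dominant
#'   stage axis exists (samples order along PC2 as in real bud data).
#' @param divergent_modules named character vector: archetype id -> planted
#'   peak stage of the High-Low divergence window. `NULL` plants none.
#' @param divergent_fraction fraction of a divergent module's genes carrying
#'   the offset (default 0.65, the discordance prevalence scale observed in
#'   CR-divergent modules).
#' @param offset_peak planted High-Low offset (log2 units) at the peak stage;
#'   off-peak stages get `-offset_peak * offset_taper` (the sign flip plants
#'   directional discordance). Per gene the offset is scaled by a
#'   Uniform(0.5, 1) multiplier.
#' @param offset_taper off-peak magnitude as a fraction of the peak.
#' @param baseline_range range of gene-level mean log2 expression.
#' @param baseline_sd spread (log2) of cultivar baseline offsets. Baselines
#'   follow a dominant genotype axis, `b(g,c) = lambda_g * delta_c + e(g,c)`,
#'   with equally spaced unit-sd cultivar scores `delta`, gene loadings
#'   `lambda_g ~ Uniform(0.4, 1.6) * baseline_sd` and a bounded iid residual;
#'   this concentrates cultivar separation on PC1 (the structure seen in real
#'   multi-genotype bud data) while keeping zero-noise values clear of the
#'   TPM = 0 clip.
#' @param amplitude_range per-gene trajectory amplitude range (log2 units).
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param hormone_module archetype id whose mean expression drives ABA; must
#'   peak at the middle stage.
#' @param hormone_k linear ABA coupling coefficient (ng/g per log2 unit).
#' @param hormone_noise_sd additive ABA noise sd (ng/g).
#' @param ga3_base,ga7_base per-stage baseline levels (ng/g) for GA3/GA7;
#'   GA7 must peak at the last stage.
#' @param ga_cv lognormal coefficient of variation for the GA channels.
#' @param class_probs functional-class assignment probabilities.
#' @param term_size genes per planted annotation term.
#' @param background_terms number of random (null) annotation terms.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(n_genes = 2000,
                       cultivars = c(NG = "Low", NS = "Low", CM = "High", ZY = "High"),
                       stages = c("S1", "S2", "S3"),
                       reps = 3,
                       archetypes = default_archetypes(stages),
                       archetype_probs = c(0.2, 0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1),
                       divergent_modules = c(A1 = "S3", A2 = "S3", A3 = "S1",
                                             A4 = "S1", A5 = "S2", A6 = "S2"),
                       divergent_fraction = 0.65,
                       offset_peak = 0.8,
                       offset_taper = 0.25,
                       baseline_range = c(6, 10),
                       baseline_sd = 1.5,
                       amplitude_range = c(0.5, 2),
                       noise_sd = 0.2,
                       hormone_module = "A7",
                       hormone_k = 20,
                       hormone_noise_sd = 5,
                       ga3_base = NULL,
                       ga7_base = NULL,
                       ga_cv = 0.15,
                       class_probs = c("TF" = 0.08, "kinase-related" = 0.07,
                                       "hormone-associated" = 0.06,
                                       "chromatin/RNA" = 0.05, "other" = 0.74),
                       term_size = 40,
                       background_terms = 20,
                       seed = 1) {
  S <- length(stages)
  if (is.null(ga3_base)) ga3_base <- 4 + 2 * (seq_len(S) %% 2)
  if (is.null(ga7_base)) ga7_base <- c(rep(2.5, S - 1) + 0.5 * seq_len(S - 1), 9)
  spec <- structure(
    list(n_genes = n_genes, cultivars = cultivars, stages = stages, reps = reps,
         archetypes = archetypes, archetype_probs = archetype_probs,
         divergent_modules = divergent_modules,
         divergent_fraction = divergent_fraction,
         offset_peak = offset_peak, offset_taper = offset_taper,
         baseline_range = baseline_range, baseline_sd = baseline_sd,
         amplitude_range = amplitude_range, noise_sd = noise_sd,
         hormone_module = hormone_module, hormone_k = hormone_k,
         hormone_noise_sd = hormone_noise_sd,
         ga3_base = ga3_base, ga7_base = ga7_base, ga_cv = ga_cv,
         class_probs = class_probs, term_size = term_size,
         background_terms = background_terms, seed = seed),
    class = "truth_spec")
  validate_truth_spec(spec)
}

#' @rdname truth_spec
#' @param spec a `truth_spec` object.
#' @export
validate_truth_spec <- function(spec) {
  abort_if(!is.numeric(spec$n_genes) || spec$n_genes < 1, "n_genes must be positive")
  abort_if(!is.numeric(spec$reps) || spec$reps < 1, "reps must be positive")
  abort_if(length(spec$stages) < 2, "need at least two stages")
  abort_if(is.null(names(spec$cultivars)) ||
             !all(spec$cultivars %in% c("Low", "High")),
           "cultivars must be a named vector with values 'Low'/'High'")
  arch <- spec$archetypes
  abort_if(is.null(rownames(arch)) || ncol(arch) != length(spec$stages),
           "archetypes must be a named matrix with one column per stage")
  mu <- rowMeans(arch)
  sds <- apply(arch, 1, stats::sd)
  abort_if(any(abs(mu) > 1e-8) || any(abs(sds - 1) > 1e-8),
           "each archetype must have zero mean and unit sd over stages")
  abort_if(length(spec$archetype_probs) != nrow(arch),
           "archetype_probs must have one entry per archetype")
  abort_if(abs(sum(spec$archetype_probs) - 1) > 1e-9,
           "archetype_probs must sum to 1")
  if (length(spec$divergent_modules)) {
    abort_if(is.null(names(spec$divergent_modules)) ||
               !all(names(spec$divergent_modules) %in% rownames(arch)),
             "divergent_modules must be named by archetype id")
    abort_if(!all(spec$divergent_modules %in% spec$stages),
             "divergent module peak stages must be stage labels")
    abort_if(!all(is.finite(c(spec$offset_peak, spec$offset_taper))),
             "planted offsets must be finite")
  }
  abort_if(length(spec$hormone_module) != 1 ||
             !spec$hormone_module %in% rownames(arch),
           "hormone_module must name exactly one archetype")
  abort_if(!setequal(names(spec$class_probs), CLASS_VOCAB) ||
             abs(sum(spec$class_probs) - 1) > 1e-9,
           "class_probs must cover the class vocabulary and sum to 1")
  spec
}

reference_design <- function(spec) {
  grid <- expand.grid(replicate = seq_len(spec$reps),
                      stage = spec$stages,
                      cultivar = names(spec$cultivars),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("cultivar", "stage", "replicate")]
  grid <- grid[order(match(grid$cultivar, names(spec$cultivars)),
                     match(grid$stage, spec$stages), grid$replicate), ]
  design <- data.frame(
    sample_id = paste0(grid$cultivar, "_", grid$stage, "_r", grid$replicate),
    cultivar = grid$cultivar,
    stage = grid$stage,
    replicate = grid$replicate,
    cr_group = unname(spec$cultivars[grid$cultivar]),
    stringsAsFactors = FALSE)
  validate_design(design)
}

#' Generate a synthetic stage-resolved expression dataset with planted truth
#'
#' Per gene `g` of archetype `a`, the log2(TPM+1) value for cultivar `c`,
#' stage `s`, replicate `r` is
#' `baseline(g,c) + amplitude(g) * archetype_a(s) + offset(g) * window(s) +
#' Normal(0, noise_sd)`, where the divergence term applies to High-CR
#' cultivars of offset-carrier genes only and `window` is +1 at the planted
#' peak stage and `-offset_taper` elsewhere. TPM = 2^x - 1, clipped at 0.
#'
#' @param spec a [truth_spec()].
#' @return list of class `chill_dataset` with elements `tpm` (genes x samples
#'   matrix), `design`, `hormones` (long table), `annotations` (terms +
#'   classes), `truth` (per-gene archetype, planted offset, peak stage,
#'   class), and `spec`.
#' @export
generate_dataset <- function(spec) {
  spec <- validate_truth_spec(spec)
  design <- reference_design(spec)
  n <- as.integer(spec$n_genes)
  arch_ids <- rownames(spec$archetypes)

  with_seed(spec$seed, {
    genes <- sprintf("G%05d", seq_len(n))
    archetype <- sample(arch_ids, n, replace = TRUE, prob = spec$archetype_probs)
    mu <- stats::runif(n, spec$baseline_range[1], spec$baseline_range[2])
    # Cultivar baselines follow a dominant genotype axis plus a bounded iid
    # residual. The per-cultivar axis scores are centered within each CR
    # group so the genotype background is orthogonal to the High-Low
    # contrast: background separates cultivars (PC1) without adding a
    # constant offset to the CR-group difference.
    n_cv <- length(spec$cultivars)
    delta <- numeric(n_cv)
    groups <- unique(spec$cultivars)
    for (i in seq_along(groups)) {
      idx <- which(spec$cultivars == groups[i])
      delta[idx] <- (seq_along(idx) - (length(idx) + 1) / 2) * 1.6 / i
    }
    delta <- delta / stats::sd(delta)
    lambda <- stats::runif(n, 0.4, 1.6) * spec$baseline_sd
    resid_half <- 0.15 * spec$baseline_sd
    b <- lambda %o% delta +
      matrix(stats::runif(n * n_cv, -resid_half, resid_half), nrow = n)
    dimnames(b) <- list(genes, names(spec$cultivars))
    amp <- stats::runif(n, spec$amplitude_range[1], spec$amplitude_range[2])
    carrier <- archetype %in% names(spec$divergent_modules) &
      stats::runif(n) < spec$divergent_fraction
    offset <- numeric(n)
    offset[carrier] <- spec$offset_peak * stats::runif(sum(carrier), 0.5, 1)
    peak_stage <- rep(NA_character_, n)
    if (any(carrier)) {
      peak_stage[carrier] <- unname(spec$divergent_modules[archetype[carrier]])
    }

    # per-gene stage windows: +1 at the planted peak, -taper elsewhere
    window <- matrix(0, nrow = n, ncol = length(spec$stages),
                     dimnames = list(genes, spec$stages))
    if (any(carrier)) {
      window[carrier, ] <- -spec$offset_taper
      window[cbind(which(carrier), match(peak_stage[carrier], spec$stages))] <- 1
    }

    s_idx <- match(as.character(design$stage), spec$stages)
    c_idx <- match(design$cultivar, names(spec$cultivars))
    high <- design$cr_group == "High"
    logx <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(genes, design$sample_id))
    for (j in seq_len(nrow(design))) {
      x <- mu + b[, c_idx[j]] + amp * spec$archetypes[archetype, s_idx[j]]
      if (high[j]) x <- x + offset * window[, s_idx[j]]
      logx[, j] <- x
    }
    if (spec$noise_sd > 0) {
      logx <- logx + matrix(stats::rnorm(length(logx), 0, spec$noise_sd),
                            nrow = n)
    }
    tpm <- pmax(2^logx - 1, 0)
    attr(tpm, "design") <- design

    classes <- sample(names(spec$class_probs), n, replace = TRUE,
                      prob = spec$class_probs)
    truth <- data.frame(gene = genes, archetype = archetype,
                        amplitude = amp, carrier = carrier,
                        offset = offset, peak_stage = peak_stage,
                        class = classes, stringsAsFactors = FALSE)

    dataset <- structure(
      list(tpm = tpm, design = design, truth = truth, spec = spec),
      class = "chill_dataset")
    dataset$hormones <- generate_hormones(dataset, spec)
    # planted terms cannot exceed the smallest archetype actually drawn
    term_size <- max(1, min(spec$term_size,
                            floor(0.8 * min(table(truth$archetype)))))
    ann <- generate_annotations(truth, term_size = term_size,
                                background_terms = spec$background_terms,
                                seed = NULL)
    ann$classes <- data.frame(gene = genes, class = classes,
                              stringsAsFactors = FALSE)
    dataset$annotations <- ann
    dataset
  })
}

#' Simulate hormone measurements coupled to the expression data
#'
#' ABA is a positive linear function of the mean log2(TPM+1) of the hormone
#' module's genes in each sample (so it inherits that archetype's mid-stage
#' peak), GA7 rises sharply at the last stage, and GA3 varies by stage.
#'
#' @param dataset a `chill_dataset` (needs `tpm`, `design`, `truth`).
#' @param spec the generating [truth_spec()].
#' @param seed optional seed; `NULL` continues the caller's RNG stream (used
#'   inside [generate_dataset()]).
#' @return long-format hormone table (sample_id, hormone, value).
#' @export
generate_hormones <- function(dataset, spec, seed = NULL) {
  module_genes <- dataset$truth$gene[dataset$truth$archetype == spec$hormone_module]
  abort_if(length(module_genes) == 0, "hormone module contains no genes")
  run <- function() {
    design <- dataset$design
    m <- colMeans(log2p1(dataset$tpm[module_genes, , drop = FALSE]))
    aba <- spec$hormone_k * m +
      stats::rnorm(nrow(design), 0, spec$hormone_noise_sd)
    aba <- pmax(aba, 1e-3)
    s_idx <- match(as.character(design$stage), spec$stages)
    lognoise <- function() exp(stats::rnorm(nrow(design), 0, spec$ga_cv))
    ga3 <- spec$ga3_base[s_idx] * lognoise()
    ga7 <- spec$ga7_base[s_idx] * lognoise()
    data.frame(
      sample_id = rep(design$sample_id, 3),
      hormone = rep(c("ABA", "GA3", "GA7"), each = nrow(design)),
      value = c(aba, ga3, ga7),
      stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate an annotation table with one planted-enriched term per archetype
#'
#' Each archetype gets a term assigned to `term_size` of its genes (so the
#' term is strongly over-represented in the recovered cluster), plus
#' `background_terms` null terms assigned to genes uniformly at random.
#'
#' @param truth per-gene truth table from [generate_dataset()].
#' @param term_size genes per planted term; must not exceed the smallest
#'   archetype.
#' @param background_terms number of random terms.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @return list with `terms` (gene/term/layer) and `term_desc`.
#' @export
generate_annotations <- function(truth, term_size = 40, background_terms = 20,
                                 seed = NULL) {
  run <- function() {
    arch_ids <- sort(unique(truth$archetype))
    rows <- list()
    for (a in arch_ids) {
      pool <- truth$gene[truth$archetype == a]
      abort_if(term_size > length(pool),
               "term_size (", term_size, ") exceeds archetype ", a,
               " size (", length(pool), ")")
      rows[[a]] <- data.frame(gene = sample(pool, term_size),
                              term = paste0("PT_", a),
                              layer = "planted", stringsAsFactors = FALSE)
    }
    if (background_terms > 0) {
      for (i in seq_len(background_terms)) {
        sz <- sample(seq(min(10, nrow(truth)), min(60, nrow(truth))), 1)
        rows[[paste0("bg", i)]] <- data.frame(
          gene = sample(truth$gene, sz),
          term = sprintf("BG_%02d", i),
          layer = "background", stringsAsFactors = FALSE)
      }
    }
    terms <- do.call(rbind, rows)
    rownames(terms) <- NULL
    desc <- unique(terms$term)
    list(terms = terms,
         term_desc = data.frame(
           term = desc,
           description = ifelse(grepl("^PT_", desc),
                                paste("planted term for archetype",
                                      sub("^PT_", "", desc)),
                                "random background term"),
           stringsAsFactors = FALSE))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write a synthetic dataset to TSV files
#'
#' Writes the same formats the readers consume: `expression.tsv`,
#' `samples.tsv`, `hormones.tsv`, `annotations.tsv`, `classes.tsv`, plus the
#' generative truth in `truth.tsv`.
#'
#' @param dataset a `chill_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- data.frame(gene = rownames(dataset$tpm), dataset$tpm,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  design <- dataset$design
  design$stage <- as.character(design$stage)
  write_tsv(design, file.path(dir, "samples.tsv"))
  write_tsv(dataset$hormones, file.path(dir, "hormones.tsv"))
  write_tsv(dataset$annotations$terms, file.path(dir, "annotations.tsv"))
  write_tsv(dataset$annotations$classes, file.path(dir, "classes.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
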