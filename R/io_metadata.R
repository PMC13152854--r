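#' Validate a sample design table
#'
#' A sample design describes one RNA-seq library per row: its cultivar, the
#' endodormancy stage at which the bud was sampled, the biological replicate
#' number and the chilling-requirement (CR) group of the cultivar. Stage
#' labels are free strings whose ordering is given by first appearance in the
#' table (the reference design uses S1 < S2 < S3).
#'
#' @param design data.frame with columns `sample_id`, `cultivar`, `stage`,
#'   `replicate`, `cr_group`.
#' @return The design with `stage` as an ordered factor (levels in order of
#'   first appearance) and an attached `cr_map` attribute (cultivar -> group).
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "cultivar", "stage", "replicate", "cr_group")
  missing_cols <- setdiff(need, names(design))
  abort_if(length(missing_cols) > 0,
           "design is missing column(s): ", paste(missing_cols, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  dup <- design$sample_id[duplicated(design$sample_id)]
  abort_if(length(dup) > 0, "duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad_grp <- setdiff(unique(design$cr_group), c("Low", "High"))
  abort_if(length(bad_grp) > 0,
           "unknown cr_group label(s): ", paste(bad_grp, collapse = ", "),
           " (expected 'Low' or 'High')")
  # each cultivar must map to exactly one CR group
  map <- unique(design[, c("cultivar", "cr_group")])
  multi <- map$cultivar[duplicated(map$cultivar)]
  abort_if(length(multi) > 0,
           "cultivar(s) assigned to more than one CR group: ",
           paste(unique(multi), collapse = ", "))
  rep_num <- suppressWarnings(as.integer(design$replicate))
  abort_if(anyNA(rep_num) || any(rep_num < 1),
           "replicate must be a positive integer for every sample")
  design$replicate <- rep_num
  stage_levels <- unique(as.character(design$stage))
  abort_if(length(stage_levels) < 2, "design must contain at least two stages")
  design$stage <- factor(as.character(design$stage), levels = stage_levels, ordered = TRUE)
  cr_map <- stats::setNames(map$cr_group, map$cultivar)
  attr(design, "cr_map") <- cr_map
  design
}

#' Read a sample design table from TSV
#'
#' @param path TSV file with columns `sample_id`, `cultivar`, `stage`,
#'   `replicate`, `cr_group`; lines starting with `#` are ignored.
#' @param stages optional vector of allowed stage labels; labels outside this
#'   set raise an error.
#' @return validated design (see [validate_design()]).
#' @export
read_sample_table <- function(path, stages = NULL) {
  design <- read_tsv(path)
  design <- validate_design(design)
  if (!is.null(stages)) {
    bad <- setdiff(levels(design$stage), stages)
    abort_if(length(bad) > 0,
             "unknown stage label(s) in ", path, ": ", paste(bad, collapse = ", "),
             " (allowed: ", paste(stages, collapse = ", "), ")")
  }
  design
}

#' Read a gene x sample TPM matrix
#'
#' The file must be tab-separated with gene ids in the first column and one
#' column per sample. Columns are reordered to match the design; samples
#' present in the design but absent from the file are an error, extra columns
#' are dropped with a warning.
#'
#' @param path TSV path.
#' @param design validated sample design.
#' @return numeric matrix (genes x samples, TPM scale) with the design
#'   attached as attribute `design`.
#' @export
read_expression <- function(path, design) {
  design <- validate_design(design)
  tab <- read_tsv(path)
  abort_if(ncol(tab) < 2, "expression file has no sample columns: ", path)
  genes <- as.character(tab[[1]])
  dup <- genes[duplicated(genes)]
  abort_if(length(dup) > 0, "duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  missing <- setdiff(design$sample_id, names(tab)[-1])
  abort_if(length(missing) > 0,
           "expression file is missing sample(s) present in the design: ",
           paste(missing, collapse = ", "))
  extra <- setdiff(names(tab)[-1], design$sample_id)
  if (length(extra) > 0) {
    warning("dropping ", length(extra), " expression column(s) absent from the design: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  vals <- tab[, design$sample_id, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) | is.na(vals[[j]]))
    abort_if(length(bad) > 0,
             "non-numeric expression value for gene '", genes[bad[1]],
             "', sample '", names(vals)[j], "'")
    neg <- which(v < 0)
    abort_if(length(neg) > 0,
             "negative TPM (", v[neg[1]], ") for gene '", genes[neg[1]],
             "', sample '", names(vals)[j], "'")
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  attr(m, "design") <- design
  m
}

#' Read a long-format hormone table
#'
#' @param path TSV with columns `sample_id`, `hormone`, `value` (ng/g).
#' @param design validated design; hormone sample ids must be a subset of the
#'   design's.
#' @return data.frame in long format.
#' @export
read_hormone_table <- function(path, design) {
  design <- validate_design(design)
  tab <- read_tsv(path)
  need <- c("sample_id", "hormone", "value")
  abort_if(!all(need %in% names(tab)),
           "hormone table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(tab$sample_id), design$sample_id)
  abort_if(length(unknown) > 0,
           "hormone table references sample(s) absent from the design: ",
           paste(unknown, collapse = ", "))
  tab$value <- suppressWarnings(as.numeric(tab$value))
  abort_if(anyNA(tab$value) || any(tab$value <= 0),
           "hormone values must be positive numbers")
  tab
}

#' Pivot a long hormone table to a sample x hormone matrix
#'
#' @param hormones long-format table from [read_hormone_table()].
#' @param design validated design giving the sample order.
#' @return numeric matrix, rows in design order, one column per hormone.
#' @export
hormones_wide <- function(hormones, design) {
  design <- validate_design(design)
  hs <- sort(unique(hormones$hormone))
  m <- matrix(NA_real_, nrow = nrow(design), ncol = length(hs),
              dimnames = list(design$sample_id, hs))
  idx <- cbind(match(hormones$sample_id, design$sample_id),
               match(hormones$hormone, hs))
  m[idx] <- hormones$value
  m
}

#' Read gene -> term annotations and gene -> functional class labels
#'
#' @param path TSV with columns `gene`, `term` (one pair per row) and
#'   optionally `layer` (annotation layer, e.g. GO/IPR/KEGG) and `description`.
#' @param classes_path optional TSV with columns `gene`, `class`; classes must
#'   come from the fixed vocabulary `TF`, `kinase-related`,
#'   `hormone-associated`, `chromatin/RNA`, `other`. Genes absent from this
#'   file default to class `other` (see [gene_classes()]).
#' @return list with elements `terms` (data.frame gene/term/layer) and
#'   `classes` (data.frame gene/class).
#' @export
read_annotation_table <- function(path, classes_path = NULL) {
  tab <- read_tsv(path)
  abort_if(nrow(tab) == 0, "annotation file is empty: ", path)
  abort_if(!all(c("gene", "term") %in% names(tab)),
           "annotation file must have columns 'gene' and 'term'")
  bad <- which(is.na(tab$gene) | tab$gene == "" | is.na(tab$term) | tab$term == "")
  abort_if(length(bad) > 0, "malformed annotation row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(tab$layer)) tab$layer <- "default"
  classes <- data.frame(gene = character(), class = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(classes_path)) {
    cls <- read_tsv(classes_path)
    abort_if(!all(c("gene", "class") %in% names(cls)),
             "class file must have columns 'gene' and 'class'")
    bad_cls <- setdiff(unique(cls$class), CLASS_VOCAB)
    abort_if(length(bad_cls) > 0,
             "unknown functional class label(s): ", paste(bad_cls, collapse = ", "),
             " (allowed: ", paste(CLASS_VOCAB, collapse = ", "), ")")
    classes <- cls[, c("gene", "class")]
  }
  list(terms = tab[, intersect(c("gene", "term", "layer", "description"), names(tab))],
       classes = classes)
}

#' Look up functional classes with the `other` default
#'
#' @param annotation list from [read_annotation_table()] (or the `annotations`
#'   element of a synthetic dataset).
#' @param genes character vector of gene ids.
#' @return named character vector of classes; genes without a class row are
#'   labelled `"other"`.
#' @export
gene_classes <- function(annotation, genes) {
  out <- rep("other", length(genes))
  names(out) <- genes
  cls <- annotation$classes
  if (!is.null(cls) && nrow(cls) > 0) {
    hit <- match(genes, cls$gene)
    out[!is.na(hit)] <- cls$class[hit[!is.na(hit)]]
  }
  out
}
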