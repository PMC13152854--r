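# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Tab-separated writer; '#'-prefixed header lines carry run provenance.
write_tsv <- function(x, path, header_lines = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  abort_if(!file.exists(path), "file not found: ", path)
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# Sample standard deviation matrix helpers -----------------------------------

row_sds <- function(m) {
  n <- ncol(m)
  abort_if(n < 2, "need at least two columns to compute a standard deviation")
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

# Functional-class vocabulary used throughout (candidate plausibility gate).
CLASS_VOCAB <- c("TF", "kinase-related", "hormone-associated", "chromatin/RNA", "other")
PLAUSIBLE_CLASSES <- setdiff(CLASS_VOCAB, "other")
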