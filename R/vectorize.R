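#' Pattern weight
#'
#' IDF-style weight of a mined pattern:
#' `W = PatLength * log2(DBSize / PatSup)`. Longer patterns weigh more
#' (linearly); patterns found in many sequences weigh less, down to exactly 0
#' for a pattern present in every sequence, which carries no discriminative
#' information. The wildcard counts toward the length.
#'
#' @param pat_length pattern length (residues plus wildcards), >= 1.
#' @param db_size number of sequences in the database, >= 1.
#' @param pat_sup absolute support, in `[1, db_size]`.
#' @return non-negative numeric weight.
#' @export
pattern_weight <- function(pat_length, db_size, pat_sup) {
  if (any(pat_length < 1)) stop("pat_length must be >= 1")
  if (any(pat_sup < 1)) stop("pat_sup must be >= 1")
  if (any(pat_sup > db_size)) stop("pat_sup cannot exceed db_size")
  pat_length * log2(db_size / pat_sup)
}

#' Build a feature space from mined patterns
#'
#' The ordered closed-pattern set plus its weight vector form the coordinate
#' system in which sequences become pattern vectors.
#'
#' @param result a `pattern_set` from [mine_closed_patterns()].
#' @return an object of class `feature_space` with fields `patterns`
#'   (the `pattern_set`), `weights`, `db_size`.
#' @export
build_feature_space <- function(result) {
  stopifnot(inherits(result, "pattern_set"))
  dbs <- attr(result, "db_size")
  if (nrow(result) == 0L) {
    warning("empty pattern set; feature space has dimension 0")
    w <- numeric(0)
  } else {
    w <- pattern_weight(result$length, dbs, result$support)
  }
  structure(list(patterns = result, weights = w, db_size = dbs),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("feature_space: %d pattern(s), db_size %d\n",
              nrow(x$patterns), x$db_size))
  if (length(x$weights))
    cat(sprintf("  weights: min %.3f, median %.3f, max %.3f\n",
                min(x$weights), stats::median(x$weights), max(x$weights)))
  invisible(x)
}

#' Convert sequences to pattern vectors
#'
#' Each sequence gets one coordinate per feature-space pattern: in `binary`
#' mode 1 when the sequence contains at least one occurrence of the pattern
#' (0 otherwise), in `weighted` mode the pattern's weight instead of 1.
#' Membership is decided by direct pattern scanning, so held-out sequences
#' that took no part in mining can be vectorized too. Within-sequence
#' multiplicity is ignored, consistent with sequence-level support.
#'
#' @param seqs a [seq_set()].
#' @param space a [build_feature_space()] result.
#' @param mode `"weighted"` (default) or `"binary"`.
#' @return numeric matrix, rows = sequence ids, columns = pattern strings,
#'   with attribute `mode`. All-zero rows are kept but trigger a warning.
#' @export
vectorize_sequences <- function(seqs, space, mode = c("weighted", "binary")) {
  stopifnot(inherits(seqs, "seq_set"), inherits(space, "feature_space"))
  mode <- match.arg(mode)
  pat <- space$patterns$pattern
  m <- match_patterns_cpp(pat, seqs$seq)
  m <- matrix(as.numeric(m), nrow = db_size(seqs),
              dimnames = list(seqs$id, pat))
  if (mode == "weighted" && length(pat))
    m <- sweep(m, 2L, space$weights, "*")
  zero <- rowSums(m) == 0
  if (any(zero) && length(pat))
    warning("all-zero pattern vector(s) for: ",
            paste(seqs$id[zero], collapse = ", "))
  attr(m, "mode") <- mode
  m
}

#' Export a pattern-vector matrix and its weights as TSV
#'
#' @param m matrix from [vectorize_sequences()].
#' @param path output path for the matrix (rows = sequence ids).
#' @param weights_path optional sidecar path for the per-pattern weights.
#' @param space the [build_feature_space()] the matrix was built from
#'   (required when `weights_path` is given).
#' @return `path`, invisibly.
#' @export
write_vector_tsv <- function(m, path, weights_path = NULL, space = NULL) {
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(weights_path)) {
    stopifnot(inherits(space, "feature_space"))
    utils::write.table(data.frame(pattern = space$patterns$pattern,
                                  weight = space$weights),
                       weights_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
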