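#' Mining parameters
#'
#' Bundles and validates the three mining knobs. `min_support` may be a
#' fraction in (0, 1) — resolved against the database size as
#' `max(2, ceiling(min_support * db_size))`, since a pattern confined to a
#' single sequence carries no comparative signal — or an absolute integer
#' count (>= 1) of supporting sequences, used as given. `min_non_wc` is the minimum number of
#' concrete (non-wildcard) residues a reported pattern must contain;
#' `max_wc` bounds the length of any run of consecutive wildcards.
#'
#' @param min_support fraction in (0, 1] or absolute integer >= 1.
#' @param min_non_wc integer >= 1.
#' @param max_wc integer >= 0.
#' @return an object of class `mining_params`.
#' @export
mining_params <- function(min_support = 0.03, min_non_wc = 2L, max_wc = 2L) {
  if (!is.numeric(min_support) || length(min_support) != 1L || min_support <= 0)
    stop("min_support must be a positive number")
  if (min_support >= 1 && min_support != round(min_support))
    stop("absolute min_support must be an integer")
  min_non_wc <- as.integer(min_non_wc)
  max_wc <- as.integer(max_wc)
  if (is.na(min_non_wc) || min_non_wc < 1L) stop("min_non_wc must be >= 1")
  if (is.na(max_wc) || max_wc < 0L) stop("max_wc must be >= 0")
  structure(list(min_support = min_support, min_non_wc = min_non_wc,
                 max_wc = max_wc),
            class = "mining_params")
}

#' Resolve the absolute support threshold
#'
#' @param min_support fractional or absolute support (see [mining_params()]).
#' @param db_size number of sequences in the database.
#' @return integer absolute threshold.
#' @export
resolve_support <- function(min_support, db_size) {
  if (min_support < 1) {
    max(2L, as.integer(ceiling(min_support * db_size)))
  } else {
    as.integer(min_support)
  }
}

#' Mine closed frequent sequential patterns
#'
#' Discovers every closed frequent pattern over the residue alphabet plus a
#' single-residue wildcard (rendered `"."`). A pattern occurs in a sequence
#' when it matches contiguously, the wildcard standing for exactly one
#' arbitrary residue; support counts supporting sequences, not occurrences.
#' Reported patterns start and end with residues, contain at least
#' `min_non_wc` residues, have no wildcard run longer than `max_wc`, meet the
#' support threshold, and are closed: no admissible proper super-pattern
#' (extension on either flank or specialization of a wildcard to a residue)
#' has the same support. Output order is lexicographic with the wildcard
#' sorting after all residues.
#'
#' @param seqs a [seq_set()].
#' @param min_support,min_non_wc,max_wc see [mining_params()].
#' @param params alternatively, a ready-made [mining_params()] object.
#' @return a `pattern_set`: a `data.frame` with columns `pattern`, `length`,
#'   `n_residues`, `support` and list-column `supporting_ids`, carrying
#'   attributes `params` (with the resolved absolute threshold) and
#'   `db_size`.
#' @export
mine_closed_patterns <- function(seqs, min_support = 0.03, min_non_wc = 2L,
                                 max_wc = 2L, params = NULL) {
  stopifnot(inherits(seqs, "seq_set"))
  if (db_size(seqs) == 0L) stop("empty sequence set")
  if (is.null(params))
    params <- mining_params(min_support, min_non_wc, max_wc)
  thr <- resolve_support(params$min_support, db_size(seqs))
  if (thr > db_size(seqs)) {
    warning(sprintf("resolved support threshold (%d) exceeds the number of sequences (%d); no pattern can be frequent",
                    thr, db_size(seqs)))
    return(empty_pattern_set(params, thr, db_size(seqs)))
  }
  raw <- mine_patterns_cpp(seqs$seq, thr, params$min_non_wc, params$max_wc)
  pattern_set(raw$pattern, raw$support,
              lapply(raw$supporting, function(i) seqs$id[i]),
              params, thr, db_size(seqs))
}

pattern_set <- function(patterns, supports, supporting_ids, params, thr, dbs) {
  ord <- order(pattern_sort_key(patterns), method = "radix")
  df <- data.frame(pattern = patterns[ord],
                   length = nchar(patterns[ord]),
                   n_residues = nchar(gsub(".", "", patterns[ord], fixed = TRUE)),
                   support = as.integer(supports[ord]),
                   stringsAsFactors = FALSE)
  df$supporting_ids <- I(unname(supporting_ids[ord]))
  params$threshold <- as.integer(thr)
  attr(df, "params") <- params
  attr(df, "db_size") <- as.integer(dbs)
  class(df) <- c("pattern_set", "data.frame")
  df
}

empty_pattern_set <- function(params, thr, dbs) {
  pattern_set(character(0), integer(0), list(), params, thr, dbs)
}

# Sort key: wildcard after every residue ('.' -> '~' > 'Z').
pattern_sort_key <- function(p) chartr(".", "~", p)

#' @export
print.pattern_set <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("pattern_set: %d closed pattern(s) from %d sequence(s)\n",
              nrow(x), attr(x, "db_size")))
  cat(sprintf("  support threshold %d (min_support = %s), min_non_wc = %d, max_wc = %d\n",
              p$threshold, format(p$min_support), p$min_non_wc, p$max_wc))
  if (nrow(x)) {
    show <- utils::head(x, 10L)
    print.data.frame(data.frame(pattern = show$pattern,
                                support = show$support), row.names = FALSE)
    if (nrow(x) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Grow a pattern by one item over a projected database
#'
#' One step of projected-database pattern growth: append a residue or the
#' wildcard `"."` to a pattern and advance each recorded occurrence end
#' position where the appended item matches (the wildcard matches any
#' residue). Sequences with no surviving occurrence are dropped, so the
#' projection's support can only shrink. End positions are 1-based indices of
#' the position just after the last matched item.
#'
#' @param pattern current pattern string (possibly empty).
#' @param pdb named list: sequence id -> integer vector of end positions.
#' @param item single residue character or `"."`.
#' @param seqs a [seq_set()].
#' @param max_wc wildcard-run limit; appending must not exceed it.
#' @return list with elements `pattern` and `pdb`.
#' @export
grow_pattern <- function(pattern, pdb, item, seqs, max_wc = 2L) {
  stopifnot(inherits(seqs, "seq_set"), nchar(item) == 1L)
  if (item == ".") {
    trail <- nchar(pattern) - nchar(sub("\\.*$", "", pattern))
    if (trail + 1L > max_wc)
      stop("appending a wildcard would exceed max_wc = ", max_wc)
  }
  out <- list()
  for (id in names(pdb)) {
    s <- seqs$seq[match(id, seqs$id)]
    ends <- pdb[[id]]
    ends <- ends[ends <= nchar(s)]
    if (item == ".") {
      keep <- ends
    } else {
      keep <- ends[substring(s, ends, ends) == item]
    }
    if (length(keep)) out[[id]] <- keep + 1L
  }
  list(pattern = paste0(pattern, item), pdb = out)
}

#' Test whether a frequent pattern is closed
#'
#' A pattern is closed when no admissible proper super-pattern has the same
#' support. It suffices to examine one-step supers: prepending a residue
#' followed by up to `max_wc` wildcards, appending up to `max_wc` wildcards
#' followed by a residue, and replacing any single wildcard by a residue.
#' Supports are recomputed by direct string scanning, independently of the
#' miner.
#'
#' @param pattern admissible pattern string (wildcard `"."`).
#' @param seqs a [seq_set()].
#' @param max_wc wildcard-run limit defining the admissible space.
#' @return `TRUE` if closed.
#' @export
is_closed_pattern <- function(pattern, seqs, max_wc = 2L) {
  stopifnot(inherits(seqs, "seq_set"))
  check_admissible(pattern, max_wc)
  sup <- pattern_support(pattern, seqs)
  if (sup == 0L) stop("pattern does not occur in the sequence set")
  alpha <- sort(unique(strsplit(paste(seqs$seq, collapse = ""), "")[[1]]))
  for (j in 0:max_wc) {
    gap <- strrep(".", j)
    for (r in alpha) {
      if (pattern_support(paste0(r, gap, pattern), seqs) == sup) return(FALSE)
      if (pattern_support(paste0(pattern, gap, r), seqs) == sup) return(FALSE)
    }
  }
  chars <- strsplit(pattern, "")[[1]]
  for (k in which(chars == ".")) {
    for (r in alpha) {
      spec <- chars; spec[k] <- r
      if (pattern_support(paste(spec, collapse = ""), seqs) == sup)
        return(FALSE)
    }
  }
  TRUE
}

check_admissible <- function(pattern, max_wc) {
  if (!nzchar(pattern)) stop("empty pattern")
  chars <- strsplit(pattern, "")[[1]]
  if (chars[1] == "." || chars[length(chars)] == ".")
    stop("pattern terminals must be residues")
  runs <- rle(chars == ".")
  if (any(runs$lengths[runs$values] > max_wc))
    stop("wildcard run exceeds max_wc = ", max_wc)
  invisible(TRUE)
}

# Support by direct (regex) scan; '.' is the wildcard and residues are
# letters, so the pattern string is its own regular expression.
pattern_support <- function(pattern, seqs) {
  sum(grepl(pattern, seqs$seq))
}

#' Brute-force closed-pattern enumeration (test oracle)
#'
#' Enumerates admissible strings over the observed alphabet plus the
#' wildcard, level by level up to `max_len`, counting support by direct
#' regex scanning and pruning only prefixes that already fall below the
#' support threshold (supers of infrequent patterns are infrequent).
#' Closedness is then decided by pairwise containment among equal-support
#' frequent patterns. Intended for tiny inputs; equals
#' [mine_closed_patterns()] whenever every frequent pattern fits in
#' `max_len`.
#'
#' @inheritParams mine_closed_patterns
#' @param max_len maximum pattern length to enumerate; defaults to the
#'   longest sequence.
#' @param max_candidates guard on the enumeration frontier size.
#' @return a `pattern_set`, ordered as in [mine_closed_patterns()].
#' @export
enumerate_patterns_bruteforce <- function(seqs, min_support = 0.03,
                                          min_non_wc = 2L, max_wc = 2L,
                                          max_len = NULL,
                                          max_candidates = 200000L) {
  stopifnot(inherits(seqs, "seq_set"))
  if (db_size(seqs) == 0L) stop("empty sequence set")
  params <- mining_params(min_support, min_non_wc, max_wc)
  thr <- resolve_support(params$min_support, db_size(seqs))
  if (thr > db_size(seqs)) {
    warning("resolved support threshold exceeds the number of sequences")
    return(empty_pattern_set(params, thr, db_size(seqs)))
  }
  if (is.null(max_len)) max_len <- max(nchar(seqs$seq))
  alpha <- sort(unique(strsplit(paste(seqs$seq, collapse = ""), "")[[1]]))

  freq <- character(0)   # frequent residue-terminal patterns (any non_wc)
  fsup <- integer(0)
  fids <- list()
  frontier <- character(0)
  for (r in alpha) {
    if (sum(grepl(r, seqs$seq, fixed = TRUE)) >= thr) frontier <- c(frontier, r)
  }
  repeat {
    keep <- logical(length(frontier))
    for (i in seq_along(frontier)) {
      p <- frontier[[i]]
      hits <- grepl(p, seqs$seq)
      if (sum(hits) >= thr) {
        keep[i] <- TRUE
        if (!endsWith(p, ".")) {
          freq <- c(freq, p)
          fsup <- c(fsup, sum(hits))
          fids <- c(fids, list(seqs$id[hits]))
        }
      }
    }
    frontier <- frontier[keep]
    if (!length(frontier) || nchar(frontier[[1]]) >= max_len) break
    ext <- character(0)
    for (p in frontier) {
      trail <- nchar(p) - nchar(sub("\\.*$", "", p))
      items <- if (trail < max_wc) c(alpha, ".") else alpha
      ext <- c(ext, paste0(p, items))
    }
    if (length(ext) > max_candidates)
      stop("brute-force candidate guard exceeded (", length(ext),
           " > ", max_candidates, ")")
    frontier <- ext
  }

  closed <- vapply(seq_along(freq), function(i) {
    same <- which(fsup == fsup[[i]])
    for (j in same) {
      if (j != i && is_subpattern(freq[[i]], freq[[j]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  sel <- closed & (nchar(gsub(".", "", freq, fixed = TRUE)) >= params$min_non_wc)
  pattern_set(freq[sel], fsup[sel], fids[sel], params, thr, db_size(seqs))
}

# TRUE when every occurrence of y implies an occurrence of x: x aligns into a
# window of y with x's residues matched exactly (x wildcards match anything,
# including y wildcards; an x residue over a y wildcard is NOT containment).
is_subpattern <- function(x, y) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx > ny) return(FALSE)
  xc <- strsplit(x, "")[[1]]
  yc <- strsplit(y, "")[[1]]
  for (o in 0:(ny - nx)) {
    if (all(xc == "." | xc == yc[o + seq_len(nx)])) return(TRUE)
  }
  FALSE
}

#' Write a pattern set as TSV
#'
#' Columns: `pattern` (wildcard rendered `"."`), `support`, `weight`
#' (`NA` unless a [build_feature_space()] weight vector is supplied),
#' `supporting_ids` (comma-separated). Rows keep the deterministic
#' lexicographic order of the pattern set.
#'
#' @param x a `pattern_set`.
#' @param path output path.
#' @param weights optional numeric vector aligned to the rows of `x`.
#' @return `path`, invisibly.
#' @export
write_pattern_tsv <- function(x, path, weights = NULL) {
  stopifnot(inherits(x, "pattern_set"))
  df <- data.frame(pattern = x$pattern,
                   support = x$support,
                   weight = if (is.null(weights)) NA_real_ else weights,
                   supporting_ids = vapply(x$supporting_ids, paste,
                                           character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
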