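#' Alignment-free phylogeny from closed sequential patterns
#'
#' The package's main entry point. Runs the full pipeline on a set of
#' unaligned sequences: mine closed frequent sequential patterns with
#' wildcards, weight them (`PatLength * log2(DBSize / PatSup)`), convert
#' every sequence into a pattern vector, compute the pairwise
#' Jensen-Shannon distance matrix over the normalized vectors, and build a
#' Neighbor-Joining tree. The whole pipeline is deterministic: identical
#' input and settings reproduce identical output byte for byte.
#'
#' The defaults (`min_support = 0.03`, `min_non_wc = 2`, `max_wc = 2`,
#' weighted vectors) are the divergent-sequence settings; for families of
#' highly similar sequences binary vectors (`mode = "binary"`) and a larger
#' support can work better. The support threshold is the method's most
#' sensitive parameter: the resolved absolute value is stored in the fit and
#' shown by `print()`.
#'
#' @param x a [seq_set()] or the path of a FASTA file.
#' @param min_support fractional (0,1] or absolute support threshold
#'   (see [mining_params()]).
#' @param min_non_wc minimum number of non-wildcard residues per pattern.
#' @param max_wc maximum run of consecutive wildcards.
#' @param mode `"weighted"` (default) or `"binary"` pattern vectors.
#' @param distance `"js"` (the Jensen-Shannon divergence itself, default) or
#'   `"sqrt-js"` (its square root, a metric).
#' @param alphabet alphabet for FASTA input (`"auto"` by default).
#' @return an object of class `pattree`: list with components `seqs`,
#'   `params` (resolved parameters incl. the absolute support threshold),
#'   `patterns` (a `pattern_set`), `space` (the `feature_space`), `vectors`
#'   (the pattern-vector matrix), `dist` (the distance matrix), `tree`
#'   (an unrooted `phylo`), `timings` (seconds per stage) and `call`.
#' @examples
#' sim <- simulate_family(n_leaves = 8, root_length = 120, seed = 42)
#' fit <- pattree(sim$seqs)
#' fit
#' rf_distance(fit$tree, sim$tree)
#' @export
pattree <- function(x, min_support = 0.03, min_non_wc = 2L, max_wc = 2L,
                    mode = c("weighted", "binary"),
                    distance = c("js", "sqrt-js"), alphabet = "auto") {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  seqs <- if (inherits(x, "seq_set")) x else read_fasta(x, alphabet)
  if (db_size(seqs) < 2L) stop("need at least 2 sequences")
  if (db_size(seqs) < 3L)
    warning("fewer than 3 sequences: the tree is a single edge")

  timings <- c(mine = 0, vectorize = 0, distance = 0, tree = 0)
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  patterns <- mine_closed_patterns(seqs, min_support, min_non_wc, max_wc)
  timings[["mine"]] <- tic() - t0
  if (nrow(patterns) == 0L)
    stop("no closed pattern satisfies the thresholds; ",
         "lower min_support or min_non_wc (divergent inputs need small ",
         "support values)")

  t0 <- tic()
  space <- build_feature_space(patterns)
  vectors <- vectorize_sequences(seqs, space, mode = mode)
  timings[["vectorize"]] <- tic() - t0

  t0 <- tic()
  d <- js_distance_matrix(vectors, sqrt = identical(distance, "sqrt-js"))
  timings[["distance"]] <- tic() - t0

  t0 <- tic()
  tree <- neighbor_joining(d)
  timings[["tree"]] <- tic() - t0

  params <- attr(patterns, "params")
  params$mode <- mode
  params$distance <- distance
  structure(list(seqs = seqs, params = params, patterns = patterns,
                 space = space, vectors = vectors, dist = d, tree = tree,
                 timings = timings, call = match.call()),
            class = "pattree")
}

#' @export
print.pattree <- function(x, ...) {
  p <- x$params
  cat("pattree fit\n")
  cat(sprintf("  sequences: %d (%s)\n", db_size(x$seqs), x$seqs$alphabet))
  cat(sprintf("  support threshold: %d of %d sequences (min_support = %s)\n",
              p$threshold, db_size(x$seqs), format(p$min_support)))
  cat(sprintf("  mining: min_non_wc = %d, max_wc = %d\n",
              p$min_non_wc, p$max_wc))
  cat(sprintf("  feature space: %d closed pattern(s), %s vectors\n",
              nrow(x$patterns), p$mode))
  cat(sprintf("  distances: %s, range [%.4f, %.4f]\n", p$distance,
              min(x$dist[upper.tri(x$dist)]), max(x$dist[upper.tri(x$dist)])))
  cat(sprintf("  tree: unrooted NJ over %d leaves\n",
              length(x$tree$tip.label)))
  invisible(x)
}

#' @export
summary.pattree <- function(object, ...) {
  w <- object$space$weights
  out <- list(fit = object,
              n_seq = db_size(object$seqs),
              n_patterns = nrow(object$patterns),
              support_range = range(object$patterns$support),
              length_range = range(object$patterns$length),
              weight_summary = summary(w),
              dist_summary = summary(object$dist[upper.tri(object$dist)]),
              timings = object$timings)
  class(out) <- "summary.pattree"
  out
}

#' @export
print.summary.pattree <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  pattern supports in [%d, %d], lengths in [%d, %d]\n",
              x$support_range[1], x$support_range[2],
              x$length_range[1], x$length_range[2]))
  cat("  weights:\n"); print(x$weight_summary)
  cat("  pairwise distances:\n"); print(x$dist_summary)
  cat(sprintf("  stage timings (s): mine %.2f, vectorize %.2f, distance %.2f, tree %.2f\n",
              x$timings[["mine"]], x$timings[["vectorize"]],
              x$timings[["distance"]], x$timings[["tree"]]))
  invisible(x)
}

#' Plot the inferred tree
#'
#' @param x a `pattree` fit.
#' @param type tree plot type, passed to [ape::plot.phylo()].
#' @param ... further arguments for [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.pattree <- function(x, type = "unrooted", ...) {
  ape::plot.phylo(x$tree, type = type, ...)
  invisible(x)
}

#' Pattern vectors for new sequences
#'
#' Projects held-out sequences into the fitted feature space by direct
#' pattern scanning, using the fit's vector mode.
#'
#' @param object a `pattree` fit.
#' @param newdata a [seq_set()] (defaults to the training sequences).
#' @param ... unused.
#' @return pattern-vector matrix, rows = sequence ids.
#' @export
predict.pattree <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$vectors)
  vectorize_sequences(newdata, object$space, mode = object$params$mode)
}

#' Write the artifacts of a fit
#'
#' @param fit a `pattree` fit.
#' @param tree optional path for the Newick tree.
#' @param matrix optional path for the PHYLIP square distance matrix.
#' @param patterns optional path for the pattern TSV.
#' @param manifest optional path for a JSON run manifest (resolved
#'   parameters, pattern count, stage timings; requires jsonlite).
#' @return `fit`, invisibly.
#' @export
write_pattree <- function(fit, tree = NULL, matrix = NULL, patterns = NULL,
                          manifest = NULL) {
  stopifnot(inherits(fit, "pattree"))
  if (!is.null(tree)) write_newick(fit$tree, tree)
  if (!is.null(matrix)) write_phylip(fit$dist, matrix)
  if (!is.null(patterns))
    write_pattern_tsv(fit$patterns, patterns, weights = fit$space$weights)
  if (!is.null(manifest)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to write the manifest")
    p <- fit$params
    jsonlite::write_json(
      list(n_sequences = db_size(fit$seqs),
           alphabet = fit$seqs$alphabet,
           min_support = p$min_support,
           resolved_support_threshold = p$threshold,
           min_non_wc = p$min_non_wc,
           max_wc = p$max_wc,
           mode = p$mode,
           distance = p$distance,
           n_patterns = nrow(fit$patterns),
           timings_sec = as.list(round(fit$timings, 3))),
      manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(fit)
}

#' Parameter sweep against a reference tree
#'
#' Re-runs the pipeline over a grid of support / wildcard settings and
#' reports the Robinson-Foulds distance of each inferred tree to a
#' reference — the harness behind support- and wildcard-sensitivity
#' experiments on simulated families.
#'
#' @param seqs a [seq_set()].
#' @param ref_tree reference `phylo` tree on the same leaf ids.
#' @param min_support,max_wc,min_non_wc vectors of settings; the full grid
#'   is evaluated.
#' @param mode vector mode for all runs.
#' @return `data.frame` with one row per grid point: the settings, the
#'   resolved threshold, `n_patterns` and `rf`. Grid points where no
#'   pattern survives get `NA`.
#' @export
pattree_sweep <- function(seqs, ref_tree, min_support = 0.03,
                          max_wc = 0:2, min_non_wc = 2L,
                          mode = "weighted") {
  grid <- expand.grid(min_support = min_support, min_non_wc = min_non_wc,
                      max_wc = max_wc, KEEP.OUT.ATTRS = FALSE)
  grid$threshold <- NA_integer_
  grid$n_patterns <- NA_integer_
  grid$rf <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      pattree(seqs, min_support = grid$min_support[i],
              min_non_wc = grid$min_non_wc[i], max_wc = grid$max_wc[i],
              mode = mode),
      error = function(e) NULL)
    if (is.null(fit)) next
    grid$threshold[i] <- fit$params$threshold
    grid$n_patterns[i] <- nrow(fit$patterns)
    grid$rf[i] <- rf_distance(fit$tree, ref_tree)
  }
  grid
}
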