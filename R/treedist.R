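#' Non-trivial splits of a tree
#'
#' Each internal edge of an unrooted tree bipartitions the leaf set; the
#' Robinson-Foulds distance counts splits present in only one of two trees.
#' Splits are canonicalized as the side **not** containing the reference
#' leaf (the lexicographically smallest label), encoded as a sorted,
#' `|`-joined label string; trivial splits (a side with fewer than 2 leaves)
#' are dropped and duplicates (e.g. the two root edges of a rooted binary
#' tree) collapse, so rooting does not matter. Multifurcating nodes simply
#' contribute fewer splits.
#'
#' @param tree a `phylo` tree.
#' @return character vector of canonical split encodings (possibly empty);
#'   an unrooted binary tree on `n` leaves yields `n - 3` splits.
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(character(0))
  ref <- sort(labs, method = "radix")[1]
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side, method = "radix"), collapse = "|")
  }, character(1))
  sort(unique(keys[!is.na(keys)]), method = "radix")
}

#' Robinson-Foulds symmetric difference between two trees
#'
#' Counts the non-trivial bipartitions found in exactly one of the two
#' unrooted topologies. Branch lengths and rooting are ignored. The distance
#' is 0 iff the unrooted topologies are identical and at most `2(n - 3)` for
#' binary trees on `n` shared leaves.
#'
#' @param t1,t2 `phylo` trees over the same leaf-label set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in first tree: [",
         paste(only1, collapse = ", "), "]; only in second tree: [",
         paste(only2, collapse = ", "), "]")
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
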