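#' Sequence-evolution parameters
#'
#' Settings for the tree-guided simulator. All rates are per site per unit
#' branch length. The defaults describe the validation regime used
#' throughout the package: a ~350-residue protein ancestor, a substitution
#' rate of 0.4 (calibrated so a 12-leaf family at the default branch lengths
#' lands at ~65-70% mean pairwise identity, the low-divergence regime), light
#' indel pressure (0.005 each way) and geometric indel lengths with mean 2.
#'
#' @param root_length length of the ancestral sequence, >= 1.
#' @param sub_rate substitution rate; along a branch of length `t` each site
#'   is replaced with probability `1 - exp(-sub_rate * t)` by a uniformly
#'   chosen different residue.
#' @param ins_rate,del_rate expected insertions/deletions per site per unit
#'   branch length; events are Poisson, positions uniform.
#' @param indel_mean_len mean of the geometric indel-length distribution.
#' @param alphabet `"protein"` (20 standard residues), `"dna"` or `"rna"`.
#' @param seed integer seed; the simulation is a pure function of parameters
#'   plus seed.
#' @return an object of class `evolution_params`.
#' @export
evolution_params <- function(root_length = 350L, sub_rate = 0.4,
                             ins_rate = 0.005, del_rate = 0.005,
                             indel_mean_len = 2, alphabet = "protein",
                             seed = 1L) {
  stopifnot(root_length >= 1, sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            indel_mean_len >= 1)
  alphabet <- match.arg(alphabet, c("protein", "dna", "rna"))
  structure(list(root_length = as.integer(root_length), sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 indel_mean_len = indel_mean_len, alphabet = alphabet,
                 seed = as.integer(seed)),
            class = "evolution_params")
}

residue_pool <- function(alphabet) {
  switch(alphabet,
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    dna = c("A", "C", "G", "T"),
    rna = c("A", "C", "G", "U"))
}

#' Random guide tree
#'
#' A random rooted binary topology (via [ape::rtree()]) with branch lengths
#' drawn uniformly from `br_range`, deterministic given the seed. Tips are
#' labelled `t1..tn`.
#'
#' @param n_leaves number of leaves, >= 2.
#' @param seed integer seed.
#' @param br_range length-2 numeric, the uniform branch-length interval.
#' @return a `phylo` tree.
#' @export
random_tree <- function(n_leaves, seed = 1L, br_range = c(0.05, 0.3)) {
  if (n_leaves < 2L) stop("need at least 2 leaves")
  stopifnot(length(br_range) == 2L, br_range[1] <= br_range[2])
  with_seed(seed, {
    ape::rtree(n_leaves, rooted = TRUE,
               br = function(k) stats::runif(k, br_range[1], br_range[2]))
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Evolve sequences along a guide tree
#'
#' Draws a uniform-random root sequence and mutates it down every branch:
#' each site substitutes with probability `1 - exp(-sub_rate * t)` to a
#' uniformly chosen different residue; deletion and insertion event counts
#' are Poisson with mean `rate * t * L`, positions uniform, lengths
#' geometric with the configured mean (substitutions are applied first,
#' then deletions, then insertions). The leaf sequences plus the guide tree
#' — the recorded "true" history — make every downstream stage testable.
#'
#' @param tree a rooted `phylo` guide tree with branch lengths.
#' @param params an [evolution_params()].
#' @return object of class `sim_result`: list with `tree` (the guide),
#'   `seqs` (a [seq_set()] of leaf sequences, ids = tip labels), `root_seq`,
#'   and `params`.
#' @export
evolve_sequences <- function(tree, params = evolution_params()) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "evolution_params"))
  if (is.null(tree$edge.length)) stop("guide tree must have branch lengths")
  pool <- residue_pool(params$alphabet)
  n <- length(tree$tip.label)
  with_seed(params$seed, {
    root_seq <- sample(pool, params$root_length, replace = TRUE)
    node_seq <- vector("list", n + tree$Nnode)
    node_seq[[n + 1L]] <- root_seq
    # cladewise order guarantees parents are filled before children
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      node_seq[[edges[e, 2]]] <-
        mutate_seq(node_seq[[edges[e, 1]]], lens[[e]], params, pool)
    }
    leaves <- vapply(seq_len(n), function(i) paste(node_seq[[i]],
                                                   collapse = ""),
                     character(1))
    structure(list(tree = tree,
                   seqs = seq_set(tree$tip.label, leaves,
                                  alphabet = params$alphabet),
                   root_seq = paste(root_seq, collapse = ""),
                   params = params),
              class = "sim_result")
  })
}

mutate_seq <- function(chars, t, params, pool) {
  L <- length(chars)
  # substitutions
  p <- 1 - exp(-params$sub_rate * t)
  hit <- which(stats::runif(L) < p)
  for (i in hit) chars[[i]] <- sample(setdiff(pool, chars[[i]]), 1L)
  # deletions
  n_del <- stats::rpois(1L, params$del_rate * t * L)
  for (k in seq_len(n_del)) {
    L <- length(chars)
    len <- stats::rgeom(1L, 1 / params$indel_mean_len) + 1L
    if (L - len < 1L) next  # never delete the whole sequence
    pos <- sample.int(L, 1L)
    chars <- chars[-(pos:min(L, pos + len - 1L))]
  }
  # insertions
  n_ins <- stats::rpois(1L, params$ins_rate * t * L)
  for (k in seq_len(n_ins)) {
    L <- length(chars)
    len <- stats::rgeom(1L, 1 / params$indel_mean_len) + 1L
    pos <- sample.int(L + 1L, 1L) - 1L  # insert after position pos (0 = front)
    chars <- append(chars, sample(pool, len, replace = TRUE), after = pos)
  }
  chars
}

#' Simulate a sequence family
#'
#' Convenience wrapper: draw a [random_tree()] and [evolve_sequences()]
#' along it with a single seed controlling both.
#'
#' @param n_leaves number of leaves.
#' @param seed integer seed.
#' @param br_range branch-length interval for the guide tree.
#' @param ... passed to [evolution_params()].
#' @return a `sim_result` (see [evolve_sequences()]).
#' @export
simulate_family <- function(n_leaves = 12L, seed = 1L,
                            br_range = c(0.05, 0.3), ...) {
  params <- evolution_params(..., seed = seed)
  tree <- random_tree(n_leaves, seed = seed, br_range = br_range)
  evolve_sequences(tree, params)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d leaves, root length %d, sub_rate %.3g, seed %d\n",
              length(x$tree$tip.label), x$params$root_length,
              x$params$sub_rate, x$params$seed))
  invisible(x)
}

#' Mean pairwise percent identity of a sequence set
#'
#' Global (Needleman-Wunsch) pairwise alignments via
#' [Biostrings::pairwiseAlignment()] (BLOSUM62 for protein, +2/-1 for
#' nucleotide), averaged over all pairs. Used to report the divergence
#' regime a simulated family actually reached.
#'
#' @param seqs a [seq_set()].
#' @param max_pairs optional cap: a deterministic subsample of pairs when
#'   the full set is larger.
#' @return mean percent identity in `[0, 100]`.
#' @export
mean_pairwise_identity <- function(seqs, max_pairs = Inf) {
  stopifnot(inherits(seqs, "seq_set"))
  n <- db_size(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  pairs <- utils::combn(n, 2L)
  if (ncol(pairs) > max_pairs) {
    idx <- round(seq(1L, ncol(pairs), length.out = max_pairs))
    pairs <- pairs[, idx, drop = FALSE]
  }
  if (seqs$alphabet == "protein") {
    utils::data("BLOSUM62", package = "Biostrings", envir = environment())
    mat <- get("BLOSUM62", envir = environment())
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  }
  ids <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- Biostrings::pairwiseAlignment(seqs$seq[pairs[1, k]],
                                       seqs$seq[pairs[2, k]],
                                       substitutionMatrix = mat,
                                       gapOpening = 10, gapExtension = 1)
    ids[k] <- Biostrings::pid(a)
  }
  mean(ids)
}
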