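#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the usual Q-criterion
#' `Q(i,j) = (N-2) d(i,j) - R_i - R_j`. Ties are broken by the
#' lexicographically smallest active index pair, making the output
#' deterministic. Negative branch-length estimates are clamped to zero with
#' the deficit moved onto the sibling edge, so leaf-to-leaf path lengths are
#' preserved. On an additive matrix the input distances are recovered
#' exactly. The result is unrooted: for `n >= 3` taxa it is serialized and
#' stored with a trifurcating root node; for `n = 2` the single edge is split
#' evenly across a degree-2 root.
#'
#' @param d symmetric numeric matrix with zero diagonal and row/column
#'   labels.
#' @return an [ape::as.phylo] `phylo` tree whose tip labels are the matrix
#'   labels.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix")
  if (any(is.na(d)) || any(!is.finite(d)))
    stop("distance matrix contains NA/NaN/Inf")
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix diagonal must be zero")
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")

  if (n == 2L) {
    half <- d[1, 2] / 2
    return(new_phylo(matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                     c(half, half), labs, 1L))
  }

  # Working state: active node ids (tips 1..n, internals n+1..) and their
  # pairwise distances.
  act <- seq_len(n)
  D <- unname(d)
  nextid <- n + 1L
  parent <- integer(0); child <- integer(0); blen <- numeric(0)

  add_edge <- function(p, c, l) {
    parent <<- c(parent, p); child <<- c(child, c); blen <<- c(blen, l)
  }

  while (length(act) > 3L) {
    m <- length(act)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lexicographically smallest (i, j), i < j, among minimizers
    best <- c(1L, 2L); bq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    u <- nextid; nextid <- nextid + 1L
    add_edge(u, act[i], vi)
    add_edge(u, act[j], vj)
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    D <- D2
    act <- c(act[keep], u)
  }

  # Final three-point star: x_a = (d_ab + d_ac - d_bc) / 2 and cyclic.
  u <- nextid
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(u, act[1], max(v1, 0))
  add_edge(u, act[2], max(v2, 0))
  add_edge(u, act[3], max(v3, 0))

  build_phylo_from_edges(parent, child, blen, labs, root = u, n_tips = n)
}

new_phylo <- function(edge, edge.length, tip.label, Nnode) {
  t <- list(edge = edge, edge.length = edge.length, tip.label = tip.label,
            Nnode = Nnode)
  class(t) <- "phylo"
  attr(t, "order") <- NULL
  t
}

# Renumber arbitrary node ids to ape's convention (tips 1..n unchanged,
# internals n+1.. in preorder from the root).
build_phylo_from_edges <- function(parent, child, blen, labs, root, n_tips) {
  kids <- split(seq_along(parent), parent)
  newid <- integer(max(c(parent, child)))
  newid[seq_len(n_tips)] <- seq_len(n_tips)
  counter <- n_tips
  ep <- integer(0); ec <- integer(0); el <- numeric(0)
  stack <- root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    counter <- counter + 1L
    newid[node] <- counter
    for (e in kids[[as.character(node)]]) {
      ch <- child[[e]]
      if (ch <= n_tips) {
        ep <- c(ep, node); ec <- c(ec, ch); el <- c(el, blen[[e]])
      } else {
        ep <- c(ep, node); ec <- c(ec, -e); el <- c(el, blen[[e]])
        stack <- c(stack, ch)
      }
    }
  }
  # second pass: resolve internal child ids recorded as -edge index
  for (k in seq_along(ec)) {
    if (ec[[k]] < 0) ec[[k]] <- newid[child[[-ec[[k]]]]]
  }
  ep <- newid[ep]
  n_internal <- counter - n_tips
  new_phylo(cbind(ep, ec, deparse.level = 0), el, labs, n_internal)
}

#' Serialize a tree as Newick
#'
#' Writes branch lengths when present and terminates with `;`. Labels
#' containing Newick metacharacters (whitespace, parentheses, commas, colons,
#' semicolons, quotes, brackets) are single-quoted, with embedded quotes
#' doubled.
#'
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return single Newick string.
#' @export
to_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  quote_label <- function(lab) {
    bad <- grepl("[\\s(),:;'\\[\\]]", lab, perl = TRUE)
    lab[bad] <- paste0("'", gsub("'", "''", lab[bad]), "'")
    lab
  }
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node) {
    if (node <= n) return(quote_label(tree$tip.label[[node]]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      ch <- rec(tree$edge[e, 2])
      if (has_len) paste0(ch, ":", fmt(tree$edge.length[[e]])) else ch
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Parse a Newick string
#'
#' Validates the syntax first (balanced parentheses, a terminating `;`, no
#' trailing garbage), reporting the 1-based character position of the first
#' problem, then builds the tree. Edges without a stated length are left
#' lengthless (`edge.length` absent when no edge has one): they count as 0
#' in path-length computations and the topology alone is used for
#' Robinson-Foulds comparison.
#'
#' @param s a Newick string.
#' @return a `phylo` tree.
#' @export
parse_newick <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  semi <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (in_quote) { if (ch == "'") in_quote <- FALSE; next }
    if (ch == "'") { in_quote <- TRUE; next }
    if (semi > 0L && !grepl("^\\s$", ch))
      stop("trailing characters after ';' at position ", i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parenthesis at position ", i)
    }
    if (ch == ";") {
      if (depth != 0L) stop("unbalanced parenthesis at position ", i)
      semi <- i
    }
  }
  if (in_quote) stop("unterminated quoted label at position ", length(chars))
  if (depth != 0L || semi == 0L)
    stop("unexpected end of input at position ", length(chars))
  tr <- tryCatch(ape::read.tree(text = s), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse Newick string")
  tr
}

#' Read a Newick tree from file
#' @param path file containing one Newick tree.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree to a Newick file
#' @param tree a `phylo` tree.
#' @param path output path.
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10L) {
  writeLines(to_newick(tree, digits = digits), path)
  invisible(path)
}
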