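#' Normalize a pattern vector to a probability vector
#'
#' Divides by the vector sum. An all-zero input (a sequence containing no
#' feature-space pattern) cannot be normalized; it is returned unchanged with
#' attribute `all_zero = TRUE`, and the Jensen-Shannon distance defines its
#' distance by convention (see [js_distance()]).
#'
#' @param v non-negative numeric vector.
#' @return probability vector (sums to 1), or a flagged zero vector.
#' @export
normalize_pvec <- function(v) {
  if (any(v < 0)) stop("pattern vectors must be non-negative")
  s <- sum(v)
  if (s == 0) {
    attr(v, "all_zero") <- TRUE
    return(v)
  }
  v / s
}

is_all_zero <- function(v) isTRUE(attr(v, "all_zero"))

#' Kullback-Leibler divergence (base-2)
#'
#' `KL(P, M) = sum_i P(i) log2(P(i) / M(i))`, with the convention
#' `0 * log(0 / .) = 0`. Defined only where `M` dominates `P`; when `M` is
#' the equal mixture of `P` with another distribution this always holds.
#'
#' @param p,m probability vectors of equal length.
#' @return non-negative divergence in bits.
#' @export
kl_divergence <- function(p, m) {
  if (length(p) != length(m)) stop("length mismatch")
  pos <- p > 0
  if (any(pos & m == 0))
    stop("KL undefined: p > 0 where m = 0")
  sum(p[pos] * log2(p[pos] / m[pos]))
}

#' Jensen-Shannon distance between two probability vectors
#'
#' `JS(P, Q) = KL(P, M)/2 + KL(Q, M)/2` with `M = (P + Q)/2`, log base 2,
#' so the value lies in `[0, 1]`: 0 for identical distributions, 1 for
#' disjoint supports. Flagged all-zero vectors (see [normalize_pvec()]) are
#' maximally distant (1) from any proper distribution and at distance 0 from
#' each other.
#'
#' @param p,q probability vectors of equal length (normalized, or flagged
#'   all-zero).
#' @return numeric in `[0, 1]`.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  zp <- is_all_zero(p); zq <- is_all_zero(q)
  if (zp && zq) return(0)
  if (zp || zq) return(1)
  m <- (p + q) / 2
  kl_divergence(p, m) / 2 + kl_divergence(q, m) / 2
}

#' Pairwise Jensen-Shannon distance matrix
#'
#' Normalizes each row of a pattern-vector matrix and computes all pairwise
#' Jensen-Shannon distances. The matrix stores the divergence itself (the
#' formula value, in `[0, 1]`); `sqrt = TRUE` stores its square root, which
#' is a metric.
#'
#' @param vectors numeric matrix from [vectorize_sequences()] (rows =
#'   sequences), or any non-negative matrix with row names.
#' @param sqrt take the square root of each divergence.
#' @return symmetric matrix with zero diagonal and the sequence ids as
#'   dimnames.
#' @export
js_distance_matrix <- function(vectors, sqrt = FALSE) {
  if (!is.matrix(vectors) || nrow(vectors) < 2L)
    stop("need a matrix with at least 2 rows")
  n <- nrow(vectors)
  probs <- vector("list", n)
  for (i in seq_len(n)) probs[[i]] <- normalize_pvec(vectors[i, ])
  d <- matrix(0, n, n, dimnames = list(rownames(vectors), rownames(vectors)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- js_distance(probs[[i]], probs[[j]])
      d[i, j] <- d[j, i] <- v
    }
  }
  if (sqrt) d <- base::sqrt(d)
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d symmetric labeled distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labs <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(labs[i], width = -10L),
                      paste(sprintf("%.9f", d[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path input path.
#' @return symmetric labeled matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[[1]]))
  if (is.na(n) || length(lines) != n + 1L)
    stop("malformed PHYLIP matrix: expected ", n, " rows")
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    labs[i] <- parts[[1]]
    d[i, ] <- as.numeric(parts[-1])
  }
  dimnames(d) <- list(labs, labs)
  d
}
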