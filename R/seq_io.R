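#' Sequence sets
#'
#' A `seq_set` is the mining database: an ordered collection of uniquely
#' identified, sanitized (uppercase, gap-free) sequences over a declared
#' alphabet. `db_size` is the number of records and is the denominator of the
#' pattern weighting score.
#'
#' @param ids character vector of unique, non-empty record identifiers.
#' @param seqs character vector of residue strings, same length as `ids`.
#' @param alphabet one of `"protein"`, `"dna"`, `"rna"`, or `"auto"` to detect
#'   from the residues (sequences made only of `A,C,G,T,U,N` are classed as
#'   nucleotide, everything else as protein).
#' @param descriptions optional character vector of free-text descriptions.
#' @return an object of class `seq_set` with fields `id`, `seq`, `desc`,
#'   `alphabet`.
#' @export
seq_set <- function(ids, seqs, alphabet = "auto", descriptions = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (length(ids) == 0L)
    stop("empty sequence set")
  if (any(!nzchar(ids)))
    stop("sequence ids must be non-empty")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  seqs <- gsub("[-.]", "", seqs)  # alignment gaps are always stripped
  if (any(!nzchar(seqs)))
    stop("empty sequence(s) after sanitization: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  alphabet <- match.arg(alphabet, c("auto", "protein", "dna", "rna"))
  if (alphabet == "auto") alphabet <- detect_alphabet(seqs)
  validate_residues(ids, seqs, alphabet)
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  structure(list(id = ids, seq = seqs, desc = as.character(descriptions),
                 alphabet = alphabet),
            class = "seq_set")
}

#' Number of records in a sequence set
#' @param x a `seq_set`.
#' @return integer record count.
#' @export
db_size <- function(x) {
  stopifnot(inherits(x, "seq_set"))
  length(x$id)
}

detect_alphabet <- function(seqs) {
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  if (all(chars %in% c("A", "C", "G", "T", "U", "N"))) {
    if ("U" %in% chars && !("T" %in% chars)) "rna" else "dna"
  } else {
    "protein"
  }
}

alphabet_chars <- function(alphabet) {
  switch(alphabet,
    dna = c("A", "C", "G", "T", "N"),
    rna = c("A", "C", "G", "U", "N"),
    protein = LETTERS,  # 20 standard residues plus ambiguity/rare codes
    stop("unknown alphabet: ", alphabet))
}

validate_residues <- function(ids, seqs, alphabet) {
  ok <- alphabet_chars(alphabet)
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, ok)
    if (length(bad))
      stop(sprintf("record '%s' contains character(s) outside the %s alphabet: %s",
                   ids[[i]], alphabet, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a FASTA file into a sequence set
#'
#' Sequences are uppercased and alignment gap characters (`-`, `.`) are
#' stripped: the method is alignment-free, so inputs exported from alignment
#' benchmarks are de-aligned on the way in. The record id is the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param alphabet `"auto"` (default), `"protein"`, `"dna"` or `"rna"`.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(ids, as.character(ss), alphabet = alphabet, descriptions = desc)
}

#' Write a sequence set to FASTA
#'
#' Output is wrapped at 60 columns and re-readable by standard parsers.
#'
#' @param x a [seq_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  ss <- Biostrings::BStringSet(x$seq)
  names(ss) <- ifelse(nzchar(x$desc), paste(x$id, x$desc), x$id)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' @export
print.seq_set <- function(x, ...) {
  lens <- nchar(x$seq)
  cat(sprintf("seq_set: %d %s sequence(s), lengths %d-%d\n",
              db_size(x), x$alphabet, min(lens), max(lens)))
  show <- utils::head(x$id, 6L)
  cat("  ids:", paste(show, collapse = ", "),
      if (db_size(x) > 6L) "..." else "", "\n")
  invisible(x)
}
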