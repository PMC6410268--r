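# Shared fixture builders; everything is generated in code.

# A small random nucleotide seq_set for property tests.
random_small_seqset <- function(n_seqs = NULL, len_range = c(4L, 10L)) {
  if (is.null(n_seqs)) n_seqs <- sample(3:6, 1)
  seqs <- vapply(seq_len(n_seqs), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = "")
  }, character(1))
  seq_set(paste0("s", seq_len(n_seqs)), seqs)
}

# A random probability vector of dimension k.
random_distribution <- function(k) {
  v <- stats::runif(k)
  v / sum(v)
}

# Write a seq_set to a temporary FASTA file and return the path.
tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
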