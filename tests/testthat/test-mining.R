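test_that("worked examples reproduce exactly", {
  s <- seq_set(c("s1", "s2", "s3"), c("ACAC", "ACGT", "ACAA"))
  r <- mine_closed_patterns(s, min_support = 3, min_non_wc = 2, max_wc = 0)
  expect_equal(r$pattern, "AC")
  expect_equal(r$support, 3L)
  expect_equal(r$supporting_ids[[1]], c("s1", "s2", "s3"))

  s2 <- seq_set(c("a", "b"), c("AAA", "AAA"))
  r2 <- mine_closed_patterns(s2, 2, 2, 0)
  expect_equal(r2$pattern, "AAA")
  expect_equal(r2$support, 2L)

  s3 <- seq_set(c("a", "b"), c("ACT", "AGT"))
  r3 <- mine_closed_patterns(s3, 2, 2, 1)
  expect_equal(r3$pattern, "A.T")
  expect_equal(r3$support, 2L)
})

test_that("support thresholds resolve as documented", {
  expect_equal(resolve_support(0.03, 200), 6L)
  expect_equal(resolve_support(0.03, 12), 2L)   # floor of 2
  expect_equal(resolve_support(0.05, 200), 10L)
  expect_equal(resolve_support(1, 10), 1L)      # integer 1 is absolute
  expect_equal(resolve_support(4, 200), 4L)     # absolute passes through
})

test_that("a threshold beyond the database yields an empty result with warning", {
  s <- seq_set(c("a", "b"), c("ACGT", "ACGT"))
  expect_warning(r <- mine_closed_patterns(s, 5, 2, 0), "threshold")
  expect_equal(nrow(r), 0L)
})

test_that("single-step growth advances matching occurrences only", {
  s <- seq_set("s1", "ACAC")
  g <- grow_pattern("A", list(s1 = c(2L, 4L)), "C", s, max_wc = 0)
  expect_equal(g$pattern, "AC")
  expect_equal(g$pdb, list(s1 = c(3L, 5L)))

  s2 <- seq_set("s1", "AG")
  g2 <- grow_pattern("A", list(s1 = 2L), "C", s2)
  expect_equal(length(g2$pdb), 0L)

  s3 <- seq_set("s1", "AGT")
  g3 <- grow_pattern("A", list(s1 = 2L), ".", s3, max_wc = 1)
  expect_equal(g3$pdb, list(s1 = 3L))
  expect_error(grow_pattern("A", list(s1 = 2L), ".", s3, max_wc = 0), "max_wc")
})

test_that("closedness test matches its definition", {
  expect_false(is_closed_pattern("AA", seq_set(c("a", "b"), c("AAA", "AAA")),
                                 max_wc = 0))
  expect_true(is_closed_pattern("AC",
                                seq_set(c("s1", "s2", "s3"),
                                        c("ACAC", "ACGT", "ACAA")),
                                max_wc = 0))
  # sole occurrence fills a whole sequence: nothing can extend it there
  expect_true(is_closed_pattern("GGT", seq_set(c("a", "b"), c("GGT", "CCC")),
                                max_wc = 0))
})

test_that("brute-force enumerator handles its own worked cases", {
  s <- seq_set("one", "ABC", alphabet = "protein")
  r <- enumerate_patterns_bruteforce(s, min_support = 1, min_non_wc = 2,
                                     max_wc = 0)
  expect_equal(r$pattern, "ABC")
  expect_equal(r$support, 1L)

  expect_warning(
    r2 <- enumerate_patterns_bruteforce(seq_set("a", "ACG"), 2, 2, 0))
  expect_equal(nrow(r2), 0L)
})

test_that("miner equals the brute-force oracle on random instances", {
  set.seed(421)
  for (i in 1:60) {
    s <- random_small_seqset()
    ms <- sample(2:db_size(s), 1)
    nw <- sample(1:3, 1)
    mw <- sample(0:2, 1)
    a <- mine_closed_patterns(s, ms, nw, mw)
    b <- enumerate_patterns_bruteforce(s, ms, nw, mw)
    expect_identical(a$pattern, b$pattern)
    expect_identical(a$support, b$support)
    expect_identical(unclass(a$supporting_ids), unclass(b$supporting_ids))
  }
})

test_that("mining output satisfies its structural invariants", {
  set.seed(99)
  for (i in 1:20) {
    s <- random_small_seqset()
    r <- mine_closed_patterns(s, 2, 2, sample(0:2, 1))
    if (nrow(r) == 0L) next
    # terminals are residues, wildcard runs bounded, support re-verified
    expect_false(any(startsWith(r$pattern, ".") | endsWith(r$pattern, ".")))
    mw <- attr(r, "params")$max_wc
    for (k in seq_len(nrow(r))) {
      runs <- rle(strsplit(r$pattern[[k]], "")[[1]] == ".")
      expect_true(all(runs$lengths[runs$values] <= mw))
      hits <- grepl(r$pattern[[k]], s$seq)
      expect_equal(sum(hits), r$support[[k]])
      expect_equal(s$id[hits], r$supporting_ids[[k]])
    }
    # anti-monotonicity: residue-terminal prefixes are at least as frequent
    for (k in seq_len(nrow(r))) {
      p <- r$pattern[[k]]
      for (cut in seq_len(nchar(p) - 1L)) {
        pre <- substr(p, 1L, cut)
        if (endsWith(pre, ".")) next
        expect_gte(sum(grepl(pre, s$seq)), r$support[[k]])
      }
    }
  }
})

test_that("raising the support threshold never adds patterns", {
  set.seed(300)
  for (i in 1:15) {
    s <- random_small_seqset()
    lo <- mine_closed_patterns(s, 2, 2, 1)
    if (db_size(s) < 3L) next
    hi <- mine_closed_patterns(s, 3, 2, 1)
    # closedness does not depend on the threshold, so the high-threshold
    # result is exactly the support >= 3 slice of the low-threshold one
    expect_true(all(hi$support >= 3L))
    expect_identical(hi$pattern, lo$pattern[lo$support >= 3L])
  }
})

test_that("output is deterministic and lexicographic with wildcard last", {
  set.seed(5)
  s <- random_small_seqset(5, c(8L, 10L))
  r1 <- mine_closed_patterns(s, 2, 2, 2)
  r2 <- mine_closed_patterns(s, 2, 2, 2)
  expect_identical(r1, r2)
  key <- chartr(".", "~", r1$pattern)
  expect_identical(key, sort(key, method = "radix"))
})

test_that("pattern TSV export is re-readable", {
  s <- seq_set(c("a", "b"), c("ACT", "AGT"))
  r <- mine_closed_patterns(s, 2, 2, 1)
  path <- tempfile(fileext = ".tsv")
  write_pattern_tsv(r, path, weights = c(3))
  back <- read.delim(path)
  expect_equal(back$pattern, "A.T")
  expect_equal(back$supporting_ids, "a,b")
  expect_equal(back$weight, 3)
})
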