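test_that("pattern weights follow the length-times-IDF form", {
  expect_identical(pattern_weight(3, 8, 2), 6)
  # present everywhere = weight exactly zero, for any database size
  for (N in c(2, 7, 200)) expect_identical(pattern_weight(5, N, N), 0)
  # independent high-precision evaluation
  expect_equal(pattern_weight(2, 200, 6), 2 * log(200 / 6) / log(2),
               tolerance = 1e-12)
  # linear in pattern length at fixed support
  expect_equal(pattern_weight(4, 50, 5), 2 * pattern_weight(2, 50, 5))
  expect_error(pattern_weight(3, 8, 9), "db_size")
  expect_error(pattern_weight(3, 8, 0))
})

test_that("feature-space weights line up with the mined patterns", {
  s <- seq_set(c("s1", "s2", "s3"), c("ACAC", "ACGT", "ACAA"))
  r <- mine_closed_patterns(s, 3, 2, 0)
  sp <- build_feature_space(r)
  expect_equal(sp$weights, 0)  # support == db_size

  s2 <- seq_set(c("a", "b", "c", "d"), c("ACT", "AGT", "CCC", "GGG"))
  r2 <- mine_closed_patterns(s2, 2, 2, 1)
  sp2 <- build_feature_space(r2)
  i <- match("A.T", sp2$patterns$pattern)
  expect_equal(sp2$weights[[i]], 3 * log2(4 / 2))  # wildcard counts in length

  s3 <- seq_set(c("a", "b"), c("ACGT", "ACGT"))
  r3 <- suppressWarnings(mine_closed_patterns(s3, 3, 2, 0))
  expect_warning(sp3 <- build_feature_space(r3), "empty")
  expect_length(sp3$weights, 0L)
})

test_that("vectorization is presence-based and scans held-out sequences", {
  s <- seq_set(c("a", "b", "c", "d"), c("ACT", "AGT", "CCC", "GGG"))
  sp <- build_feature_space(mine_closed_patterns(s, 2, 2, 1))
  new <- seq_set(c("n1", "n2"), c("ACGT", "TTTT"))
  expect_warning(v <- vectorize_sequences(new, sp, mode = "binary"), "n2")
  expect_true(all(v %in% c(0, 1)))
  expect_equal(unname(v["n2", ]), rep(0, ncol(v)))
  # ACT matches the fuzzy pattern A.T
  expect_equal(unname(v["n1", "A.T"]), 0)   # ACGT has no A.T window
  va <- vectorize_sequences(seq_set("x", "ACT"), sp, mode = "binary")
  expect_equal(unname(va[1, "A.T"]), 1)
})

test_that("binary column sums equal supports; weighted = binary * weights", {
  set.seed(17)
  for (i in 1:10) {
    s <- random_small_seqset(5, c(6L, 10L))
    r <- mine_closed_patterns(s, 2, 2, 1)
    if (nrow(r) == 0L) next
    sp <- build_feature_space(r)
    vb <- suppressWarnings(vectorize_sequences(s, sp, mode = "binary"))
    vw <- suppressWarnings(vectorize_sequences(s, sp, mode = "weighted"))
    expect_equal(unname(colSums(vb)), as.numeric(r$support))
    expect_equal(unname(vw), unname(sweep(vb, 2, sp$weights, "*")),
                 ignore_attr = TRUE)
    # membership agrees with the mined supporting sets
    for (k in seq_len(nrow(r)))
      expect_equal(rownames(vb)[vb[, k] > 0], r$supporting_ids[[k]])
  }
})

test_that("vector TSV export round-trips", {
  s <- seq_set(c("a", "b"), c("ACT", "AGT"))
  sp <- build_feature_space(mine_closed_patterns(s, 2, 2, 1))
  v <- suppressWarnings(vectorize_sequences(s, sp))
  p1 <- tempfile(); p2 <- tempfile()
  write_vector_tsv(v, p1, weights_path = p2, space = sp)
  back <- read.delim(p1, check.names = FALSE)
  expect_equal(back$id, c("a", "b"))
  expect_equal(back[["A.T"]], unname(v[, "A.T"]))
  expect_equal(read.delim(p2)$weight, sp$weights)
})
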