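test_that("two taxa give a single edge of the full distance", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t <- neighbor_joining(d)
  expect_equal(sort(t$tip.label), c("A", "B"))
  expect_equal(sum(t$edge.length), 3)
  expect_equal(to_newick(t), "(A:1.5,B:1.5);")
})

test_that("the 4-taxon additive matrix recovers the AB|CD split and paths", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  t <- neighbor_joining(d)
  expect_equal(tree_splits(t), "C|D")  # side away from reference leaf A
  expect_equal(unname(ape::cophenetic.phylo(t)[labs, labs]), unname(d),
               tolerance = 1e-9)
})

test_that("three taxa solve the closed-form star", {
  labs <- c("x", "y", "z")
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(labs, labs))
  t <- neighbor_joining(d)
  # x_i = (d_ij + d_ik - d_jk) / 2
  lens <- t$edge.length[match(1:3, t$edge[, 2])]
  expect_equal(lens, c((5 + 9 - 8) / 2, (5 + 8 - 9) / 2, (9 + 8 - 5) / 2))
})

test_that("NJ exactly inverts path-length matrices of random trees", {
  set.seed(43)
  for (i in 1:30) {
    tr <- random_tree(sample(5:15, 1), seed = i, br_range = c(0.1, 2))
    m <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(m)
    expect_equal(rf_distance(nj, tr), 0L)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(m), colnames(m)] - m)),
              1e-6)
  }
})

test_that("invalid matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(d), "symmetric")
  d2 <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(neighbor_joining(d2), "NA")
  d3 <- matrix(c(1, 2, 2, 0), 2, 2)
  expect_error(neighbor_joining(d3), "diagonal")
})

test_that("Newick serialization round-trips and quotes awkward labels", {
  tr <- random_tree(8, seed = 5)
  s <- to_newick(tr)
  expect_true(endsWith(s, ";"))
  back <- parse_newick(s)
  expect_equal(rf_distance(back, tr), 0L)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  cb <- ape::cophenetic.phylo(back)
  expect_equal(cb[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-6)

  t2 <- neighbor_joining(matrix(c(0, 2, 2, 0), 2, 2,
                                dimnames = list(c("sp one", "B"),
                                                c("sp one", "B"))))
  expect_match(to_newick(t2), "'sp one'", fixed = TRUE)
})

test_that("Newick parsing reports malformed input with a position", {
  expect_error(parse_newick("(A,B"), "position")
  expect_error(parse_newick("(A,B));"), "position 6")
  expect_error(parse_newick("(A,B); x"), "trailing")
  t <- parse_newick("((A:1,B:2):1,C:3);")
  expect_equal(sort(t$tip.label), c("A", "B", "C"))
  expect_equal(sort(t$edge.length), c(1, 1, 2, 3))
  t2 <- parse_newick("(A,B,(C,D));")
  expect_equal(tree_splits(t2), "C|D")
})

test_that("Newick files round-trip on disk", {
  tr <- random_tree(6, seed = 9)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_equal(rf_distance(read_newick(path), tr), 0L)
})
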