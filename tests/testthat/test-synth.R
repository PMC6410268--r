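test_that("random guide trees are seeded, sized and labelled as promised", {
  t2 <- random_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_identical(to_newick(random_tree(10, seed = 7)),
                   to_newick(random_tree(10, seed = 7)))
  expect_false(identical(to_newick(random_tree(10, seed = 7)),
                         to_newick(random_tree(10, seed = 8))))
  expect_length(tree_splits(random_tree(10, seed = 3)), 7L)
  expect_error(random_tree(1))
  br <- random_tree(30, seed = 4, br_range = c(0.2, 0.4))$edge.length
  expect_true(all(br >= 0.2 & br <= 0.4))
})

test_that("zero rates copy the root to every leaf", {
  sim <- simulate_family(n_leaves = 6, root_length = 50, sub_rate = 0,
                         ins_rate = 0, del_rate = 0, seed = 3)
  expect_true(all(sim$seqs$seq == sim$root_seq))
  expect_equal(sort(sim$seqs$id), sort(sim$tree$tip.label))
})

test_that("simulation is a pure function of parameters and seed", {
  a <- simulate_family(n_leaves = 8, root_length = 80, seed = 11)
  b <- simulate_family(n_leaves = 8, root_length = 80, seed = 11)
  expect_identical(a$seqs$seq, b$seqs$seq)
  expect_identical(to_newick(a$tree), to_newick(b$tree))
  c <- simulate_family(n_leaves = 8, root_length = 80, seed = 12)
  expect_false(identical(a$seqs$seq, c$seqs$seq))
})

test_that("a deletion-dominated branch shortens the sequence", {
  tr <- neighbor_joining(matrix(c(0, 4, 4, 0), 2, 2,
                                dimnames = list(c("p", "q"), c("p", "q"))))
  shorter <- 0L
  for (rep in 1:50) {
    sim <- evolve_sequences(tr, evolution_params(root_length = 200,
                                                 sub_rate = 0, ins_rate = 0,
                                                 del_rate = 0.2, seed = rep))
    if (all(nchar(sim$seqs$seq) < 200)) shorter <- shorter + 1L
  }
  # each leaf sits 2 units from the root: ~80 expected deletion events
  expect_gte(shorter, 48L)
})

test_that("substitution-only identity tracks the analytic expectation", {
  # two leaves one unit from the root, rate r, no indels: per branch a site
  # substitutes with probability s = 1 - exp(-r) to a uniform different
  # residue, so the leaves agree with probability (1-s)^2 + s^2/19 exactly
  r <- 0.25
  tr <- neighbor_joining(matrix(c(0, 2, 2, 0), 2, 2,
                                dimnames = list(c("p", "q"), c("p", "q"))))
  obs <- numeric(100)
  for (rep in 1:100) {
    sim <- evolve_sequences(tr, evolution_params(root_length = 300,
                                                 sub_rate = r, ins_rate = 0,
                                                 del_rate = 0, seed = rep))
    a <- strsplit(sim$seqs$seq[[1]], "")[[1]]
    b <- strsplit(sim$seqs$seq[[2]], "")[[1]]
    obs[rep] <- mean(a == b)
  }
  s <- 1 - exp(-r)
  p_same <- (1 - s)^2 + s^2 / 19
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - p_same), max(3 * se, 0.01))
})

test_that("pairwise identity declines as the substitution rate rises", {
  ids <- vapply(c(0.2, 0.6, 1.8), function(r) {
    mean(vapply(1:3, function(rep) {
      sim <- simulate_family(n_leaves = 6, root_length = 150, sub_rate = r,
                             seed = 600 + rep)
      mean_pairwise_identity(sim$seqs, max_pairs = 10)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ids) < 0))
})
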