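---
title: "Alignment-free phylogenies from closed sequential patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free phylogenies from closed sequential patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pattree)
```

## The method

Multiple sequence alignment becomes unreliable when sequences are highly
divergent, and distance estimates built on a poor alignment propagate into a
poor tree. `pattree` reconstructs phylogenies without aligning. Its feature
space is the set of *closed frequent sequential patterns*: contiguous motifs
over the residue alphabet extended with a single-residue wildcard (written
`.`), e.g. `A.T`, which matches `ACT`, `AGT`, ... A pattern *occurs* in a
sequence when it matches contiguously, the wildcard standing for exactly one
arbitrary residue (never zero or several — variable-gap semantics would change
every support count). *Support* is the number of distinct sequences containing
at least one occurrence; within-sequence multiplicity is deliberately ignored
so that the vector representation below stays presence-based.

Three constraints define the admissible pattern space:

* `min_support` — fractional thresholds `f` resolve to
  `max(2, ceiling(f * DBSize))`: a pattern seen in a single sequence carries
  no comparative information, hence the floor of 2;
* `min_non_wc` — a reported pattern must contain at least this many concrete
  residues (default 2);
* `max_wc` — no run of consecutive wildcards may exceed this length
  (default 2); both terminals must be residues, since flanking wildcards add
  no discriminative information.

Only *closed* patterns are kept: a frequent pattern is discarded when some
admissible proper super-pattern — an extension on either flank or the
specialization of a wildcard to a residue — has exactly the same support,
because the longer pattern then carries strictly more information about the
same set of sequences.

Each pattern receives the IDF-style weight

$$W = \mathrm{PatLength} \times \log_2\!\frac{\mathrm{DBSize}}{\mathrm{PatSup}},$$

zero exactly for patterns present in every sequence. Every sequence becomes a
vector over the pattern space (entry `W`, or 1 in binary mode, when the
pattern occurs in it), vectors are normalized to probability distributions,
and pairwise distances are the Jensen–Shannon divergence

$$\mathrm{JS}(P,Q) = \tfrac12 \mathrm{KL}(P,M) + \tfrac12 \mathrm{KL}(Q,M),
\qquad M = \tfrac12 (P+Q),$$

with base-2 logarithms, so distances live in $[0, 1]$. The matrix feeds a
Neighbor-Joining construction; the result is an unrooted tree. Tree quality
against a reference is measured by the Robinson–Foulds symmetric difference
(the number of non-trivial bipartitions present in exactly one of the two
unrooted topologies).

## A worked example

```{r example}
sim <- simulate_family(n_leaves = 8, seed = 1, sub_rate = 0.2)
fit <- pattree(sim$seqs)
fit
rf_distance(fit$tree, sim$tree)
```

## Mining: search strategy and why it is exact

The miner grows patterns depth-first over projected occurrence lists: for the
current pattern it records, per sequence, every end offset of an occurrence,
and appending an item only rescans those offsets. Support pruning (drop a
branch whose support falls below the threshold) is classical and exact. On
similar sequences the *frequent* space explodes combinatorially — every
wildcard masking of a long shared block is frequent — while the *closed* set
stays small, so three further prunings are applied, each of which provably
discards only branches in which every pattern is non-closed:

* *wildcard unanimity*: appending a wildcard is skipped when every surviving
  occurrence is followed by the same residue `b`; any pattern below that
  branch has an equal-support specialization with `b` in the wildcard's
  place;
* *left unanimity*: a branch dies when, for some gap `j <= max_wc`, every
  occurrence of the current pattern is preceded (at distance `j + 1`, with
  `j` wildcards in between) by one and the same residue — every descendant
  then has an equal-support left extension;
* *retroactive unanimity*: a child whose occurrence set has become unanimous
  at an existing wildcard position is skipped, since every pattern below it
  specializes there with equal support.

Closedness of a reported pattern is decided exactly from its own occurrence
list by checking every one-step super-pattern (left/right extensions through
up to `max_wc` wildcards, and wildcard specializations). A chain argument
reduces an arbitrary equal-support super-pattern to a sequence of such
one-step supers with equal support throughout, so the one-step check is
equivalent to the full definition. The package also ships
`enumerate_patterns_bruteforce()`, a level-wise enumerator over the full
admissible string space with regex-based support counting and pairwise
containment for closedness — structurally independent of the miner — and the
test suite asserts exact equality of the two on hundreds of randomized
instances.

Ties and determinism: patterns are reported in lexicographic order with the
wildcard sorting after every residue; Neighbor-Joining breaks Q-criterion
ties by the lexicographically smallest active index pair. Two runs on the
same input are byte-identical.

## Numerical and degenerate-case choices

* Normalization to probability vectors is mandatory before the divergence
  (the Kullback–Leibler terms require distributions). Probability sums are
  checked to `1e-9`.
* A sequence containing no feature-space pattern yields an all-zero vector;
  it is kept (dropping it would silently change the taxon set), flagged, and
  placed at the maximal distance 1 from every proper distribution and at 0
  from other all-zero vectors. The case does not arise in ordinary runs and
  is reported with a warning.
* The distance matrix stores the Jensen–Shannon divergence exactly as
  defined; `distance = "sqrt-js"` stores its square root (a true metric).
  The square root of the divergence also satisfies the triangle inequality
  in the test suite's property checks.
* Negative Neighbor-Joining branch estimates are clamped to zero with the
  deficit moved to the sibling edge, preserving leaf-to-leaf path lengths.
* The protein wildcard is rendered `.` precisely so that the ambiguity code
  `X` remains an ordinary residue; `X`, `B`, `Z`, `U` in input are matched
  like any other letter. Alignment gaps (`-`, `.`) are always stripped on
  input, because the method consumes unaligned sequences.

## The simulator: what it emulates and what it does not

`simulate_family()` provides the validation bed: a random binary guide tree
(`ape::rtree`, branch lengths uniform on `[0.05, 0.3]` by default), a root
sequence drawn uniformly over the 20 standard residues, and along each branch
of length `t` per-site substitution with probability `1 - exp(-rt)` to a
uniformly chosen different residue, plus Poisson insertion/deletion events
(rate 0.005 per site per unit length each, geometric lengths of mean 2).
Everything is a pure function of the parameters and one integer seed.

The defaults are the package's study conditions. The substitution rate
default of 0.4 was calibrated so that a 12-leaf, 300–350-residue family lands
at roughly 65–70% mean pairwise identity — the "low divergence" regime — and
the degradation studies multiply it by 2 and 4. The model is deliberately
simpler than full protein-evolution simulators: no substitution-matrix
(PAM/BLOSUM) preferences, no site-rate heterogeneity, no empirically shaped
indel spectrum. The mining pipeline consumes only the sequences, so any
divergence dial suffices for validating topology recovery; but passing these
tests demonstrates correctness of the machinery and sensible behaviour under
idealized evolution, not state-of-the-art accuracy on real protein families.

Problem sizes used in the shipped validation studies — 12-leaf trees,
300-residue roots, 20 replicates per divergence rung (10 in the acceptance
script) — were chosen as the smallest sets in which topology recovery and its
degradation are clearly measurable.

## Parameter guidance and known limitations

The support threshold is the method's most sensitive parameter. Its
fractional default (0.03) targets divergent families;
on small databases it resolves to the floor of 2, which admits very long
pair-specific patterns when some sequences are close relatives. Those giant
patterns concentrate vector mass on terminal pairs and compress the deeper
part of the distance spectrum. In that regime — highly similar families —
binary vectors (`mode = "binary"`) measurably outperform weighted ones, and
the package's own validation shows exactly the expected pattern: at ~65%
mean identity the weighted default recovers the true 12-leaf topology in
about 70–90% of replicates (misses are almost exclusively the shortest
internal branches, under ~0.1 expected substitutions per site), recovery
stays flat through ~50% identity, and degrades sharply below ~30%. Users
with low-divergence data should prefer binary vectors and/or a larger
support; users with highly divergent data are in the regime the defaults
were designed for.

Other limitations, stated plainly: positions of occurrences are used only
inside the miner's projection, never as features; patterns are unordered
set-features (their arrangement along the sequence is ignored); no
saturation correction is applied to the divergence; and mode selection
(weighted vs binary) is documented guidance, not automated.
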