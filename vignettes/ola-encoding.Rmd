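---
title: "Ordered leaf attachment: encoding tree topologies as integer vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordered leaf attachment: encoding tree topologies as integer vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olatree)
```

## The encoding

A rooted binary tree whose `n` leaves carry a fixed linear order
(labels `0..n-1`) can be viewed as the outcome of a construction that
adds one leaf at a time: start from the single leaf 0, and at step
`i` attach leaf `i` as the sister of some node of the current tree.
Recording *where* each leaf attached reconstructs the tree exactly.
The ordered-leaf-attachment (OLA) code is that record: entry `a_i` is
the label of leaf `i`'s sister at the moment of attachment.

When the sister is a leaf, its label is the obvious choice.  When the
sister is an internal node a labeling convention is needed, and the
convention is what makes the codec linear-time: the internal node
created when leaf `i` arrives is labeled `-i`.  Because internal
labels are negative they can never collide with leaf labels, so they
are assigned once and never renumbered as the tree grows — this is
the essential difference from encodings that label internal nodes
with positive integers and must re-index them at every step, which
costs quadratic time overall.

At step `i` the current tree has nodes labeled `0..i-1` (leaves) and
`-1..-(i-1)` (internals), so `a_i` can be any integer with
`-i < a_i < i`.  These constraints are also sufficient: every vector
in

\[
\mathcal{C}_{n-1} \;=\; \{(a_1,\ldots,a_{n-1}) \in \mathbb{Z}^{n-1}
  : -i < a_i < i\}
\]

decodes to a tree, and the map is a bijection onto the
\((2n-3)!! = 1\cdot3\cdots(2n-3)\) rooted binary leaf-ordered
topologies.  `is_valid_vector()` tests membership,
`enumerate_vectors()` lists the set, and `random_vector()` samples it
uniformly — which, through the bijection, is also a uniform sampler
of tree topologies (`random_tree()`).

### Canonical labels without replaying the construction

To encode an existing tree we must recover the `-i` labels without
knowing the construction order.  Two linear-time traversals do it
(`canonical_labels()`):

* a root-ward pass labels every node with its **clade founder**, the
  smallest leaf label below it;
* each internal node's **clade splitter** is the larger of its two
  children's founders, and the canonical label is minus the splitter.

The intuition: the node created when leaf `i` arrived is the highest
point whose clade was "split open" by leaf `i`, i.e. the node where
`i` is the largest founder among the children.  The test suite checks
the equivalence against an independent oracle that literally replays
the attachment process and records labels, exhaustively for all
trees on up to 6 leaves and on larger random trees.

`encode()` then deconstructs the tree leaf `n-1` down to leaf `1`,
recording each removed leaf's sister label; each step is O(1) array
arithmetic, so encoding is linear.  `decode()` replays attachment
with an array mapping labels to nodes, also linear.  Both run on a
flat parent/children integer-array representation; `"phylo"` objects
(ape) appear only at the user-facing boundary, and traversals are
iterative so caterpillar trees on 10^5 leaves do not exhaust the call
stack.

### One decoding subtlety

Decoding says "subdivide the parent edge of the node labeled `a_i`".
The target can be the current root, which has no parent edge.  We
treat the root as having a phantom edge above it: subdividing it
creates a new root whose children are the old root and the new leaf.
This is the unique reading under which decoding inverts encoding's
root-deletion case, and under which the published worked example
`(0,-1,1,-3)` re-encodes to itself; the round-trip identity is tested
exhaustively for all trees on up to 6 leaves.

## The OLA distance

Since the codec is injective for a fixed leaf order, the Hamming
distance between codes (`ola_distance()`) is a metric on leaf-ordered
topologies.  Entry 1 is always 0, so the distance lies in
`[0, n-2]`.  Three relationships to classical rearrangement distances
motivate the simulation experiments:

* **NNI, on average.**  A single nearest-neighbor interchange can
  displace up to `n-2` code entries in the worst case, but the
  *expected* OLA distance to a uniformly random NNI neighbor is at
  most 4, for every starting tree.
  `experiment_nni_expectation()` estimates the per-size means.
* **SPR, via tree height.**  One subtree-prune-regraft move changes
  code entries only along the pruned and regrafted paths, giving
  \(d_{\mathrm{OLA}}(T,T') \le 2\,\mathrm{ht}(T)\).
  `experiment_spr_max()` records sampled maxima against the height.
* **OLA moves, back to SPR.**  Changing one code entry yields a tree
  within \(\mathrm{ht}(T)\) SPR moves, and within 2 SPR moves on
  average over uniform single-entry changes.
  `experiment_ola_to_spr()` measures exact SPR distances to sampled
  OLA neighbors.

The distance depends on the leaf order.  `shuffled_ola_distance()`
averages over random joint relabelings of both trees, a summary that
tracks SPR distance more stably than any single ordering.

## Rearrangement machinery

**NNI.** Each internal non-root node contributes one internal edge
and two swap variants, so a tree has exactly `2(n-2)` moves.
Sampling (`random_nni_neighbor()`) is uniform over *moves*, not over
distinct neighbor topologies, because the expectation bound above
averages over moves.

**Rooted SPR, planted convention.**  A move cuts the edge above a
non-root node, suppresses its parent, and reattaches the subtree by
subdividing any edge of the remaining tree — including the phantom
edge above the root, which makes the pruned clade sister to
everything else.  Regrafts recreating the original tree are
excluded, and `spr_neighbors()` merges duplicate topologies (using
OLA codes as canonical keys — the codec supplies its own perfect
hash).

**Uniform sampling over distinct SPR neighbors.**  Enumerating the
O(n²) neighborhood to sample one neighbor would be wasteful for the
larger experiment sizes, so `random_spr_neighbor()` uses a counting
argument instead.  Valid (prune `p`, regraft `x`) pairs number
\(P = \sum_p (2n-3-m_p)\), where `m_p` counts nodes in `p`'s subtree.
A pair is *NNI-form* when `x` is a child of `p`'s sibling, the
sibling of `p`'s parent, or `p`'s grandparent; exactly three pairs
produce each NNI topology (prune a grandchild down to its nephew,
prune the nephew up to the aunt, or lift the sibling above the
grandparent), and every non-NNI-form pair produces a unique topology.
Hence there are \(D = P - 2\cdot 2(n-2)\) distinct neighbors, and a
uniform draw picks an NNI move with probability `2(n-2)/D` and
otherwise a uniform non-NNI pair by rejection.  The premise —
three-fold NNI multiplicity, uniqueness elsewhere, distinctness of
NNI results — is not assumed silently: the suite verifies the count
`D` against the exhaustively deduplicated neighborhood for *every*
tree on up to 6 leaves and for random trees on 7 and 8, and verifies
the sampler's law by a chi-square test against the enumerated
neighborhood.

**Exact SPR distance.**  `spr_distance_exact()` is a breadth-first
search in the unit-SPR graph with OLA codes as visited-set keys,
guarded to `n <= 10` (the graph on `n` leaves has `(2n-3)!!`
vertices).  An optional environment memoizes neighborhood expansions
across calls; the experiments exploit this, since hundreds of queries
concentrate around the same focal trees.

## What the generator emulates, and what it does not

All test inputs are synthetic.  Focal trees are drawn uniformly over
leaf-ordered topologies via uniform valid vectors — the natural null
model here, and the distance bounds being checked hold for *every*
tree, so they are distribution-free over the choice of focal tree.
Uniform topologies are not a model of real phylogenies: inferred
trees are typically more balanced than uniform (closer to Yule
processes), carry branch lengths, and their leaf order is an
analyst's choice rather than random.  Passing experiments therefore
demonstrate the combinatorial bounds and the codec's correctness, not
calibration against empirical tree distributions.  Branch lengths are
parsed and discarded throughout: the codec is purely topological.

## Parameters, scales and numerical choices

* Experiment defaults mirror the published simulations:
  `experiment_nni_expectation()` runs 50 focal trees × 20 NNI
  neighbors at sizes 5–1000; `experiment_spr_max()` 30 × 30 at sizes
  20–200.  `experiment_ola_to_spr()` defaults to sizes 5–7 with
  30 × 20 draws: exact BFS distances replace whatever heuristic might
  be used at larger sizes, because a bound check is only meaningful
  against the true distance, and exact search is feasible precisely
  up to the guard.
* Guards: `enumerate_vectors()` stops at `n = 8` (135 135 vectors);
  `spr_distance_exact()` at `n = 10`.  Both are arguments, not
  constants, but the defaults keep accidental combinatorial
  explosions out of interactive use.
* Randomness follows the R idiom: one global RNG stream, seeded by
  the caller (`set.seed()` or the experiments' `seed` argument);
  every experiment row records the seed, and tables are bit-identical
  across runs with the same arguments.
* Canonical Newick output orders children by clade founder,
  ascending, so equal topologies serialize identically — handy for
  diffing and for uniqueness checks.
* Restriction (`restrict_to_first_k()`) returns the induced topology
  on leaves `0..k-1`, so the restricted tree's code is exactly the
  first `k-1` entries of the original code.  (Describing the same
  operation as pruning leaves "larger than k" would keep leaf `k` and
  break that prefix identity; we fix the convention that makes the
  identity hold.)
* Degenerate input: the single-leaf tree is valid with the empty
  code; `n = 0` is rejected.  Ties in child order (impossible for
  founders, which are distinct) never arise.

## Known limitations

The codec covers rooted binary trees only: multifurcations are
rejected rather than resolved, unrooted trees are not re-rooted
automatically, and branch lengths have no representation in the
code.  The OLA distance depends on the chosen leaf order — two trees
close under one ordering can be distant under another — which is why
the shuffled variant exists.  The exact SPR search is exponential in
distance and deliberately capped; no approximate SPR distance is
provided for large trees.
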