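# olatree

Integer-vector encoding of phylogenetic tree topologies by ordered
leaf attachment (OLA), in R.

## The problem

Phylogenetic inference and, increasingly, machine-learning methods
over tree space need tree topologies represented as vectors: vectors
can be hashed, embedded, averaged over, and fed to models that know
nothing about trees.  A good encoding should be cheap to compute,
easy to invert, and its coordinate space should be simple enough
that *every* vector in it is a tree.

The OLA code has all three properties.  A rooted binary tree with
leaves ordered `0..n-1` is grown one leaf at a time; entry `a_i`
records the label of the node that leaf `i` attached next to — a
leaf label if the sister is a leaf, or the canonical label `-j` of
the internal node created when leaf `j` arrived.  This gives a
bijection

    { rooted binary leaf-ordered topologies on n leaves }
        <-->  { (a_1, ..., a_{n-1}) in Z^{n-1} : -i < a_i < i }

computable in both directions in O(n) time, with the valid set a box
of integer points of cardinality (2n-3)!!.  The Hamming distance
between codes ("OLA distance") is then a metric on leaf-ordered
topologies, with provable relationships to classical rearrangement
distances: expected OLA distance to a uniform NNI neighbor is at most
4; OLA distance to any SPR neighbor is at most twice the tree height;
a single code-entry change stays within tree-height SPR moves, and
within 2 on average.

The package provides the codec (`encode`, `decode`,
`is_valid_vector`, `enumerate_vectors`), canonical internal-node
labeling (`canonical_labels`), uniform tree sampling through the
bijection (`random_tree`), the OLA metric (`ola_distance`,
`shuffled_ola_distance`), NNI/SPR/OLA neighborhoods with uniform
samplers, an exact breadth-first-search SPR distance for small trees
(`spr_distance_exact`), and the simulation experiments that check
the distance bounds.  Trees are `ape` `"phylo"` objects; a thin CLI
(`exec/ola`) wraps the same functions.

## A worked example

```r
library(olatree)

t <- parse_newick("((0,(2,3)),(1,4));")
encode(t)
#> [1] 0 0 2 1
```

Read the code as attachment instructions: leaf 1 attaches to leaf 0;
leaf 2 to leaf 0 again; leaf 3 to leaf 2; leaf 4 to leaf 1.  Decoding
any valid vector inverts this, including negative entries that name
internal nodes:

```r
write_newick(decode(c(0, -1, 1, -3)))
#> ((0,((1,3),4)),2);
```

The canonical internal labels are visible in annotated output —
internal node `-j` is the one created when leaf `j` arrived:

```r
write_newick(t, annotate = TRUE)
#> ((0,(2,3)-3)-2,(1,4)-4)-1;

ola_distance(t, decode(c(0, -1, 1, -3)))
#> [1] 3
```

The two codes `(0,0,2,1)` and `(0,-1,1,-3)` differ in positions 2, 3
and 4, so the trees are at OLA distance 3.  A small version of the
NNI experiment (mean OLA distance from uniformly random focal trees
to uniform NNI neighbors, which theory bounds by 4):

```r
tab <- experiment_nni_expectation(sizes = c(10, 100), n_focal = 10,
                                  n_neighbors = 20, seed = 1)
aggregate(value ~ n, tab, mean)
#>     n value
#> 1  10 1.160
#> 2 100 1.185
```

Observed means sit well below the bound at both sizes.

The same operations are available from a shell:

```sh
Rscript exec/ola encode tree.nwk --order taxa.txt
Rscript exec/ola decode "0,0,2,1"
Rscript exec/ola sprdist a.nwk b.nwk
Rscript exec/ola experiment nni --sizes 5,10,50 --seed 1 --out results.csv
```

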