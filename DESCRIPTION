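Package: olatree
Title: Ordered Leaf Attachment Encoding of Phylogenetic Tree Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A linear-time bijective codec between rooted, binary,
    leaf-ordered phylogenetic tree topologies on n leaves and integer
    vectors (a_1, ..., a_{n-1}) satisfying -i < a_i < i (the "ordered
    leaf attachment", or OLA, code).  Provides canonical internal-node
    labeling by clade-founder/clade-splitter traversals, the induced
    OLA (Hamming) distance on tree codes, enumeration and uniform
    sampling of tree topologies through the bijection, NNI, SPR and
    OLA rearrangement neighborhoods with uniform move sampling, an
    exact breadth-first-search SPR distance for small trees, and
    simulation experiments relating the OLA distance to NNI and SPR
    distances.  Trees are read and written as 'ape' "phylo" objects
    with Newick I/O.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
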