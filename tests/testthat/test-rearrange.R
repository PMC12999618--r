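code_key <- function(t) paste(encode(t), collapse = ",")

test_that("a tree has exactly 2(n-2) NNI moves", {
  for (n in 3:6) {
    vs <- enumerate_vectors(n)
    idx <- if (n < 6) seq_len(nrow(vs)) else seq(1, nrow(vs), by = 9)
    for (r in idx) {
      t <- decode(vs[r, ])
      nb <- nni_neighbors(t)
      expect_length(nb, 2L * (n - 2L))
      for (x in nb) expect_false(labeled_isomorphic(x$tree, t))
    }
  }
  expect_identical(nni_neighbors(parse_newick("(0,1);")), list())
})

test_that("the 3-leaf tree has the two other topologies as NNI neighbors", {
  nb <- nni_neighbors(parse_newick("((0,1),2);"))
  got <- sort(vapply(nb, function(x) write_newick(x$tree), character(1)))
  expect_identical(got, c("((0,2),1);", "(0,(1,2));"))
})

test_that("the NNI relation is symmetric", {
  for (t in all_trees(5)) {
    k <- code_key(t)
    for (x in nni_neighbors(t)) {
      back <- vapply(nni_neighbors(x$tree), function(y) code_key(y$tree),
                     character(1))
      expect_true(k %in% back)
    }
  }
})

test_that("random_nni_neighbor is uniform and differs from its input", {
  t <- parse_newick("((0,1),2);")
  set.seed(211)
  draws <- replicate(2000, write_newick(random_nni_neighbor(t)))
  tab <- table(draws)
  expect_identical(length(tab), 2L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  set.seed(3); a <- write_newick(random_nni_neighbor(decode(random_vector(20))))
  set.seed(3); b <- write_newick(random_nni_neighbor(decode(random_vector(20))))
  expect_identical(a, b)
})

test_that("SPR neighborhoods contain the NNI neighborhood and reach all
           3-leaf topologies", {
  nb3 <- spr_neighbors(parse_newick("((0,1),2);"))
  got <- sort(unique(vapply(nb3, function(x) write_newick(x$tree),
                            character(1))))
  expect_identical(got, c("((0,2),1);", "(0,(1,2));"))
  for (t in all_trees(5)) {
    spr_keys <- vapply(spr_neighbors(t), function(x) code_key(x$tree),
                       character(1))
    expect_false(anyDuplicated(spr_keys) > 0)
    for (x in nni_neighbors(t))
      expect_true(code_key(x$tree) %in% spr_keys)
  }
})

test_that("regrafting above the root makes the pruned clade sister to the rest", {
  t <- parse_newick("(((0,1),2),3);")
  nb <- spr_neighbors(t)
  # prune clade {0,1} and regraft on the phantom edge above the root
  want <- parse_newick("((0,1),(2,3));")
  expect_true(any(vapply(nb, function(x) labeled_isomorphic(x$tree, want),
                         logical(1))))
})

test_that("the distinct-neighbor count matches the pair-counting formula", {
  # the uniform sampler relies on: valid (prune, regraft) pairs number
  # P = sum_p (2n-3-m_p), NNI topologies are triple-counted, all other
  # pairs are unique, so |distinct| = P - 2 * 2(n-2).  Verified
  # exhaustively at n = 5 and on random larger trees.
  count_formula <- function(t) {
    n <- length(t$tip.label)
    tr <- olatree:::.phylo_to_tr(t)
    size <- olatree:::.tr_sizes(tr)
    cand <- setdiff(seq_len(2L * n - 1L), tr$root)
    sum(2L * n - 3L - size[cand]) - 4L * (n - 2L)
  }
  for (t in all_trees(5))
    expect_length(spr_neighbors(t), count_formula(t))
  set.seed(223)
  for (n in c(6L, 7L, 8L)) {
    for (i in 1:10) {
      t <- random_tree(n)
      expect_length(spr_neighbors(t), count_formula(t))
    }
  }
})

test_that("random_spr_neighbor is uniform over distinct topologies", {
  set.seed(227)
  t <- decode(c(0, 0, 2, 1))
  keys <- vapply(spr_neighbors(t), function(x) code_key(x$tree), character(1))
  draws <- replicate(8000, code_key(random_spr_neighbor(t)))
  tab <- table(factor(draws, levels = keys))
  expect_identical(sum(tab), 8000L)   # support is exactly the neighborhood
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("OLA neighborhoods have sum_{i>=2} (2i-2) members at distance 1", {
  nb3 <- ola_neighbors(decode(c(0, 0)))
  expect_length(nb3, 2L)
  got <- vapply(nb3, function(x) code_key(x$tree), character(1))
  expect_setequal(got, c("0,-1", "0,1"))
  t4 <- random_tree(4)
  expect_length(ola_neighbors(t4), 6L)
  for (x in ola_neighbors(t4))
    expect_identical(ola_distance(x$tree, t4), 1L)
})

test_that("random_ola_neighbor hits every Hamming-1 vector uniformly", {
  set.seed(229)
  t <- decode(c(0, 0))
  draws <- replicate(2000, code_key(random_ola_neighbor(t)))
  tab <- table(factor(draws, levels = c("0,-1", "0,1")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  t7 <- random_tree(7)
  for (i in 1:10)
    expect_identical(ola_distance(random_ola_neighbor(t7), t7), 1L)
})

test_that("exact SPR distance: identity, unit moves, symmetry, guard", {
  set.seed(233)
  t <- random_tree(6)
  expect_identical(spr_distance_exact(t, t), 0L)
  for (i in 1:5) {
    nb <- random_spr_neighbor(t)
    expect_identical(spr_distance_exact(t, nb), 1L)
  }
  cache <- new.env(parent = emptyenv())
  for (i in 1:5) {
    t1 <- random_tree(6); t2 <- random_tree(6)
    d12 <- spr_distance_exact(t1, t2, cache = cache)
    d21 <- spr_distance_exact(t2, t1, cache = cache)
    expect_identical(d12, d21)
  }
  expect_error(spr_distance_exact(random_tree(12), random_tree(12)),
               "too large for exact SPR")
  expect_error(spr_distance_exact(random_tree(5), random_tree(6)),
               "incompatible trees")
})

test_that("spr_walk takes unit steps", {
  set.seed(239)
  t <- random_tree(7)
  expect_length(spr_walk(t, 0), 1L)
  walk <- spr_walk(t, 4)
  cache <- new.env(parent = emptyenv())
  for (j in 1:4) {
    expect_false(labeled_isomorphic(walk[[j]], walk[[j + 1]]))
    expect_identical(spr_distance_exact(walk[[j]], walk[[j + 1]],
                                        cache = cache), 1L)
  }
})
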