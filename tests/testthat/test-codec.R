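test_that("is_valid_vector enforces -i < a_i < i", {
  expect_true(is_valid_vector(c(0, 0, 2, 1)))
  expect_true(is_valid_vector(0))
  expect_true(is_valid_vector(integer(0)))
  expect_false(is_valid_vector(c(0, -2)))
  expect_false(is_valid_vector(1))
  expect_false(is_valid_vector(c(0, 1, 3)))
  expect_error(is_valid_vector(c(0, 0.5)), "type error")
  expect_error(is_valid_vector("0,1"), "type error")
})

test_that("encode reproduces the worked examples", {
  expect_identical(encode(parse_newick("((0,(2,3)),(1,4));")),
                   c(0L, 0L, 2L, 1L))
  expect_identical(encode(parse_newick("((0,((1,3),4)),2);")),
                   c(0L, -1L, 1L, -3L))
  expect_identical(encode(parse_newick("(0,1);")), 0L)
  expect_identical(encode(parse_newick("0;")), integer(0))
})

test_that("decode attaches each leaf next to the labeled node", {
  expect_true(labeled_isomorphic(decode(0L), parse_newick("(0,1);")))
  expect_true(labeled_isomorphic(decode(c(0, -1)), parse_newick("((0,1),2);")))
  expect_true(labeled_isomorphic(decode(c(0, 0, 2, 1)),
                                 parse_newick("((0,(2,3)),(1,4));")))
  expect_identical(write_newick(decode(integer(0))), "0;")
  expect_error(decode(c(0, 5)), "invalid OLA vector")
})

test_that("enumerate_vectors lists (2n-3)!! vectors lexicographically", {
  expect_identical(enumerate_vectors(2), matrix(0L, 1, 1))
  e3 <- enumerate_vectors(3)
  expect_identical(e3, rbind(c(0L, -1L), c(0L, 0L), c(0L, 1L)))
  expect_identical(nrow(enumerate_vectors(5)), 105L)
  e4 <- enumerate_vectors(4)
  expect_identical(nrow(e4), 15L)
  keys <- apply(e4, 1, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  # lexicographic: rows already in order
  ord <- do.call(order, as.data.frame(e4))
  expect_identical(ord, seq_len(15L))
  expect_error(enumerate_vectors(9), "range error")
  expect_error(enumerate_vectors(1), "range error")
})

test_that("random_vector is uniform over the valid set", {
  set.seed(101)
  expect_identical(random_vector(2), 0L)
  keys <- apply(enumerate_vectors(4), 1, paste, collapse = ",")
  draws <- replicate(15000, paste(random_vector(4), collapse = ","))
  tab <- table(factor(draws, levels = keys))
  expect_identical(length(tab), 15L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  # determinism under a fixed seed
  set.seed(7); a <- random_vector(50)
  set.seed(7); b <- random_vector(50)
  expect_identical(a, b)
  expect_true(is_valid_vector(a))
})

test_that("random_tree pushes the uniform law onto topologies", {
  set.seed(103)
  keys <- replicate(3000, write_newick(random_tree(3)))
  tab <- table(keys)
  expect_identical(length(tab), 3L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  expect_true(labeled_isomorphic(random_tree(2), parse_newick("(0,1);")))
  expect_true(is_valid_vector(encode(random_tree(40))))
})

test_that("the codec is a bijection on all trees with up to 5 leaves", {
  for (n in 2:5) {
    vs <- enumerate_vectors(n)
    trees <- lapply(seq_len(nrow(vs)), function(r) decode(vs[r, ]))
    # injective: pairwise distinct topologies (canonical serialization)
    expect_false(anyDuplicated(vapply(trees, write_newick, character(1))) > 0)
    # left inverse
    for (r in seq_len(nrow(vs)))
      expect_identical(encode(trees[[r]]), vs[r, ])
    # right inverse
    for (tr in trees)
      expect_true(labeled_isomorphic(decode(encode(tr)), tr))
  }
})

test_that("round trips hold for large random vectors", {
  set.seed(107)
  for (n in c(10L, 100L, 1000L)) {
    reps <- if (n == 1000L) 200L else 1000L
    for (i in seq_len(reps)) {
      v <- random_vector(n)
      expect_identical(encode(decode(v)), v)
    }
  }
})

test_that("nonnegative codes are exactly the Yule-type trees", {
  # grow Yule-type trees with an independent builder that records the
  # sister *leaf* at each step; the encoder must return those labels
  set.seed(109)
  for (i in 1:15) {
    y <- oracle_yule(sample(3:15, 1))
    expect_identical(encode(parse_newick(y$newick)), y$v)
    expect_true(all(y$v >= 0))
  }
})

test_that("encode is prefix-stable under restriction (all n <= 6)", {
  for (n in 3:6) {
    vs <- enumerate_vectors(n)
    for (r in seq_len(nrow(vs))) {
      t <- decode(vs[r, ])
      for (k in 2:(n - 1)) {
        expect_identical(encode(restrict_to_first_k(t, k)),
                         vs[r, seq_len(k - 1L)])
      }
    }
  }
})

test_that("vector text round-trips through parse/format", {
  expect_identical(parse_vector("0,0,2,1"), c(0L, 0L, 2L, 1L))
  expect_identical(parse_vector("(0, -1, 1, -3)"), c(0L, -1L, 1L, -3L))
  expect_identical(parse_vector("[0,1]"), c(0L, 1L))
  expect_identical(format_vector(c(0L, -1L)), "0,-1")
  expect_error(parse_vector("0;1"), "parse error")
})
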