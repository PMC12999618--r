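# Tree rearrangements: NNI, rooted SPR, and OLA moves.
#
# NNI: swap a subtree across one internal edge; a tree has exactly
# 2(n-2) moves (two per internal non-root node).
#
# Rooted SPR, planted convention: cut the edge above a non-root node
# p, suppress its parent, and reattach p by subdividing the edge above
# any node x of the remaining tree.  Taking x to be the remaining root
# subdivides the phantom edge above the root, making p sister to
# everything else.  Regrafts that recreate the original tree are
# excluded, and distinct (prune, regraft) pairs yielding the same
# topology are merged.
#
# OLA move: change exactly one entry of the tree's OLA code to
# another valid value; the neighbor is the decoded vector.

# ---- NNI ----------------------------------------------------------

# Deterministic move list: internal non-root nodes ordered by
# canonical label ascending; within a node, variant 1 exchanges the
# child with the smaller clade-founder with the node's sibling,
# variant 2 the other child.
.nni_moves_tr <- function(tr, cn) {
  n <- tr$n
  if (n < 3L) return(NULL)
  ints <- (n + 1L):(2L * n - 1L)
  vs <- ints[ints != tr$root]
  vs <- vs[order(cn$lab[vs])]
  list(v = rep(vs, each = 2L), variant = rep(1:2, times = length(vs)))
}

.nni_apply_tr <- function(tr, v, variant, founder) {
  u <- tr$par[v]
  s <- .other_kid(tr, u, v)
  c1 <- tr$kid1[v]; c2 <- tr$kid2[v]
  if (founder[c2] < founder[c1]) { tmp <- c1; c1 <- c2; c2 <- tmp }
  cc <- if (variant == 1L) c1 else c2
  tr <- .swap_kid(tr, u, s, cc)
  tr <- .swap_kid(tr, v, cc, s)
  tr$par[cc] <- u
  tr$par[s] <- v
  tr
}

#' All NNI neighbors of a tree
#'
#' Enumerates the \eqn{2(n-2)} nearest-neighbor-interchange moves
#' (two per internal edge) in a deterministic order, and the tree each
#' produces.  Moves are reported by the canonical labels of the edge's
#' endpoints and of the grandchild that is exchanged with the edge's
#' sibling subtree.
#'
#' @param t a `"phylo"` tree with integer tip labels, `n >= 3`.
#' @return a list of entries `list(move, tree)`, where `move` has
#'   fields `edge` (canonical labels `c(parent, child)` of the
#'   internal edge) and `swapped` (label of the exchanged grandchild);
#'   empty list when `n < 3`.
#' @examples
#' nb <- nni_neighbors(parse_newick("((0,1),2);"))
#' sapply(nb, function(x) write_newick(x$tree))
#' @export
nni_neighbors <- function(t) {
  tr <- .phylo_to_tr(t)
  if (tr$n < 3L) return(list())
  cn <- .tr_canon(tr)
  mv <- .nni_moves_tr(tr, cn)
  lapply(seq_along(mv$v), function(j) {
    v <- mv$v[j]
    tr2 <- .nni_apply_tr(tr, v, mv$variant[j], cn$founder)
    c1 <- tr$kid1[v]; c2 <- tr$kid2[v]
    if (cn$founder[c2] < cn$founder[c1]) { tmp <- c1; c1 <- c2; c2 <- tmp }
    cc <- if (mv$variant[j] == 1L) c1 else c2
    list(move = list(edge = c(cn$lab[tr$par[v]], cn$lab[v]),
                     swapped = cn$lab[cc]),
         tree = .tr_to_phylo(tr2))
  })
}

#' Draw one NNI neighbor uniformly at random
#'
#' Uniform over the \eqn{2(n-2)} moves (not over distinct resulting
#' topologies, matching expectation bounds that average over moves).
#'
#' @inheritParams nni_neighbors
#' @return a `"phylo"` tree differing from `t` by one NNI move.
#' @export
random_nni_neighbor <- function(t) {
  .tr_to_phylo(.random_nni_tr(.phylo_to_tr(t)))
}

.random_nni_tr <- function(tr, cn = NULL) {
  if (tr$n < 3L)
    stop("range error: NNI moves need at least 3 leaves")
  if (is.null(cn)) cn <- .tr_canon(tr)
  mv <- .nni_moves_tr(tr, cn)
  j <- sample.int(length(mv$v), 1L)
  .nni_apply_tr(tr, mv$v[j], mv$variant[j], cn$founder)
}

# ---- rooted SPR ---------------------------------------------------

# ids of all nodes in the subtree rooted at p
.tr_subtree_ids <- function(tr, p) {
  out <- integer(0)
  stack <- p
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    if (tr$kid1[v] > 0L) stack <- c(stack, tr$kid1[v], tr$kid2[v])
  }
  out
}

# Remove the edge above p and suppress its parent q.  Entries for p's
# subtree and q become stale but are left in place; callers must only
# touch nodes of the remaining tree.
.spr_prune_tr <- function(tr, p) {
  q <- tr$par[p]
  s <- .other_kid(tr, q, p)
  g <- tr$par[q]
  tr$par[s] <- g
  if (g == 0L) tr$root <- s else tr <- .swap_kid(tr, g, q, s)
  list(tr = tr, q = q, s = s)
}

# Reattach p by subdividing the edge above x, reusing q's id for the
# new internal node.
.spr_attach_tr <- function(rem, p, q, x) {
  tr <- rem
  pw <- tr$par[x]
  tr$kid1[q] <- x
  tr$kid2[q] <- p
  tr$par[x] <- q
  tr$par[p] <- q
  tr$par[q] <- pw
  if (pw == 0L) tr$root <- q else tr <- .swap_kid(tr, pw, x, q)
  tr
}

# Exhaustive distinct SPR neighborhood.  Returns parallel lists:
# keys (OLA code strings, the canonical form), trees (tr), moves
# (prune/regraft canonical labels).  Duplicated topologies keep the
# first (prune, regraft) pair that produced them.
.spr_enum_tr <- function(tr) {
  n <- tr$n
  if (n < 3L)
    return(list(keys = character(0), trees = list(), moves = list()))
  cn <- .tr_canon(tr)
  m <- 2L * n - 1L
  self <- .code_key(.encode_tr(tr))
  seen <- new.env(parent = emptyenv())
  keys <- character(0); trees <- list(); moves <- list()
  for (p in seq_len(m)) {
    if (p == tr$root) next
    sub <- .tr_subtree_ids(tr, p)
    pr <- .spr_prune_tr(tr, p)
    q <- pr$q
    targets <- setdiff(seq_len(m), c(sub, q, pr$s))
    for (x in targets) {
      t2 <- .spr_attach_tr(pr$tr, p, q, x)
      key <- .code_key(.encode_tr(t2))
      if (key == self || !is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      keys <- c(keys, key)
      trees[[length(trees) + 1L]] <- t2
      moves[[length(moves) + 1L]] <-
        list(prune = cn$lab[p], regraft = cn$lab[x])
    }
  }
  list(keys = keys, trees = trees, moves = moves)
}

#' All distinct SPR neighbors of a tree
#'
#' Enumerates every single rooted-SPR rearrangement under the planted
#' convention (the phantom edge above the root is a legal regraft
#' target), excludes regrafts that recreate the input, and merges
#' duplicate resulting topologies.
#'
#' @param t a `"phylo"` tree with integer tip labels, `n >= 3`.
#' @return a list of entries `list(move, tree)`; `move` holds the
#'   canonical labels of the pruned node (`prune`) and of the node
#'   above whose parent edge it was regrafted (`regraft`), for one
#'   representative move per distinct topology.
#' @export
spr_neighbors <- function(t) {
  tr <- .phylo_to_tr(t)
  enum <- .spr_enum_tr(tr)
  lapply(seq_along(enum$keys), function(j) {
    list(move = enum$moves[[j]], tree = .tr_to_phylo(enum$trees[[j]]))
  })
}

# Uniform sampling over *distinct* SPR neighbor topologies without
# enumerating them.  Valid (prune p, regraft x) pairs number
# P = sum_p (2n - 3 - m_p), with m_p the node count of p's subtree.
# Each NNI neighbor arises from exactly three pairs (prune a
# grandchild down to its "nephew", prune the nephew up to the "aunt",
# or prune the sibling above the grandparent); every other pair gives
# a unique topology.  Hence there are D = P - 2K distinct neighbors,
# K = 2(n-2) of them NNI.  Sample: with probability K/D a uniform NNI
# move, otherwise a uniform non-NNI pair by rejection.  The premise
# (3-fold NNI multiplicity, uniqueness elsewhere) is verified
# exhaustively against the enumerated neighborhood in the test suite.
.random_spr_tr <- function(tr) {
  n <- tr$n
  if (n < 3L)
    stop("range error: SPR moves need at least 3 leaves")
  m <- 2L * n - 1L
  size <- .tr_sizes(tr)
  cand <- setdiff(seq_len(m), tr$root)
  cp <- 2L * n - 3L - size[cand]
  P <- sum(cp)
  K <- 2L * (n - 2L)
  D <- P - 2L * K
  if (stats::runif(1) < K / D)
    return(.random_nni_tr(tr))
  repeat {
    p <- cand[sample.int(length(cand), 1L, prob = cp)]
    sub <- .tr_subtree_ids(tr, p)
    q <- tr$par[p]
    s <- .other_kid(tr, q, p)
    targets <- setdiff(seq_len(m), c(sub, q, s))
    x <- targets[sample.int(length(targets), 1L)]
    # reject NNI-form pairs (handled by the NNI branch above)
    g <- tr$par[q]
    nni_pair <-
      (tr$par[x] == s) ||                        # down to a nephew
      (g > 0L && x == .other_kid(tr, g, q)) ||   # up to the aunt
      (g > 0L && x == g)                         # sibling above grandparent
    if (!nni_pair) {
      pr <- .spr_prune_tr(tr, p)
      return(.spr_attach_tr(pr$tr, p, q, x))
    }
  }
}

#' Draw one SPR neighbor uniformly at random
#'
#' Uniform over the distinct single-SPR neighbor topologies (the
#' deduplicated neighborhood of [spr_neighbors()]), computed without
#' enumerating the neighborhood, so sampling is cheap even for large
#' trees.
#'
#' @inheritParams nni_neighbors
#' @return a `"phylo"` tree differing from `t` by one SPR move.
#' @export
random_spr_neighbor <- function(t) {
  .tr_to_phylo(.random_spr_tr(.phylo_to_tr(t)))
}

#' Random walk in tree space under SPR moves
#'
#' @param t starting `"phylo"` tree, `n >= 3`.
#' @param steps number of moves, `>= 0`.
#' @return list of `steps + 1` trees, starting with `t`, each
#'   differing from its predecessor by one uniform SPR move.
#' @export
spr_walk <- function(t, steps) {
  if (length(steps) != 1L || steps != trunc(steps) || steps < 0L)
    stop("range error: steps must be a non-negative integer")
  tr <- .phylo_to_tr(t)
  out <- vector("list", steps + 1L)
  out[[1L]] <- .tr_to_phylo(tr)
  for (j in seq_len(steps)) {
    tr <- .random_spr_tr(tr)
    out[[j + 1L]] <- .tr_to_phylo(tr)
  }
  out
}

# ---- OLA moves ----------------------------------------------------

#' All OLA neighbors of a tree
#'
#' An OLA move replaces one entry of the tree's code with another
#' valid value.  Position 1 admits no alternative (\eqn{a_1 = 0}), so
#' a tree on \eqn{n} leaves has \eqn{\sum_{i=2}^{n-1} (2i - 2)}
#' OLA neighbors, each at OLA distance exactly 1.
#'
#' @inheritParams nni_neighbors
#' @return a list of entries `list(move, tree)`; `move` has fields
#'   `position` and `new_value`.
#' @export
ola_neighbors <- function(t) {
  a <- encode(t)
  n <- length(a) + 1L
  if (n < 3L) return(list())
  out <- list()
  for (i in 2L:(n - 1L)) {
    for (val in setdiff((-(i - 1L)):(i - 1L), a[i])) {
      b <- a
      b[i] <- val
      out[[length(out) + 1L]] <-
        list(move = list(position = i, new_value = val),
             tree = decode(b))
    }
  }
  out
}

#' Draw one OLA neighbor uniformly at random
#'
#' Uniform over all vectors at Hamming distance 1 from the tree's
#' code: position \eqn{i} is chosen with probability proportional to
#' its \eqn{2i - 2} alternative values, then the value uniformly.
#'
#' @inheritParams nni_neighbors
#' @return a `"phylo"` tree at OLA distance 1 from `t`.
#' @export
random_ola_neighbor <- function(t) {
  a <- encode(t)
  .tr_to_phylo(.decode_tr(.random_ola_code(a)))
}

.random_ola_code <- function(a) {
  n <- length(a) + 1L
  if (n < 3L)
    stop("range error: OLA moves need at least 3 leaves")
  pos <- 2L:(n - 1L)
  i <- if (length(pos) == 1L) pos else
    pos[sample.int(length(pos), 1L, prob = 2L * pos - 2L)]
  alt <- setdiff((-(i - 1L)):(i - 1L), a[i])
  a[i] <- alt[sample.int(length(alt), 1L)]
  a
}

# ---- exact SPR distance (breadth-first search) --------------------

# Distinct-neighbor code keys of the tree encoded by `key`, memoized
# in `cache` (an environment) so repeated queries around the same
# region of tree space expand each topology at most once.
.spr_neighbor_keys <- function(key, cache) {
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  keys <- .spr_enum_tr(.decode_tr(.key_code(key)))$keys
  cache[[key]] <- keys
  keys
}

#' Exact SPR distance between two small trees
#'
#' Breadth-first search in the unit-SPR graph, using OLA codes as
#' canonical keys for visited topologies.  Exact but exponential in
#' the distance, hence guarded to small trees.
#'
#' @param t1,t2 `"phylo"` trees on the same leaf set `0..n-1`.
#' @param max_n guard on the number of leaves (default 10).
#' @param cache optional environment memoizing neighborhood
#'   expansions across calls (create with `new.env()`); useful when
#'   computing many distances between nearby trees.
#' @return the length of a shortest path of rooted SPR moves; 0 iff
#'   the trees are equal.
#' @export
spr_distance_exact <- function(t1, t2, max_n = 10L, cache = NULL) {
  a <- .phylo_to_tr(t1)
  b <- .phylo_to_tr(t2)
  if (a$n != b$n)
    stop("incompatible trees: different leaf counts")
  if (a$n > max_n)
    stop("too large for exact SPR: n = ", a$n, " exceeds guard ", max_n)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  .spr_dist_keys(.code_key(.encode_tr(a)), .code_key(.encode_tr(b)), cache)
}

.spr_dist_keys <- function(k1, k2, cache) {
  if (k1 == k2) return(0L)
  visited <- new.env(parent = emptyenv())
  visited[[k1]] <- TRUE
  front <- k1
  d <- 0L
  while (length(front)) {
    d <- d + 1L
    nbrs <- unique(unlist(lapply(front, .spr_neighbor_keys, cache = cache),
                          use.names = FALSE))
    if (k2 %in% nbrs) return(d)
    fresh <- nbrs[vapply(nbrs, function(k) is.null(visited[[k]]),
                         logical(1))]
    for (k in fresh) visited[[k]] <- TRUE
    front <- fresh
  }
  stop("unreachable: SPR graph is connected")   # cannot happen
}
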