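# Internal array representation of a rooted binary leaf-ordered tree.
#
# A "tr" is a plain list:
#   n    -- number of leaves
#   par  -- integer(2n-1), parent node id (0 for the root)
#   kid1 -- integer(2n-1), first child id (0 for leaves)
#   kid2 -- integer(2n-1), second child id (0 for leaves)
#   root -- id of the root node
# Node ids: leaf with label L has id L + 1 (ids 1..n); internal nodes
# occupy ids n+1 .. 2n-1 in no particular order.  All core algorithms
# (labeling, encoding, decoding, rearrangements) run on this flat form
# so that each step is O(1) array arithmetic; "phylo" objects are only
# produced/consumed at the user-facing boundary.

.tr_new <- function(n) {
  m <- 2L * n - 1L
  list(n = n, par = integer(m), kid1 = integer(m), kid2 = integer(m),
       root = 1L)
}

# Preorder node ids, iteratively (no recursion: caterpillar trees on
# 10^5 leaves would blow the call stack).  If `founder` is supplied,
# the child whose clade-founder is smaller is visited first, which
# makes downstream output canonical.
.tr_preorder <- function(tr, founder = NULL) {
  n <- tr$n
  m <- 2L * n - 1L
  out <- integer(m)
  stack <- integer(m)
  stack[1L] <- tr$root
  top <- 1L
  k <- 0L
  kid1 <- tr$kid1
  kid2 <- tr$kid2
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    out[k] <- v
    c1 <- kid1[v]
    if (c1 > 0L) {
      c2 <- kid2[v]
      if (!is.null(founder) && founder[c2] < founder[c1]) {
        tmp <- c1; c1 <- c2; c2 <- tmp
      }
      # push second child first so the first is popped first
      top <- top + 1L; stack[top] <- c2
      top <- top + 1L; stack[top] <- c1
    }
  }
  out[seq_len(k)]
}

# Clade-founder labels: minimum leaf label in the clade below each
# node.  One pass over the reverse preorder (children before parents).
.tr_founder <- function(tr, pre = NULL) {
  if (is.null(pre)) pre <- .tr_preorder(tr)
  n <- tr$n
  founder <- integer(2L * n - 1L)
  founder[seq_len(n)] <- 0:(n - 1L)
  kid1 <- tr$kid1
  kid2 <- tr$kid2
  for (v in rev(pre)) {
    if (kid1[v] > 0L)
      founder[v] <- min(founder[kid1[v]], founder[kid2[v]])
  }
  founder
}

# Canonical labels for every node: leaves keep their leaf label,
# internal node v gets -(clade-splitter of v) where the clade-splitter
# is the larger of the two children's clade-founder labels.  Returns
# list(founder, splitter, lab, label2node); label2node maps a label L
# (in -(n-1)..n-1) to a node id via index L + n.
.tr_canon <- function(tr) {
  n <- tr$n
  m <- 2L * n - 1L
  pre <- .tr_preorder(tr)
  founder <- .tr_founder(tr, pre)
  splitter <- integer(m)
  lab <- integer(m)
  lab[seq_len(n)] <- 0:(n - 1L)
  kid1 <- tr$kid1
  kid2 <- tr$kid2
  internal <- pre[kid1[pre] > 0L]
  if (length(internal)) {
    splitter[internal] <- pmax(founder[kid1[internal]],
                               founder[kid2[internal]])
    lab[internal] <- -splitter[internal]
  }
  label2node <- integer(m)
  label2node[lab + n] <- seq_len(m)
  list(founder = founder, splitter = splitter, lab = lab,
       label2node = label2node)
}

# Number of edges from the root down to the farthest leaf.
.tr_height <- function(tr) {
  if (tr$n == 1L) return(0L)
  pre <- .tr_preorder(tr)
  depth <- integer(2L * tr$n - 1L)
  par <- tr$par
  for (v in pre) if (v != tr$root) depth[v] <- depth[par[v]] + 1L
  max(depth[seq_len(tr$n)])
}

# Subtree node counts (number of nodes, leaves + internals, at or
# below each node).
.tr_sizes <- function(tr) {
  pre <- .tr_preorder(tr)
  size <- rep(1L, 2L * tr$n - 1L)
  kid1 <- tr$kid1
  kid2 <- tr$kid2
  for (v in rev(pre)) {
    if (kid1[v] > 0L) size[v] <- 1L + size[kid1[v]] + size[kid2[v]]
  }
  size
}

.other_kid <- function(tr, p, v) {
  if (tr$kid1[p] == v) tr$kid2[p] else tr$kid1[p]
}

# Replace child `old` of node p by `new` (p > 0 assumed).
.swap_kid <- function(tr, p, old, new) {
  if (tr$kid1[p] == old) tr$kid1[p] <- new else tr$kid2[p] <- new
  tr
}

# ---- phylo <-> tr conversion --------------------------------------

.is_single_leaf <- function(phy) {
  inherits(phy, "phylo") && length(phy$tip.label) == 1L
}

.single_leaf_phylo <- function() {
  structure(list(edge = matrix(integer(0), 0L, 2L),
                 tip.label = "0", Nnode = 0L),
            class = "phylo")
}

.phylo_to_tr <- function(phy) {
  if (!inherits(phy, "phylo"))
    stop("parse error: not a \"phylo\" tree object")
  n <- length(phy$tip.label)
  if (n == 0L) stop("parse error: tree has no leaves")
  labs <- suppressWarnings(as.integer(phy$tip.label))
  if (anyNA(labs) || !identical(sort(labs), 0:(n - 1L)))
    stop("label error: leaf labels must be exactly the integers 0..n-1")
  if (n == 1L) {
    tr <- .tr_new(1L)
    return(tr)
  }
  if (is.null(phy$Nnode) || phy$Nnode != n - 1L)
    stop("not binary: tree must have exactly n-1 internal nodes")
  edge <- phy$edge
  if (nrow(edge) != 2L * n - 2L)
    stop("not binary: unexpected edge count")
  deg <- tabulate(edge[, 1L], nbins = 2L * n - 1L)
  if (any(deg[(n + 1L):(2L * n - 1L)] != 2L))
    stop("not binary: every internal node must have exactly 2 children")
  # map phylo ids to tr ids: tip i -> its label + 1, internals unchanged
  map <- c(labs + 1L, (n + 1L):(2L * n - 1L))
  tr <- .tr_new(n)
  u <- map[edge[, 1L]]
  v <- map[edge[, 2L]]
  tr$par[v] <- u
  first <- !duplicated(u)
  tr$kid1[u[first]] <- v[first]
  tr$kid2[u[!first]] <- v[!first]
  # root: the internal node with no parent
  ints <- (n + 1L):(2L * n - 1L)
  tr$root <- ints[tr$par[ints] == 0L][1L]
  if (is.na(tr$root)) stop("parse error: no root found")
  tr
}

# Convert back to an ape "phylo".  Internal nodes are renumbered
# n+1, n+2, ... in canonical preorder (children ordered by
# clade-founder), so the output is deterministic for a given topology.
.tr_to_phylo <- function(tr) {
  n <- tr$n
  if (n == 1L) return(.single_leaf_phylo())
  founder <- .tr_founder(tr)
  pre <- .tr_preorder(tr, founder)
  newid <- integer(2L * n - 1L)
  newid[seq_len(n)] <- seq_len(n)
  ints <- pre[pre > n]
  newid[ints] <- n + seq_along(ints)
  par <- tr$par
  edge <- matrix(0L, 2L * n - 2L, 2L)
  k <- 0L
  for (v in pre) {
    if (v != tr$root) {
      k <- k + 1L
      edge[k, 1L] <- newid[par[v]]
      edge[k, 2L] <- newid[v]
    }
  }
  structure(list(edge = edge, tip.label = as.character(0:(n - 1L)),
                 Nnode = n - 1L),
            class = "phylo", order = "cladewise")
}
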