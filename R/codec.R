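# Ordered-leaf-attachment (OLA) codec.
#
# A rooted binary tree on leaves 0..n-1, taken with that leaf order,
# corresponds to exactly one integer vector (a_1, ..., a_{n-1}) with
# -i < a_i < i.  Entry a_i is the label of the node that leaf i is
# attached next to when the tree is grown leaf by leaf: a leaf label
# if the sister is a leaf, or the canonical (negative) label if the
# sister is an internal node.  Both directions run in time linear in
# the number of leaves.

# -- core, on the flat array form -----------------------------------

.encode_tr <- function(tr) {
  n <- tr$n
  if (n == 1L) return(integer(0))
  cn <- .tr_canon(tr)
  lab <- cn$lab
  par <- tr$par
  kid1 <- tr$kid1
  kid2 <- tr$kid2
  root <- tr$root
  a <- integer(n - 1L)
  # peel leaves n-1, n-2, ..., 1; leaf i has node id i + 1
  for (i in (n - 1L):1L) {
    v <- i + 1L
    p <- par[v]
    s <- if (kid1[p] == v) kid2[p] else kid1[p]
    a[i] <- lab[s]
    g <- par[p]
    par[s] <- g
    if (g == 0L) {
      root <- s
    } else if (kid1[g] == p) {
      kid1[g] <- s
    } else {
      kid2[g] <- s
    }
  }
  a
}

.decode_tr <- function(a) {
  n <- length(a) + 1L
  tr <- .tr_new(n)
  if (n == 1L) return(tr)
  par <- tr$par
  kid1 <- tr$kid1
  kid2 <- tr$kid2
  root <- 1L            # the single-leaf tree {0}
  for (i in seq_len(n - 1L)) {
    ai <- a[i]
    target <- if (ai >= 0L) ai + 1L else n - ai   # leaf ai, or internal -ai
    w <- n + i           # new internal node, canonical label -i
    leaf <- i + 1L
    p <- par[target]
    par[w] <- p
    par[target] <- w
    par[leaf] <- w
    kid1[w] <- target
    kid2[w] <- leaf
    if (p == 0L) {
      # the target is the current root: its "parent edge" is the
      # phantom edge above the root, so the new node becomes the root
      root <- w
    } else if (kid1[p] == target) {
      kid1[p] <- w
    } else {
      kid2[p] <- w
    }
  }
  tr$par <- par
  tr$kid1 <- kid1
  tr$kid2 <- kid2
  tr$root <- root
  tr
}

.code_key <- function(a) paste(a, collapse = ",")
.key_code <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

# -- public API -----------------------------------------------------

#' Test whether an integer vector is a valid OLA code
#'
#' A vector \eqn{(a_1, \ldots, a_{n-1})} is a valid ordered-leaf-
#' attachment code if and only if \eqn{-i < a_i < i} for every
#' position \eqn{i}.  In particular \eqn{a_1 = 0} always.  The set of
#' valid vectors of length \eqn{n-1} has cardinality
#' \eqn{(2n-3)!! = 1 \cdot 3 \cdots (2n-3)}, matching the number of
#' rooted binary leaf-ordered topologies on \eqn{n} leaves.
#'
#' @param v numeric or integer vector (whole numbers required).
#' @return `TRUE` or `FALSE`.  Non-numeric or fractional input is an
#'   error (`"type error"`).
#' @examples
#' is_valid_vector(c(0, 0, 2, 1))   # TRUE
#' is_valid_vector(c(0, -2))        # FALSE: requires -2 < a_2 < 2
#' @export
is_valid_vector <- function(v) {
  if (length(v) == 0L) return(TRUE)
  if (!is.numeric(v) || anyNA(v) || any(v != trunc(v)))
    stop("type error: OLA vector entries must be whole numbers")
  i <- seq_along(v)
  all(-i < v & v < i)
}

#' Encode a tree as its OLA integer vector
#'
#' Computes the canonical internal-node labels once, then deconstructs
#' the tree by removing leaves \eqn{n-1, n-2, \ldots, 1}; at each step
#' the label of the removed leaf's sister node is recorded as
#' \eqn{a_i}, and the leaf and its parent are deleted (the sister is
#' reconnected to the grandparent, or becomes the root).  Runs in time
#' linear in the number of leaves.
#'
#' @param t a rooted binary tree of class `"phylo"` whose tip labels
#'   are the integers `0..n-1` (see [parse_newick()]).
#' @return integer vector of length \eqn{n-1} in the valid set;
#'   `integer(0)` for the degenerate single-leaf tree.
#' @seealso [decode()], [ola_distance()]
#' @examples
#' encode(parse_newick("((0,(2,3)),(1,4));"))   # 0 0 2 1
#' encode(parse_newick("((0,((1,3),4)),2);"))   # 0 -1 1 -3
#' @export
encode <- function(t) {
  .encode_tr(.phylo_to_tr(t))
}

#' Decode an OLA vector into its tree
#'
#' Starting from the single-leaf tree \{0\}, for each
#' \eqn{i = 1, \ldots, n-1} the node currently labeled \eqn{a_i} is
#' located, its parent edge is subdivided by a new internal node with
#' canonical label \eqn{-i}, and leaf \eqn{i} is hung below the new
#' node.  When the target node is the current root, its phantom parent
#' edge is subdivided: the new internal node becomes the root, with
#' the old root and the new leaf as children.  `encode(decode(v))`
#' returns `v` for every valid vector.
#'
#' @param v integer vector in the valid set (see [is_valid_vector()]).
#' @return a `"phylo"` tree with tip labels `0..n-1`.
#' @examples
#' decode(c(0, -1))          # the 3-leaf tree ((0,1),2)
#' write_newick(decode(c(0, 0, 2, 1)))
#' @export
decode <- function(v) {
  v <- as.integer(v)
  if (!is_valid_vector(v))
    stop("invalid OLA vector: entries must satisfy -i < a_i < i")
  .tr_to_phylo(.decode_tr(v))
}

#' Enumerate all valid OLA vectors of a given tree size
#'
#' Produces every valid vector \eqn{(a_1, \ldots, a_{n-1})} exactly
#' once, in lexicographic order, as the rows of an integer matrix.
#' There are \eqn{(2n-3)!!} of them, one per rooted binary
#' leaf-ordered topology on \eqn{n} leaves.
#'
#' @param n number of leaves; guarded to `2 <= n <= 8` (the count
#'   grows as a double factorial).
#' @return integer matrix with \eqn{(2n-3)!!} rows and \eqn{n-1}
#'   columns.
#' @examples
#' enumerate_vectors(3)   # rows (0,-1), (0,0), (0,1)
#' nrow(enumerate_vectors(5))   # 105
#' @export
enumerate_vectors <- function(n) {
  if (length(n) != 1L || n != trunc(n) || n < 2L || n > 8L)
    stop("range error: n must be an integer in 2..8")
  n <- as.integer(n)
  mat <- matrix(0L, 1L, 1L)
  if (n == 2L) return(mat)
  for (i in 2L:(n - 1L)) {
    vals <- (-(i - 1L)):(i - 1L)
    r <- nrow(mat)
    mat <- cbind(mat[rep(seq_len(r), each = length(vals)), , drop = FALSE],
                 rep(vals, times = r))
  }
  dimnames(mat) <- NULL
  mat
}

#' Draw a uniformly random valid OLA vector
#'
#' Entry \eqn{a_i} is drawn uniformly and independently from
#' \eqn{\{-(i-1), \ldots, i-1\}}, so every valid vector has
#' probability \eqn{1/(2n-3)!!}.  Uses R's global random number
#' generator; call [set.seed()] for reproducibility.
#'
#' @param n number of leaves, `n >= 2`.
#' @return integer vector of length \eqn{n-1}.
#' @export
random_vector <- function(n) {
  if (length(n) != 1L || n != trunc(n) || n < 2L)
    stop("range error: n must be an integer >= 2")
  n <- as.integer(n)
  a <- integer(n - 1L)
  for (i in seq_len(n - 1L))
    a[i] <- sample.int(2L * i - 1L, 1L) - i
  a
}

#' Draw a uniformly random tree topology
#'
#' Decodes a uniformly random valid OLA vector.  Because the codec is
#' a bijection, the result is uniform over all \eqn{(2n-3)!!} rooted
#' binary leaf-ordered topologies on \eqn{n} leaves.
#'
#' @inheritParams random_vector
#' @return a `"phylo"` tree with tip labels `0..n-1`.
#' @examples
#' set.seed(1)
#' write_newick(random_tree(5))
#' @export
random_tree <- function(n) {
  decode(random_vector(n))
}

#' Parse an OLA vector from text
#'
#' Accepts comma-separated integers, with optional surrounding
#' parentheses or brackets and whitespace, e.g. `"0,0,2,1"` or
#' `"(0, -1, 1, -3)"`.
#'
#' @param text a single character string.
#' @return integer vector (not validity-checked; see
#'   [is_valid_vector()]).
#' @export
parse_vector <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("type error: expected a single string")
  s <- gsub("^[\\s\\(\\[]+|[\\s\\)\\]]+$", "", text, perl = TRUE)
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  out <- suppressWarnings(as.integer(parts))
  if (length(out) == 0L || anyNA(out))
    stop("parse error: could not read comma-separated integers")
  out
}

#' Format an OLA vector as text
#'
#' @param v integer vector.
#' @return a single string of bare comma-separated integers.
#' @export
format_vector <- function(v) paste(as.integer(v), collapse = ",")
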