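# Canonical internal-node labels.
#
# Two linear-time traversals label every node of a leaf-ordered tree:
# a post-order (root-ward) pass assigns each node its clade-founder
# (smallest leaf label below it), then each internal node's
# clade-splitter is the larger of its two children's clade-founders,
# and the canonical label is minus the clade-splitter.  The canonical
# labels of the internal nodes are exactly {-1, ..., -(n-1)}, each
# used once: -i marks the internal node that was created when leaf i
# joined the growing tree.

#' Canonical internal-node labeling of a tree
#'
#' Computes, for every node of `t`, the clade-founder label (minimum
#' leaf label in its clade), and for every internal node the
#' clade-splitter label (maximum of the two children's clade-founders)
#' and the canonical label (minus the clade-splitter).  The canonical
#' labels of the \eqn{n - 1} internal nodes are a bijection onto
#' \eqn{\{-1, \ldots, -(n-1)\}}.
#'
#' @param t a `"phylo"` tree with integer tip labels `0..n-1` and
#'   `n >= 2` leaves.
#' @return an object of class `"ola_labeling"`: a list with integer
#'   vectors `founder`, `splitter` and `canonical`, each indexed by
#'   the node numbering of `t` (tips `1..n`, internals `n+1..2n-1`);
#'   `splitter` and `canonical` are `NA` at tips.
#' @examples
#' cl <- canonical_labels(parse_newick("((0,1),2);"))
#' cl$canonical   # NA NA NA -2 -1  (root is node 4)
#' @export
canonical_labels <- function(t) {
  tr <- .phylo_to_tr(t)
  n <- tr$n
  if (n < 2L)
    stop("no internal nodes: labeling needs at least 2 leaves")
  cn <- .tr_canon(tr)
  # map tr node ids back to the phylo numbering of `t`
  labs <- as.integer(t$tip.label)
  m <- 2L * n - 1L
  map <- c(labs + 1L, (n + 1L):m)   # phylo id -> tr id
  founder <- cn$founder[map]
  splitter <- ifelse(seq_len(m) <= n, NA_integer_, cn$splitter[map])
  canonical <- ifelse(seq_len(m) <= n, NA_integer_, cn$lab[map])
  structure(list(founder = founder, splitter = splitter,
                 canonical = canonical, n = n),
            class = "ola_labeling")
}

#' @export
print.ola_labeling <- function(x, ...) {
  cat("Canonical labeling of a tree on", x$n, "leaves\n")
  ints <- which(!is.na(x$canonical))
  df <- data.frame(node = ints,
                   founder = x$founder[ints],
                   splitter = x$splitter[ints],
                   canonical = x$canonical[ints])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Look up the node carrying a given label
#'
#' Labels in `0..n-1` are leaf labels; labels in `-(n-1)..-1` are
#' canonical internal labels.
#'
#' @param labeling an `"ola_labeling"` from [canonical_labels()].
#' @param t the tree the labeling was computed from.
#' @param label integer in `-(n-1)..-1` or `0..n-1`.
#' @return the node number (in the numbering of `t`) carrying that
#'   label.
#' @export
node_by_label <- function(labeling, t, label) {
  if (!inherits(labeling, "ola_labeling"))
    stop("type error: expected an \"ola_labeling\"")
  n <- labeling$n
  if (length(label) != 1L || label != trunc(label) ||
      label <= -n || label >= n)
    stop("label error: label must lie in -(n-1)..(n-1)")
  label <- as.integer(label)
  if (label >= 0L) {
    which(t$tip.label == as.character(label))[1L]
  } else {
    which(labeling$canonical == label)[1L]
  }
}
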