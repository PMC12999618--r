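# Rooted binary leaf-ordered trees: Newick I/O, validation, height,
# restriction, isomorphism, leaf relabeling.
#
# The working representation is an ape "phylo" object whose tip
# labels are the character strings "0".."n-1"; the integer label is
# the leaf's position in the linear leaf order.  Named taxa are
# translated to integer labels at the I/O boundary only, via a taxon
# order (a character vector; position i+1 holds the taxon with label
# i).

#' Read a taxon order file
#'
#' One taxon name per line; the taxon on line \eqn{i} receives
#' integer leaf label \eqn{i - 1}.  Blank lines and leading/trailing
#' whitespace are ignored.
#'
#' @param path path to a plain-text file.
#' @return character vector of taxon names.
#' @export
read_taxon_order <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (anyDuplicated(x))
    stop("label error: duplicate taxon names in order file")
  if (length(x) == 0L) stop("label error: empty taxon order")
  x
}

#' Parse a Newick string into a leaf-ordered tree
#'
#' Reads a rooted binary topology.  Branch lengths and internal node
#' names in the input are accepted and discarded: the encoding is
#' purely topological.  If `order` is given, taxon names are mapped
#' to integer labels by their position in it (first taxon is leaf 0);
#' otherwise the tip labels themselves must be the integers `0..n-1`.
#'
#' @param text a Newick string, e.g. `"((0,1),2);"`.
#' @param order optional character vector of taxon names defining the
#'   leaf order (see [read_taxon_order()]).
#' @return a `"phylo"` tree with tip labels `"0".."n-1"`, children
#'   in canonical order (smaller clade-founder first).
#' @section Errors: multifurcations raise `"not binary"`; duplicate or
#'   unknown taxa raise `"label error"`; malformed text raises
#'   `"parse error"`.
#' @examples
#' parse_newick("((0,1),2);")
#' parse_newick("((A:1,B:2):3,C:4);", order = c("A", "B", "C"))
#' @export
parse_newick <- function(text, order = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("parse error: expected a single Newick string")
  text <- trimws(text)
  # a bare "label;" is the degenerate single-leaf tree, which ape
  # cannot represent cleanly
  if (grepl("^[^(),;:]+(:[0-9.eE+-]+)?;?$", text)) {
    nm <- sub(":.*$", "", sub(";$", "", text))
    nm <- .map_taxa(nm, order)
    if (!identical(nm, "0"))
      stop("label error: single leaf must be labeled 0")
    return(.single_leaf_phylo())
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("parse error: malformed Newick string")
  phy$tip.label <- .map_taxa(phy$tip.label, order)
  phy$edge.length <- NULL
  phy$node.label <- NULL
  .tr_to_phylo(.phylo_to_tr(phy))
}

# translate taxon names to "0".."n-1" according to `order`
.map_taxa <- function(tips, order) {
  if (anyDuplicated(tips))
    stop("label error: duplicate taxon in tree")
  if (is.null(order)) return(tips)
  if (anyDuplicated(order))
    stop("label error: duplicate taxon names in order")
  idx <- match(tips, order)
  if (anyNA(idx))
    stop("label error: taxon not present in order: ",
         paste(tips[is.na(idx)], collapse = ", "))
  as.character(idx - 1L)
}

#' Write a tree as a canonical Newick string
#'
#' Children are ordered by clade founder (the smallest leaf label in
#' the clade), ascending, so equal topologies always serialize to the
#' same string.  With `annotate = TRUE` the canonical internal-node
#' labels are appended as internal node names, e.g.
#' `"((0,1)-1,2)-2;"` — useful for inspecting the labeling.
#'
#' @param t a `"phylo"` tree with integer tip labels.
#' @param annotate if `TRUE`, include canonical internal labels.
#' @return a single Newick string.
#' @examples
#' write_newick(parse_newick("(2,(1,0));"))   # "((0,1),2);"
#' @export
write_newick <- function(t, annotate = FALSE) {
  tr <- .phylo_to_tr(t)
  n <- tr$n
  if (n == 1L) return("0;")
  cn <- .tr_canon(tr)
  pre <- .tr_preorder(tr, cn$founder)
  # assemble strings bottom-up over the reverse preorder
  txt <- character(2L * n - 1L)
  txt[seq_len(n)] <- as.character(0:(n - 1L))
  kid1 <- tr$kid1
  kid2 <- tr$kid2
  founder <- cn$founder
  for (v in rev(pre)) {
    if (kid1[v] > 0L) {
      c1 <- kid1[v]; c2 <- kid2[v]
      if (founder[c2] < founder[c1]) { tmp <- c1; c1 <- c2; c2 <- tmp }
      tag <- if (annotate) as.character(cn$lab[v]) else ""
      txt[v] <- paste0("(", txt[c1], ",", txt[c2], ")", tag)
    }
  }
  paste0(txt[tr$root], ";")
}

#' Tree height
#'
#' The number of edges on the longest path from the root to a leaf.
#'
#' @param t a `"phylo"` tree with integer tip labels.
#' @return a non-negative integer; 0 for a single-leaf tree.
#' @examples
#' tree_height(parse_newick("((0,1),(2,3));"))   # 2
#' @export
tree_height <- function(t) {
  .tr_height(.phylo_to_tr(t))
}

#' Restrict a tree to its first k leaves
#'
#' Deletes every leaf with label `>= k` and suppresses the resulting
#' one-child internal nodes, giving the induced topology on leaves
#' `0..k-1`.  The OLA code of the restriction is the first
#' \eqn{k - 1} entries of the original code (prefix stability).
#'
#' @param t a `"phylo"` tree with integer tip labels `0..n-1`.
#' @param k number of leaves to keep, `1 <= k < n`.
#' @return a `"phylo"` tree on leaves `0..k-1`.
#' @export
restrict_to_first_k <- function(t, k) {
  tr <- .phylo_to_tr(t)   # validates
  n <- tr$n
  if (length(k) != 1L || k != trunc(k) || k < 1L || k >= n)
    stop("range error: k must satisfy 1 <= k < n")
  k <- as.integer(k)
  if (k == 1L) return(.single_leaf_phylo())
  phy <- .tr_to_phylo(tr)
  kept <- ape::keep.tip(phy, as.character(0:(k - 1L)))
  .tr_to_phylo(.phylo_to_tr(kept))
}

#' Test equality of two trees as leaf-labeled rooted topologies
#'
#' Two trees are equal when they induce the same set of clades
#' (leaf-label sets below internal nodes); the order of children is
#' irrelevant.
#'
#' @param t1,t2 `"phylo"` trees with integer tip labels.
#' @return `TRUE` or `FALSE`.
#' @examples
#' labeled_isomorphic(parse_newick("((0,1),2);"),
#'                    parse_newick("(2,(1,0));"))   # TRUE
#' @export
labeled_isomorphic <- function(t1, t2) {
  a <- .phylo_to_tr(t1)
  b <- .phylo_to_tr(t2)
  if (a$n != b$n) return(FALSE)
  setequal(.clade_keys(a), .clade_keys(b))
}

# one sorted-leaf-set string per internal node
.clade_keys <- function(tr) {
  n <- tr$n
  if (n == 1L) return(character(0))
  pre <- .tr_preorder(tr)
  sets <- vector("list", 2L * n - 1L)
  for (v in seq_len(n)) sets[[v]] <- v - 1L
  kid1 <- tr$kid1; kid2 <- tr$kid2
  for (v in rev(pre)) {
    if (kid1[v] > 0L)
      sets[[v]] <- sort(c(sets[[kid1[v]]], sets[[kid2[v]]]))
  }
  vapply(sets[(n + 1L):(2L * n - 1L)],
         function(s) paste(s, collapse = ","), character(1))
}

#' Relabel leaves by a permutation
#'
#' Applies a permutation of `0..n-1` to the leaf labels: the leaf
#' currently labeled \eqn{i} becomes \eqn{perm_i}.  The tree shape is
#' unchanged; only the leaf order (and hence the OLA code) moves.
#' Used to study how the OLA distance behaves under shuffles of the
#' leaf order.
#'
#' @param t a `"phylo"` tree with integer tip labels.
#' @param perm integer vector of length `n`; `perm[i + 1]` is the new
#'   label of leaf `i`.  Must be a bijection on `0..n-1`.
#' @return a `"phylo"` tree.
#' @export
permute_leaf_labels <- function(t, perm) {
  tr <- .phylo_to_tr(t)   # validates t
  n <- tr$n
  perm <- suppressWarnings(as.integer(perm))
  if (length(perm) != n || anyNA(perm) ||
      !identical(sort(perm), 0:(n - 1L)))
    stop("label error: perm must be a bijection on 0..n-1")
  phy <- .tr_to_phylo(tr)
  phy$tip.label <- as.character(perm[as.integer(phy$tip.label) + 1L])
  .tr_to_phylo(.phylo_to_tr(phy))
}
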