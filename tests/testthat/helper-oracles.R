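# Independent oracles used across the suite.  These deliberately
# avoid the package's array-based tree core: trees are grown as a
# plain label -> parent-label map and serialized recursively, so they
# provide a second, structurally different route to the attachment
# semantics and to the canonical labeling.

# Grow a tree by sequential leaf attachment from a vector: leaf i is
# attached next to the node currently labeled v[i], under a new
# internal node labeled -i.  Returns a named character map
# node-label -> parent-label (NA at the root).
oracle_attach_tree <- function(v) {
  parent <- c("0" = NA_character_)
  for (i in seq_along(v)) {
    tgt <- as.character(v[i])
    w <- as.character(-i)
    leaf <- as.character(i)
    stopifnot(tgt %in% names(parent))
    parent[w] <- parent[[tgt]]
    parent[tgt] <- w
    parent[leaf] <- w
  }
  parent
}

# Sorted leaf set below each internal node, named by internal label.
oracle_clades <- function(parent) {
  labs <- names(parent)
  leaves <- labs[as.integer(labs) >= 0]
  clades <- list()
  for (lf in leaves) {
    x <- lf
    while (!is.na(parent[[x]])) {
      x <- parent[[x]]
      clades[[x]] <- c(clades[[x]], as.integer(lf))
    }
  }
  lapply(clades, sort)
}

# Newick serialization of the parent map (recursive; small n only).
oracle_newick <- function(parent) {
  labs <- names(parent)
  kids <- split(labs[!is.na(parent)], parent[!is.na(parent)])
  ser <- function(x) {
    ch <- kids[[x]]
    if (is.null(ch)) return(x)
    paste0("(", ser(ch[1]), ",", ser(ch[2]), ")")
  }
  root <- labs[is.na(parent)]
  paste0(ser(root), ";")
}

# Grow a Yule-type tree: each new leaf attaches as sister to a
# uniformly chosen existing leaf.  Returns list(v, newick).
oracle_yule <- function(n) {
  parent <- c("0" = NA_character_)
  v <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    existing <- 0:(i - 1L)
    v[i] <- existing[sample.int(i, 1L)]
    parent <- oracle_attach_tree_step(parent, v[i], i)
  }
  list(v = v, newick = oracle_newick(parent))
}

oracle_attach_tree_step <- function(parent, target, i) {
  tgt <- as.character(target)
  w <- as.character(-i)
  leaf <- as.character(i)
  parent[w] <- parent[[tgt]]
  parent[tgt] <- w
  parent[leaf] <- w
  parent
}

# Sorted leaf labels below a node of a "phylo" tree, via ape.
phylo_clade <- function(t, node) {
  n <- length(t$tip.label)
  if (node <= n) return(as.integer(t$tip.label[node]))
  root <- n + 1L
  tips <- if (node == root) t$tip.label
          else ape::extract.clade(t, node)$tip.label
  sort(as.integer(tips))
}

# All tree codes on n leaves, as phylo trees (enumeration shortcut).
all_trees <- function(n) {
  vs <- enumerate_vectors(n)
  lapply(seq_len(nrow(vs)), function(r) decode(vs[r, ]))
}
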