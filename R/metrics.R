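# OLA distance: the Hamming distance between two trees' codes under a
# shared leaf order.  Because the codec is injective, this is a true
# metric on leaf-ordered topologies (identity, symmetry and the
# triangle inequality are inherited from the Hamming metric).

#' OLA distance between two trees
#'
#' The number of positions at which the OLA codes of the two trees
#' differ.  Both trees must be on the same leaf set `0..n-1` taken in
#' the same order.  The distance lies in \eqn{[0, n-2]}: the first
#' code entry is always 0, so at most \eqn{n-2} positions can differ.
#'
#' @param t1,t2 `"phylo"` trees with integer tip labels `0..n-1`.
#' @return a non-negative integer.
#' @examples
#' ola_distance(decode(c(0, 0, 2, 1)), decode(c(0, -1, 1, -3)))  # 3
#' @export
ola_distance <- function(t1, t2) {
  a <- encode(t1)
  b <- encode(t2)
  if (length(a) != length(b))
    stop("incompatible trees: different numbers of leaves")
  sum(a != b)
}

#' OLA distance averaged over shuffled leaf orders
#'
#' The OLA distance depends on the chosen leaf order.  Averaging it
#' over random simultaneous relabelings (the same permutation applied
#' to both trees) gives an order-robust summary that correlates
#' better with SPR distance than any single ordering.
#'
#' @inheritParams ola_distance
#' @param k number of random permutations to average over, `>= 1`.
#' @return the mean OLA distance over `k` shuffles (a number, not
#'   necessarily an integer).
#' @export
shuffled_ola_distance <- function(t1, t2, k) {
  if (length(k) != 1L || k != trunc(k) || k < 1L)
    stop("range error: k must be a positive integer")
  n <- length(t1$tip.label)
  if (n != length(t2$tip.label))
    stop("incompatible trees: different numbers of leaves")
  d <- numeric(k)
  for (j in seq_len(k)) {
    perm <- sample.int(n) - 1L
    d[j] <- ola_distance(permute_leaf_labels(t1, perm),
                         permute_leaf_labels(t2, perm))
  }
  mean(d)
}
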