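# Simulation experiments relating the OLA distance to NNI and SPR
# rearrangements.  Each experiment draws uniformly random focal trees
# (through the codec bijection), samples rearrangement neighbors, and
# summarizes distances per focal tree in a tidy table.  Every row is
# reproducible from (sizes, counts, seed): a single seeded RNG stream
# drives all sampling.

.experiment_table <- function(n, focal_index, seed, statistic_name,
                              value, tree_height) {
  data.frame(n = n, focal_index = focal_index, seed = seed,
             statistic_name = statistic_name, value = value,
             tree_height = tree_height)
}

#' Mean OLA distance to NNI neighbors
#'
#' For each tree size, draws uniformly random focal trees; for each
#' focal tree, draws NNI moves uniformly and records the mean OLA
#' distance between the focal tree and its sampled neighbors.  The
#' expected OLA distance to a uniform NNI neighbor is at most 4 for
#' every focal tree, and in practice the means sit well below that
#' bound.
#'
#' @param sizes integer vector of tree sizes (leaves), within
#'   `[5, 1000]`.
#' @param n_focal focal trees per size (default 50).
#' @param n_neighbors sampled NNI neighbors per focal tree
#'   (default 20).
#' @param seed integer seed; the whole table is a deterministic
#'   function of the arguments.
#' @return a data frame with columns `n`, `focal_index`, `seed`,
#'   `statistic_name` (`"mean_ola_nni"`), `value` and `tree_height`.
#' @examples
#' tab <- experiment_nni_expectation(c(5, 10), n_focal = 5,
#'                                   n_neighbors = 10, seed = 1)
#' aggregate(value ~ n, tab, mean)
#' @export
experiment_nni_expectation <- function(sizes = c(5, 10, 50, 100, 500, 1000),
                                       n_focal = 50, n_neighbors = 20,
                                       seed = 1) {
  if (any(sizes < 5 | sizes > 1000))
    stop("range error: sizes must lie in [5, 1000]")
  set.seed(seed)
  rows <- vector("list", length(sizes) * n_focal)
  k <- 0L
  for (n in as.integer(sizes)) {
    for (f in seq_len(n_focal)) {
      tr <- .decode_tr(random_vector(n))
      a <- .encode_tr(tr)
      cn <- .tr_canon(tr)
      d <- vapply(seq_len(n_neighbors), function(j) {
        sum(.encode_tr(.random_nni_tr(tr, cn)) != a)
      }, numeric(1))
      k <- k + 1L
      rows[[k]] <- .experiment_table(n, f, seed, "mean_ola_nni",
                                     mean(d), .tr_height(tr))
    }
  }
  do.call(rbind, rows)
}

#' Maximum OLA distance to SPR neighbors versus tree height
#'
#' For each focal tree, samples distinct SPR neighbors uniformly and
#' records the maximum OLA distance from the focal tree to a sampled
#' neighbor, together with the focal tree's height: the distance
#' never exceeds twice the height.
#'
#' @param sizes integer vector of tree sizes, within `[5, 500]`.
#' @param n_focal focal trees per size (default 30).
#' @param n_neighbors sampled SPR neighbors per focal tree
#'   (default 30).
#' @inheritParams experiment_nni_expectation
#' @return a data frame as in [experiment_nni_expectation()], with
#'   `statistic_name = "max_ola_spr"`.
#' @export
experiment_spr_max <- function(sizes = c(20, 50, 100, 200),
                               n_focal = 30, n_neighbors = 30,
                               seed = 1) {
  if (any(sizes < 5 | sizes > 500))
    stop("range error: sizes must lie in [5, 500]")
  set.seed(seed)
  rows <- vector("list", length(sizes) * n_focal)
  k <- 0L
  for (n in as.integer(sizes)) {
    for (f in seq_len(n_focal)) {
      tr <- .decode_tr(random_vector(n))
      a <- .encode_tr(tr)
      d <- vapply(seq_len(n_neighbors), function(j) {
        sum(.encode_tr(.random_spr_tr(tr)) != a)
      }, numeric(1))
      k <- k + 1L
      rows[[k]] <- .experiment_table(n, f, seed, "max_ola_spr",
                                     max(d), .tr_height(tr))
    }
  }
  do.call(rbind, rows)
}

#' Mean exact SPR distance to OLA neighbors
#'
#' For each focal tree, samples OLA neighbors uniformly (single-entry
#' code changes) and records the mean exact SPR distance from the
#' focal tree to its neighbors, computed by breadth-first search in
#' the unit-SPR graph.  Each individual distance is bounded by the
#' focal tree's height, and the mean over uniform neighbors is below
#' 2.  Tree sizes are limited by the exact-search guard.
#'
#' @param sizes integer vector of tree sizes, each `<= max_n`.
#' @param n_focal focal trees per size (default 30).
#' @param n_neighbors sampled OLA neighbors per focal tree
#'   (default 20).
#' @param max_n guard for the exact SPR search (default 10).
#' @inheritParams experiment_nni_expectation
#' @return a data frame as in [experiment_nni_expectation()], with
#'   `statistic_name = "mean_spr_ola"`.
#' @export
experiment_ola_to_spr <- function(sizes = c(5, 6, 7),
                                  n_focal = 30, n_neighbors = 20,
                                  seed = 1, max_n = 10L) {
  if (any(sizes < 3 | sizes > max_n))
    stop("too large for exact SPR: sizes must lie in [3, ", max_n, "]")
  set.seed(seed)
  rows <- vector("list", length(sizes) * n_focal)
  k <- 0L
  for (n in as.integer(sizes)) {
    cache <- new.env(parent = emptyenv())
    for (f in seq_len(n_focal)) {
      a <- random_vector(n)
      tr <- .decode_tr(a)
      key <- .code_key(a)
      d <- vapply(seq_len(n_neighbors), function(j) {
        bkey <- .code_key(.random_ola_code(a))
        as.numeric(.spr_dist_keys(key, bkey, cache))
      }, numeric(1))
      k <- k + 1L
      rows[[k]] <- .experiment_table(n, f, seed, "mean_spr_ola",
                                     mean(d), .tr_height(tr))
    }
  }
  do.call(rbind, rows)
}

#' Write an experiment table as CSV
#'
#' @param table a data frame from one of the experiment functions.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
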