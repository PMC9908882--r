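#' Random PCSF benchmark instance
#'
#' Draws a small random directed graph with outdegree-reciprocal edge
#' costs, one or two root nodes and binary node prizes — the instance
#' family used to validate the heuristic solver against the exact one.
#'
#' @param seed integer seed.
#' @param max_nodes,max_edges instance size caps (defaults 12 / 20).
#' @param prize_prob probability that a non-root node is prized.
#' @return list with `interactome`, `prizes` (named 0/1 vector) and
#'   `roots`.
#' @export
random_pcsf_instance <- function(seed, max_nodes = 12L, max_edges = 20L,
                                 prize_prob = 0.4) {
  set.seed(as.integer(seed))
  n <- sample(4:max_nodes, 1)
  nodes <- sprintf("v%02d", seq_len(n))
  m <- sample(3:min(max_edges, n * (n - 1L)), 1)
  pairs <- expand.grid(source = nodes, target = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  el <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  inter <- assign_edge_weights(el)
  present <- sort(unique(c(el$source, el$target)))
  roots <- sample(present, sample(1:2, 1))
  pr <- stats::setNames(as.numeric(stats::runif(n) < prize_prob), nodes)
  pr[roots] <- 0
  list(interactome = inter, prizes = pr[pr > 0], roots = roots)
}

#' Random directed graph for controllability validation
#'
#' @param seed integer seed.
#' @param max_nodes maximum node count (default 8).
#' @param edge_prob probability of each ordered node pair being an
#'   edge (default 0.25).
#' @return list with `edges` (data.frame) and `nodes`.
#' @export
random_digraph <- function(seed, max_nodes = 8L, edge_prob = 0.25) {
  set.seed(as.integer(seed))
  n <- sample(2:max_nodes, 1)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < edge_prob
  list(edges = pairs[keep, , drop = FALSE], nodes = nodes)
}
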