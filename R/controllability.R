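#' Bipartite mapping of a directed network
#'
#' Maps a directed graph to the bipartite graph used in structural
#' controllability analysis: the left partition holds an out-copy
#' `x+` of every node, the right partition an in-copy `y-`, and each
#' directed edge x -> y becomes the bipartite edge (x+, y-).
#' Self-loops are removed first (self-dynamics are treated separately
#' in the structural-controllability convention) with a logged count.
#'
#' @param edges data.frame with columns `source`, `target`, or an
#'   `igraph` directed graph.
#' @param nodes optional character vector of node names (to include
#'   isolated nodes).
#' @return list with `graph` (bipartite `igraph`, vertex attribute
#'   `type`: `FALSE` = out-copy, `TRUE` = in-copy), `nodes`,
#'   `n_self_loops`.
#' @export
bipartite_mapping <- function(edges, nodes = NULL) {
  if (inherits(edges, "igraph")) {
    nodes <- union(nodes, igraph::V(edges)$name)
    edges <- igraph::as_data_frame(edges, what = "edges")
    names(edges)[1:2] <- c("source", "target")
  }
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  loops <- edges$source == edges$target
  edges <- edges[!loops, , drop = FALSE]
  edges <- unique(edges[, c("source", "target")])
  vs <- data.frame(name = c(paste0(nodes, "+"), paste0(nodes, "-")),
                   type = rep(c(FALSE, TRUE), each = length(nodes)),
                   stringsAsFactors = FALSE)
  es <- if (nrow(edges)) {
    data.frame(from = paste0(edges$source, "+"),
               to = paste0(edges$target, "-"), stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0))
  }
  g <- igraph::graph_from_data_frame(es, directed = FALSE, vertices = vs)
  list(graph = g, nodes = nodes, n_self_loops = sum(loops))
}

#' Maximum matching and driver-node count of a directed network
#'
#' Computes a maximum-cardinality matching of the bipartite mapping
#' (no two matched edges share a source out-copy or a target in-copy)
#' and derives the minimum driver-node count N_D = max(N - |M|, 1):
#' nodes whose in-copy is unmatched must receive external control
#' inputs, and a perfectly matched network still needs one input.
#'
#' @param x output of [bipartite_mapping()], or anything it accepts.
#' @return list of class `matching_result`: `matching` (data.frame
#'   source/target of matched edges), `size`, `N`, `N_D`,
#'   `driver_set` (one deterministic witness: the unmatched in-copy
#'   nodes, lexicographic).
#' @export
max_matching <- function(x) {
  if (!is.list(x) || is.null(x$graph)) x <- bipartite_mapping(x)
  g <- x$graph
  m <- igraph::max_bipartite_match(g)
  mm <- m$matching
  left <- names(mm)[grepl("\\+$", names(mm))]
  matched <- !is.na(mm[left])
  pairs <- data.frame(source = sub("\\+$", "", left[matched]),
                      target = sub("-$", "", unname(mm[left][matched])),
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  N <- length(x$nodes)
  size <- nrow(pairs)
  drivers <- sort(setdiff(x$nodes, pairs$target))
  structure(list(matching = pairs, size = size, N = N,
                 N_D = max(N - size, 1L), driver_set = drivers),
            class = "matching_result")
}

#' Classify nodes as indispensable, neutral or dispensable
#'
#' Removes each node (with its incident edges) in turn, recomputes the
#' driver count N'_D on the reduced network, and classifies the node
#' against the intact network's N_D: indispensable (a control node)
#' when N'_D > N_D, dispensable when N'_D < N_D, neutral otherwise.
#'
#' @param edges directed edge data.frame (`source`, `target`) or
#'   `igraph` graph.
#' @param nodes optional node universe including isolated nodes.
#' @return data.frame `node`, `N_D_removed`, `class`; attributes
#'   `N_D`, `N`.
#' @export
classify_nodes <- function(edges, nodes = NULL) {
  bm <- bipartite_mapping(edges, nodes)
  if (length(bm$nodes) < 2L) stop("need at least 2 nodes")
  base <- max_matching(bm)
  el <- if (inherits(edges, "igraph")) {
    df <- igraph::as_data_frame(edges, what = "edges")
    names(df)[1:2] <- c("source", "target"); df
  } else edges
  res <- lapply(bm$nodes, function(v) {
    keep <- el$source != v & el$target != v
    sub <- max_matching(bipartite_mapping(el[keep, , drop = FALSE],
                                          nodes = setdiff(bm$nodes, v)))
    cls <- if (sub$N_D > base$N_D) "indispensable"
           else if (sub$N_D < base$N_D) "dispensable" else "neutral"
    data.frame(node = v, N_D_removed = sub$N_D, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "N_D") <- base$N_D
  attr(out, "N") <- base$N
  out
}

#' Fraction of indispensable (controller) nodes
#'
#' @param classification output of [classify_nodes()].
#' @return scalar |indispensable| / N.
#' @export
controller_fraction <- function(classification) {
  if (!nrow(classification)) stop("empty classification")
  mean(classification$class == "indispensable")
}
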