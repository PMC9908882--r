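INTERACTION_TYPES <- c("kinase->target", "TF->target", "TF->miRNA",
                       "signaling", "miRNA->gene", "gene->metabolite",
                       "phosphatase->target")

#' Assign outdegree-reciprocal edge weights to a directed interactome
#'
#' Every directed edge (x, y) gets weight w(e) = 1 / kout(x), the
#' reciprocal of the outdegree of its source, and cost
#' c(e) = 1 - w(e). Outdegree is counted on the deduplicated simple
#' digraph (distinct targets), so the weights out of any non-sink node
#' sum to 1; parallel edges of different interaction types share the
#' weight of their (source, target) pair. Self-loops are dropped and
#' duplicate rows within a type removed.
#'
#' @param edge_list data.frame with columns `source`, `target` and
#'   optionally `type` and `sign`.
#' @return an `interactome`: the cleaned edge data.frame with added
#'   `weight` and `cost` columns; attributes `kout` and `degree`
#'   (named per-node vectors; `degree` is total degree on the simple
#'   digraph).
#' @export
assign_edge_weights <- function(edge_list) {
  req <- c("source", "target")
  if (!all(req %in% names(edge_list))) {
    bad <- which(!stats::complete.cases(edge_list[intersect(req, names(edge_list))]))
    stop("edge list must have source/target columns",
         if (length(bad)) paste0(" (malformed rows: ", toString(bad), ")"))
  }
  el <- edge_list
  if (is.null(el$type)) el$type <- "signaling"
  if (is.null(el$sign)) el$sign <- NA_integer_
  bad <- which(is.na(el$source) | is.na(el$target) |
                 el$source == "" | el$target == "")
  if (length(bad)) stop("malformed edge rows: ", toString(bad))
  el <- el[el$source != el$target, , drop = FALSE]          # no self-loops
  el <- el[!duplicated(el[, c("source", "target", "type", "sign")]), , drop = FALSE]
  simple <- unique(el[, c("source", "target")])
  kout <- table(factor(simple$source, levels = unique(c(el$source, el$target))))
  deg <- table(factor(c(simple$source, simple$target),
                      levels = names(kout)))
  el$weight <- 1 / as.numeric(kout[el$source])
  el$cost <- 1 - el$weight
  rownames(el) <- NULL
  structure(el, kout = c(kout), degree = c(deg), class = c("interactome", "data.frame"))
}

#' Merge a precomputed signed causal edge list into an interactome
#'
#' Takes the union of the scaffold and an externally derived signed
#' directed edge list (e.g. the output of a causal-inference tool) and
#' recomputes all outdegree-reciprocal weights on the merged graph.
#' Duplicate edges with conflicting signs are both kept and flagged.
#'
#' @param interactome edge data.frame (or `interactome`).
#' @param signed_edge_list data.frame with `source`, `target`,
#'   optional `type`, `sign`. May be empty.
#' @return merged `interactome`; attribute `sign_conflicts` holds
#'   flagged (source, target, type) rows, if any.
#' @export
merge_causal_edges <- function(interactome, signed_edge_list) {
  base <- as.data.frame(interactome)[, intersect(c("source", "target", "type", "sign"),
                                                 names(interactome)), drop = FALSE]
  if (!is.null(signed_edge_list) && nrow(signed_edge_list)) {
    add <- signed_edge_list
    if (is.null(add$type)) add$type <- "signaling"
    if (is.null(add$sign)) add$sign <- NA_integer_
    base <- rbind(base[, c("source", "target", "type", "sign")],
                  add[, c("source", "target", "type", "sign")])
  }
  merged <- assign_edge_weights(base)
  key <- paste(merged$source, merged$target, merged$type)
  dup <- key[duplicated(key)]
  conf <- merged[key %in% dup, , drop = FALSE]
  if (nrow(conf)) attr(merged, "sign_conflicts") <- unique(conf[, c("source", "target", "type")])
  merged
}

#' Cumulative binary prize schedule from log2FC tables
#'
#' A node's per-timepoint magnitude is the maximum |log2FC| over all
#' measurements mapping to it (phosphosites and multi-layer
#' measurements collapse onto their parent gene/protein node). The
#' node is prized at timepoint t when its magnitude strictly exceeded
#' `threshold` at any timepoint i <= t (cumulative union), so the
#' schedule is monotone: once prized, always prized. Nodes absent from
#' every table get no prize.
#'
#' @param lfc_tables named list of feature x (T-1) log2FC matrices.
#' @param threshold strict |log2FC| cutoff (default 1).
#' @param feature_to_node function mapping feature ids to node ids;
#'   the default strips a phosphosite `_S<k>` suffix.
#' @return binary node x timepoint matrix of class `prize_schedule`.
#' @export
cumulative_prizes <- function(lfc_tables, threshold = 1,
                              feature_to_node = function(x) sub("_S[0-9]+$", "", x)) {
  if (!is.list(lfc_tables)) lfc_tables <- list(lfc_tables)
  Tm1 <- ncol(lfc_tables[[1]])
  hits <- list()
  for (tab in lfc_tables) {
    stopifnot(ncol(tab) == Tm1)
    nodes <- feature_to_node(rownames(tab))
    hits[[length(hits) + 1L]] <- rowsum((abs(tab) > threshold) + 0, nodes)
  }
  all_nodes <- sort(unique(unlist(lapply(hits, rownames))))
  sig <- matrix(0, length(all_nodes), Tm1,
                dimnames = list(all_nodes, colnames(lfc_tables[[1]])))
  for (h in hits) sig[rownames(h), ] <- sig[rownames(h), , drop = FALSE] + h
  p <- t(apply(sig > 0, 1, cummax))
  storage.mode(p) <- "double"
  structure(p, class = c("prize_schedule", class(p)))
}

#' Parameters of the prize-collecting Steiner forest
#'
#' @param beta prize scale (default 10).
#' @param mu hub (degree) penalty (default 0).
#' @param omega per-tree charge (default 5).
#' @param D maximum hop depth from a tree root (root = depth 0;
#'   default 5).
#' @param roots names of the receptor nodes attached to the dummy node
#'   (default TGFBR1/TGFBR2).
#' @return validated parameter list of class `pcsf_params`.
#' @export
pcsf_params <- function(beta = 10, mu = 0, omega = 5, D = 5L,
                        roots = c("TGFBR1", "TGFBR2")) {
  stopifnot(beta > 0, omega > 0, D >= 1, mu >= 0, length(roots) >= 1)
  structure(list(beta = beta, mu = mu, omega = omega, D = as.integer(D),
                 roots = as.character(roots)), class = "pcsf_params")
}

# augmented edge table: dummy -> each root at cost omega
attach_dummy <- function(interactome, params) {
  missing_roots <- setdiff(params$roots, unique(c(interactome$source, interactome$target)))
  if (length(missing_roots)) {
    stop("root node(s) absent from interactome: ", toString(missing_roots))
  }
  dummy <- data.frame(source = "__DUMMY__", target = params$roots,
                      type = "dummy", sign = NA_integer_,
                      weight = NA_real_, cost = params$omega,
                      stringsAsFactors = FALSE)
  rbind(dummy, as.data.frame(interactome)[, names(dummy)])
}

#' Solve the rooted depth-bounded prize-collecting Steiner forest
#'
#' Minimizes f(F) = sum over excluded nodes of (beta p(v) - mu k(v))
#' + sum of selected edge costs + omega * kappa, over forests whose
#' every node is reachable from a root along selected directed edges
#' within hop depth D. Tree roots are the designated receptor nodes; an
#' implicit dummy node with cost-omega edges to the roots encodes the
#' per-tree charge.
#'
#' `mode = "exact"` enumerates all parent assignments (guaranteed
#' optimum; refuses instances over an internal size cap, intended for
#' graphs up to roughly 20 candidate edges). `mode = "heuristic"` runs
#' a deterministic cheapest-path accretion: it repeatedly attaches the
#' prized node whose depth-feasible minimum-cost directed path from
#' the current forest (or from a root, paying omega) has the best
#' margin (path cost + mu-degree charges - recovered prizes), ties
#' broken lexicographically; no randomness.
#'
#' @param interactome an [assign_edge_weights()] result.
#' @param prizes named numeric vector of node prizes p(v) (typically
#'   binary); missing nodes have prize 0.
#' @param params a [pcsf_params()].
#' @param mode `"exact"` or `"heuristic"`.
#' @param undirected if `TRUE`, each edge is also usable in reverse
#'   (relaxation for cross-checks against undirected solvers).
#' @return a `pcsf_forest`: list with `nodes` (data.frame node/depth),
#'   `edges` (selected edge data.frame), `kappa`, `objective`, `mode`,
#'   `params`.
#' @export
solve_pcsf <- function(interactome, prizes, params = pcsf_params(),
                       mode = c("heuristic", "exact"), undirected = FALSE) {
  mode <- match.arg(mode)
  el <- as.data.frame(interactome)
  if (undirected) {
    rev <- el; rev$source <- el$target; rev$target <- el$source
    el <- assign_edge_weights(rbind(el[, c("source", "target", "type", "sign")],
                                    rev[, c("source", "target", "type", "sign")]))
    el <- as.data.frame(el)
  }
  # collapse parallel typed edges to one candidate per (source, target)
  el <- el[order(el$source, el$target, el$cost), , drop = FALSE]
  el <- el[!duplicated(el[, c("source", "target")]), , drop = FALSE]
  nodes <- sort(unique(c(el$source, el$target, params$roots)))
  deg <- attr(interactome, "degree")
  k <- stats::setNames(rep(0, length(nodes)), nodes)
  if (!is.null(deg)) k[intersect(names(deg), nodes)] <- deg[intersect(names(deg), nodes)]
  p <- stats::setNames(rep(0, length(nodes)), nodes)
  pr <- prizes[names(prizes) %in% nodes]
  p[names(pr)] <- pr
  pen <- params$beta * p - params$mu * k

  aug <- attach_dummy(el, params)
  if (mode == "exact") {
    idx <- stats::setNames(seq_along(nodes), nodes)
    efrom <- ifelse(aug$source == "__DUMMY__", 0L, idx[aug$source])
    eto <- idx[aug$target]
    res <- pcsf_exact_cpp(as.integer(efrom), as.integer(eto), aug$cost,
                          as.numeric(pen), length(nodes), params$D, 1e7)
    sel <- aug[res$edges, , drop = FALSE]
  } else {
    # deterministic branching: every non-empty root subset (greedy
    # accretion can otherwise overpay omega by opening a tree per root)
    # crossed with every tied-best first attachment (single-target
    # margins cannot see multi-target synergy, so exact ties are
    # explored rather than broken blindly); keep the best forest
    subsets <- unlist(lapply(seq_along(params$roots), function(k)
      utils::combn(sort(params$roots), k, simplify = FALSE)), recursive = FALSE)
    best <- NULL
    for (rs in subsets) {
      prs <- params; prs$roots <- rs
      aug <- attach_dummy(el, prs)
      for (strat in c("plain", "mixed")) {
        firsts <- heuristic_first_choices(aug, pen, prs, nodes, strat)
        for (fc in firsts) {
          sel <- pcsf_heuristic(aug, pen, prs, nodes, force_first = fc,
                                strategy = strat)
          f <- forest_from_edges(sel, el, pen, params, nodes)
          if (is.null(best) || f$objective < best$objective - 1e-12) best <- f
        }
      }
    }
    return(best)
  }
  forest_from_edges(sel, el, pen, params, nodes)
}

# the tied-best first attachments of the accretion (candidates whose
# margin equals the minimum within tolerance); NA means "no viable
# first attachment" and yields the empty run
heuristic_first_choices <- function(aug, pen, params, nodes,
                                    strategy = "mixed") {
  el <- aug[aug$source != "__DUMMY__", , drop = FALSE]
  prized <- names(pen)[pen > 0]
  if (!length(prized)) return(list(NULL))
  sp <- heuristic_paths_best(el, character(0),
                             stats::setNames(integer(0), character(0)),
                             params, nodes, pen, strategy)
  margins <- vapply(prized, function(v) {
    if (is.null(sp[[v]])) Inf else sp[[v]]$margin
  }, 1.0)
  ok <- is.finite(margins) & margins < -1e-12
  if (!any(ok)) return(list(NULL))
  tied <- sort(prized[ok][margins[ok] <= min(margins[ok]) + 1e-9])
  as.list(tied)
}

# deterministic best-margin-path accretion heuristic
pcsf_heuristic <- function(aug, pen, params, nodes, force_first = NULL,
                           strategy = "mixed") {
  el <- aug[aug$source != "__DUMMY__", , drop = FALSE]
  included <- character(0)
  depth <- stats::setNames(integer(0), character(0))
  sel_rows <- integer(0)
  tree_roots <- character(0)
  prized <- names(pen)[pen > 0]
  first_iter <- TRUE
  repeat {
    targets <- setdiff(prized, included)
    if (!length(targets)) break
    sp <- heuristic_paths_best(el, included, depth, params, nodes, pen,
                               strategy)
    margins <- vapply(targets, function(v) {
      if (is.null(sp[[v]])) Inf else sp[[v]]$margin
    }, 1.0)
    ok <- is.finite(margins) & margins < -1e-12
    if (first_iter && !is.null(force_first)) {
      best <- force_first
      if (is.null(sp[[best]])) break
    } else {
      if (!any(ok)) break
      best <- sort(targets[ok][margins[ok] == min(margins[ok])])[1]
    }
    first_iter <- FALSE
    p <- sp[[best]]
    depth[p$nodes] <- p$depths
    included <- c(included, p$nodes)
    sel_rows <- c(sel_rows, p$edges)
    if (p$opens_tree) tree_roots <- union(tree_roots, p$nodes[1])
  }
  aug_rows <- el[unique(sel_rows), , drop = FALSE]
  dummy <- aug[aug$source == "__DUMMY__" & aug$target %in% tree_roots, , drop = FALSE]
  rbind(dummy, aug_rows)
}

# Attachment-path candidates per accretion step. "plain" uses minimum-
# cost paths only (conservative with the depth budget); "mixed" also
# runs the prize-discounted search (see heuristic_paths) and keeps, per
# target, the candidate with the better recomputed margin. Discounted
# paths can collect several prizes at once but may spend depth that a
# later attachment needs, so the solver runs both strategies and keeps
# the better forest.
heuristic_paths_best <- function(el, included, depth, params, nodes, pen,
                                 strategy = "mixed") {
  out <- heuristic_paths(el, included, depth, params, nodes,
                         pen, discount = FALSE)
  if (strategy == "mixed") {
    disc <- heuristic_paths(el, included, depth, params, nodes,
                            pen, discount = TRUE)
    for (v in nodes) {
      if (!is.null(disc[[v]]) &&
          (is.null(out[[v]]) || disc[[v]]$margin < out[[v]]$margin - 1e-12)) {
        out[[v]] <- disc[[v]]
      }
    }
  }
  out
}

# Best-margin attachment paths from the current forest (cost 0 at their
# depth) or a not-yet-opened root (cost omega at depth 0) to every
# reachable node. States (node, depth) form a DAG (edges strictly
# increase depth), so prize-discounted shortest paths -- edge relaxation
# weight c(e) - pen(target) -- are computed exactly by DP over depth
# layers despite negative weights. A reconstructed walk that revisits a
# node (possible with discounts) is discarded; the reported margin is
# recomputed from the unique path nodes, so discounting only steers the
# search, never the accounting.
heuristic_paths <- function(el, included, depth, params, nodes, pen,
                            discount = TRUE) {
  D <- params$D
  n <- length(nodes)
  nid <- stats::setNames(seq_len(n), nodes)
  dist <- matrix(Inf, n, D + 1L)              # node x depth(0..D)
  par_edge <- matrix(NA_integer_, n, D + 1L)
  par_state <- matrix(NA_integer_, n, D + 1L)
  for (u in included) {
    if (depth[u] <= D) dist[nid[u], depth[u] + 1L] <- 0
  }
  open_roots <- setdiff(intersect(params$roots, nodes), included)
  for (r in open_roots) {
    dist[nid[r], 1L] <- min(dist[nid[r], 1L],
                            params$omega - (if (discount) pen[r] else 0))
  }
  out_by_src <- split(seq_len(nrow(el)), el$source)
  for (dpos in seq_len(D)) {                  # layer-by-layer DP
    live <- which(is.finite(dist[, dpos]))
    for (u in live) {
      for (e in out_by_src[[nodes[u]]]) {
        vname <- el$target[e]
        if (vname %in% included) next         # forest nodes only as sources
        v <- nid[vname]
        nd <- dist[u, dpos] + el$cost[e] - (if (discount) pen[vname] else 0)
        if (nd < dist[v, dpos + 1L] - 1e-15) {
          dist[v, dpos + 1L] <- nd
          par_edge[v, dpos + 1L] <- e
          par_state[v, dpos + 1L] <- (dpos - 1L) * n + u
        }
      }
    }
  }
  out <- vector("list", n)
  names(out) <- nodes
  for (v in nodes) {
    if (!any(is.finite(dist[nid[v], ]))) next
    dpos <- which.min(dist[nid[v], ])
    pn <- character(0); pe <- integer(0); pd <- integer(0)
    cur <- nid[v]; cd <- dpos
    opens <- FALSE
    repeat {
      nm <- nodes[cur]
      if (nm %in% included) break
      pn <- c(nm, pn); pd <- c(cd - 1L, pd)
      pedge <- par_edge[cur, cd]
      if (is.na(pedge)) { opens <- nm %in% open_roots; break }
      pe <- c(pedge, pe)
      ps <- par_state[cur, cd]
      cur <- ((ps - 1L) %% n) + 1L
      cd <- ((ps - 1L) %/% n) + 1L
    }
    if (anyDuplicated(pn)) next               # discount-induced revisit
    margin <- sum(el$cost[pe]) + (if (opens) params$omega else 0) -
      sum(pen[pn])
    out[[v]] <- list(nodes = pn, edges = pe,
                     depths = stats::setNames(pd, pn),
                     opens_tree = opens, margin = margin)
  }
  out
}

# build and validate the forest object from selected augmented edges
forest_from_edges <- function(sel, el, pen, params, nodes) {
  sel_real <- sel[sel$source != "__DUMMY__", , drop = FALSE]
  kappa <- sum(sel$source == "__DUMMY__")
  g_nodes <- unique(c(sel_real$source, sel_real$target,
                      sel$target[sel$source == "__DUMMY__"]))
  # depths by BFS from roots over selected edges
  dep <- stats::setNames(rep(NA_integer_, length(g_nodes)), g_nodes)
  frontier <- sel$target[sel$source == "__DUMMY__"]
  dep[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    nxt <- sel_real$target[sel_real$source %in% frontier]
    nxt <- nxt[is.na(dep[nxt])]
    d <- d + 1L
    dep[nxt] <- d
    frontier <- nxt
  }
  obj <- sum(pen[setdiff(nodes, g_nodes)]) +
    sum(sel_real$cost) + params$omega * kappa
  structure(list(
    nodes = data.frame(node = g_nodes, depth = unname(dep[g_nodes]),
                       stringsAsFactors = FALSE),
    edges = sel_real[, intersect(c("source", "target", "type", "sign", "cost"),
                                 names(sel_real)), drop = FALSE],
    kappa = kappa, objective = unname(obj), params = params),
    class = "pcsf_forest")
}

#' @export
print.pcsf_forest <- function(x, ...) {
  cat(sprintf("<pcsf_forest> %d nodes, %d edges, %d tree(s), f(F) = %.4f\n",
              nrow(x$nodes), nrow(x$edges), x$kappa, x$objective))
  invisible(x)
}

#' Recompute and validate the PCSF objective of a forest
#'
#' Independent certificate check: verifies the forest invariants
#' (|E_F| = |V_F| - kappa, unique parents, rooted reachability along
#' directed edges, depth <= D) and recomputes
#' f(F) = sum over excluded v of (beta p(v) - mu k(v)) + sum of edge
#' costs + omega kappa from parts.
#'
#' @param forest a `pcsf_forest`.
#' @param prizes named prize vector (as passed to [solve_pcsf()]).
#' @param params a [pcsf_params()].
#' @param interactome the scaffold the forest was solved on.
#' @return scalar objective value (errors on an invalid certificate).
#' @export
forest_objective <- function(forest, prizes, params, interactome) {
  ed <- forest$edges
  vf <- forest$nodes$node
  if (nrow(ed) != length(vf) - forest$kappa) stop("not a forest: |E| != |V| - kappa")
  if (any(duplicated(ed$target))) stop("node with two parents")
  roots_used <- setdiff(vf, ed$target)
  if (length(roots_used) != forest$kappa) stop("tree count inconsistent with roots")
  if (!all(roots_used %in% params$roots)) stop("tree rooted at a non-root node")
  # reachability + depth
  dep <- stats::setNames(rep(NA_integer_, length(vf)), vf)
  dep[roots_used] <- 0L
  frontier <- roots_used; d <- 0L
  while (length(frontier)) {
    nxt <- ed$target[ed$source %in% frontier]
    nxt <- nxt[is.na(dep[nxt])]
    d <- d + 1L
    dep[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(dep)) stop("node unreachable from the roots")
  if (any(dep > params$D)) stop("depth bound violated")
  nodes <- sort(unique(c(interactome$source, interactome$target, params$roots)))
  deg <- attr(interactome, "degree")
  k <- stats::setNames(rep(0, length(nodes)), nodes)
  if (!is.null(deg)) k[intersect(names(deg), nodes)] <- deg[intersect(names(deg), nodes)]
  p <- stats::setNames(rep(0, length(nodes)), nodes)
  pr <- prizes[names(prizes) %in% nodes]
  p[names(pr)] <- pr
  excl <- setdiff(nodes, vf)
  sum(params$beta * p[excl] - params$mu * k[excl]) +
    sum(ed$cost) + params$omega * forest$kappa
}

#' Solve the forest separately for every timepoint
#'
#' Runs [solve_pcsf()] at each timepoint with the cumulative prize
#' schedule and reports each node's first appearance, giving the
#' network growth curve.
#'
#' @param interactome an [assign_edge_weights()] result.
#' @param prize_schedule a [cumulative_prizes()] matrix.
#' @param params a [pcsf_params()].
#' @param mode solver mode, see [solve_pcsf()].
#' @return list with `forests` (one `pcsf_forest` per timepoint) and
#'   `first_appearance` (named integer vector, timepoint index of
#'   first inclusion).
#' @export
run_temporal_series <- function(interactome, prize_schedule,
                                params = pcsf_params(),
                                mode = c("heuristic", "exact")) {
  mode <- match.arg(mode)
  tps <- colnames(prize_schedule)
  forests <- list()
  first <- list()
  for (ti in seq_along(tps)) {
    pr <- stats::setNames(prize_schedule[, ti], rownames(prize_schedule))
    f <- solve_pcsf(interactome, pr, params, mode = mode)
    forests[[tps[ti]]] <- f
    new <- setdiff(f$nodes$node, names(first))
    for (v in new) first[[v]] <- ti
  }
  list(forests = forests,
       first_appearance = unlist(first[sort(names(first))]))
}

#' Convert a forest to an igraph object (e.g. for GraphML export)
#' @param forest a `pcsf_forest`.
#' @return directed `igraph` graph with a `depth` vertex attribute.
#' @export
forest_to_igraph <- function(forest) {
  g <- igraph::graph_from_data_frame(forest$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = forest$nodes$node)
  igraph::V(g)$depth <- forest$nodes$depth[match(igraph::V(g)$name,
                                                 forest$nodes$node)]
  g
}
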