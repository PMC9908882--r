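# Small builders and independent brute-force oracles used across tests.

# omics_matrix from a T x R design with given per-feature profiles:
# value(f, t, r) = profile[f, t+1] + noise
make_omics <- function(profiles, n_reps = 3, noise_sd = 0, layer = "TEST",
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- ncol(profiles)
  tp <- rep(0:(Tn - 1), each = n_reps)
  rp <- rep(seq_len(n_reps), Tn)
  V <- profiles[, tp + 1, drop = FALSE] +
    matrix(rnorm(nrow(profiles) * length(tp), sd = noise_sd), nrow(profiles))
  colnames(V) <- sprintf("t%d_r%d", tp, rp)
  rownames(V) <- rownames(profiles)
  omics_matrix(V, layer)
}

# de_result stand-in for ligand-receptor tests: named p-values and an
# lfc matrix with rows = features
make_de <- function(p, lfc) {
  out <- data.frame(feature = names(p), adj_p = unname(p),
                    stringsAsFactors = FALSE)
  attr(out, "lfc") <- lfc
  class(out) <- c("de_result", "data.frame")
  out
}

# brute-force maximum matching cardinality on a directed edge list:
# no two chosen edges may share a source or share a target
bf_max_matching <- function(edges) {
  edges <- unique(edges[edges$source != edges$target, c("source", "target")])
  m <- nrow(edges)
  if (!m) return(0L)
  best <- 0L
  rec <- function(i, used_s, used_t, size) {
    if (size + (m - i + 1L) <= best) return()   # bound
    if (i > m) { best <<- max(best, size); return() }
    s <- edges$source[i]; t <- edges$target[i]
    if (!(s %in% used_s) && !(t %in% used_t)) {
      rec(i + 1L, c(used_s, s), c(used_t, t), size + 1L)
    }
    rec(i + 1L, used_s, used_t, size)
  }
  rec(1L, character(0), character(0), 0L)
  best
}

bf_n_driver <- function(edges, nodes) {
  max(length(nodes) - bf_max_matching(edges), 1L)
}

bf_classify <- function(edges, nodes) {
  base <- bf_n_driver(edges, nodes)
  vapply(nodes, function(v) {
    keep <- edges$source != v & edges$target != v
    nd <- bf_n_driver(edges[keep, , drop = FALSE], setdiff(nodes, v))
    if (nd > base) "indispensable" else if (nd < base) "dispensable" else "neutral"
  }, "")
}

# brute-force PCSF oracle: enumerate all edge subsets of the augmented
# graph (dummy -> roots at cost omega), keep rooted depth-bounded
# forests, return the minimum objective. Independent of the solver's
# parent-assignment enumeration.
bf_pcsf_objective <- function(interactome, prizes, params) {
  el <- as.data.frame(interactome)
  el <- el[order(el$source, el$target, el$cost), ]
  el <- el[!duplicated(el[, c("source", "target")]), ]
  nodes <- sort(unique(c(el$source, el$target, params$roots)))
  deg <- attr(interactome, "degree")
  k <- setNames(rep(0, length(nodes)), nodes)
  if (!is.null(deg)) k[intersect(names(deg), nodes)] <- deg[intersect(names(deg), nodes)]
  p <- setNames(rep(0, length(nodes)), nodes)
  p[intersect(names(prizes), nodes)] <- prizes[intersect(names(prizes), nodes)]
  pen <- params$beta * p - params$mu * k
  aug <- rbind(data.frame(source = ".d", target = params$roots,
                          cost = params$omega, stringsAsFactors = FALSE),
               el[, c("source", "target", "cost")])
  m <- nrow(aug)
  stopifnot(m <= 16)                       # oracle is for tiny instances
  best <- sum(pen)                          # empty forest
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (!length(sel)) next
    sub <- aug[sel, , drop = FALSE]
    if (any(duplicated(sub$target))) next
    depth <- c(".d" = -1)
    frontier <- ".d"
    repeat {
      nxt <- sub$target[sub$source %in% frontier]
      nxt <- setdiff(nxt, names(depth))
      if (!length(nxt)) break
      depth[nxt] <- depth[[frontier[1]]] + 1  # frontier all at same depth
      frontier <- nxt
    }
    vf <- setdiff(names(depth), ".d")
    if (!all(sub$source %in% c(".d", vf)) || !all(sub$target %in% vf)) next
    if (length(vf) && max(depth[vf]) > params$D) next
    obj <- sum(pen[setdiff(nodes, vf)]) + sum(sub$cost)
    if (obj < best) best <- obj
  }
  best
}
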