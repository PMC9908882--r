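#' Configuration (sample-similarity) matrix of one omics layer
#'
#' For an n x p data matrix X (samples in rows, features in columns)
#' the configuration matrix is S = XX' computed after feature
#' mean-centering. Centering keeps the downstream RV coefficient from
#' being dominated by feature means; set `center = FALSE` for the
#' uncentered textbook formula.
#'
#' @param X numeric matrix, samples x features, no missing values. An
#'   [omics_matrix()] may be passed (its transpose is used).
#' @param center logical, mean-center features first (default TRUE).
#' @return symmetric positive semidefinite n x n matrix.
#' @export
configuration_matrix <- function(X, center = TRUE) {
  if (inherits(X, "omics_matrix")) X <- t(X$values)
  stopifnot(is.matrix(X), !anyNA(X))
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (center) X <- sweep(X, 2, colMeans(X))
  tcrossprod(X)
}

#' RV coefficient between two configuration matrices
#'
#' RV(S_i, S_j) = vec(S_i)'vec(S_j) /
#' sqrt(vec(S_i)'vec(S_i) * vec(S_j)'vec(S_j)); lies in \[0, 1\] for
#' positive semidefinite inputs and equals 1 for S_i = S_j.
#'
#' @param S_i,S_j square numeric matrices of equal dimension.
#' @return scalar RV coefficient.
#' @export
rv_coefficient <- function(S_i, S_j) {
  stopifnot(all(dim(S_i) == dim(S_j)))
  den <- sqrt(sum(S_i^2) * sum(S_j^2))
  if (den == 0) stop("RV undefined for a zero configuration matrix")
  sum(S_i * S_j) / den
}

#' RV coefficient matrix over a set of layers
#'
#' @param mats named list of preprocessed [omics_matrix()] objects or
#'   of precomputed configuration matrices. Layers are aligned on their
#'   shared sample columns (replicates kept distinct).
#' @param center passed to [configuration_matrix()].
#' @return symmetric matrix of RV coefficients with unit diagonal.
#' @export
rv_matrix <- function(mats, center = TRUE) {
  if (inherits(mats[[1]], "omics_matrix")) {
    shared <- Reduce(intersect, lapply(mats, function(m) colnames(m$values)))
    if (length(shared) < 2L) stop("fewer than 2 shared samples across layers")
    S <- lapply(mats, function(m) {
      configuration_matrix(t(m$values[, shared, drop = FALSE]), center = center)
    })
  } else {
    S <- mats
  }
  k <- length(S)
  out <- diag(1, k)
  dimnames(out) <- list(names(S), names(S))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[i, j] <- out[j, i] <- rv_coefficient(S[[i]], S[[j]])
  }
  out
}

#' Partial RV coefficient by recursive partial correlation
#'
#' Applies the recursive first-order partial-correlation formula
#' r_ij.k = (r_ij - r_ik r_jk) / sqrt((1 - r_ik^2)(1 - r_jk^2)) to a
#' matrix of RV coefficients, recursing over the conditioning set in
#' sorted order. An empty conditioning set returns the marginal value.
#'
#' @param rv_matrix square RV matrix with unit diagonal.
#' @param i,j indices or names of the two layers.
#' @param conditioning_set indices/names of conditioning layers.
#' @return scalar partial RV coefficient.
#' @export
partial_rv <- function(rv_matrix, i, j, conditioning_set = NULL) {
  idx <- function(x) if (is.character(x)) match(x, rownames(rv_matrix)) else as.integer(x)
  i <- idx(i); j <- idx(j)
  cs <- sort(vapply(conditioning_set, idx, 1L))
  rec <- function(i, j, cs) {
    if (!length(cs)) return(rv_matrix[i, j])
    k <- cs[length(cs)]
    rest <- cs[-length(cs)]
    rij <- rec(i, j, rest); rik <- rec(i, k, rest); rjk <- rec(j, k, rest)
    den <- (1 - rik^2) * (1 - rjk^2)
    if (den <= 0) stop("degenerate conditioning: |r| = 1 in denominator")
    (rij - rik * rjk) / sqrt(den)
  }
  rec(i, j, cs)
}

#' PC-style skeleton over layers from an RV matrix
#'
#' Runs the skeleton phase of the PC algorithm on the layer-level RV
#' matrix: starting from the complete graph, an edge (i, j) is removed
#' whenever some conditioning set drawn from the current neighbourhood
#' (sizes 0, 1, ..., `max_order`) gives |partial RV| below `epsilon`.
#' Deterministic given the sorted node order. Edge orientation is not
#' attempted.
#'
#' @param rv_matrix square RV matrix with unit diagonal.
#' @param epsilon removal threshold in (0, 1).
#' @param max_order maximum conditioning-set size (default 2).
#' @return undirected `igraph` graph over the layers.
#' @export
topology_skeleton <- function(rv_matrix, epsilon = 0.1, max_order = 2L) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  k <- nrow(rv_matrix)
  nm <- rownames(rv_matrix)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  adj <- matrix(TRUE, k, k); diag(adj) <- FALSE
  for (ord in 0:max_order) {
    pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (!adj[i, j]) next
      nbrs <- sort(setdiff(which(adj[i, ] | adj[j, ]), c(i, j)))
      if (length(nbrs) < ord) next
      subsets <- if (ord == 0) list(integer(0)) else
        utils::combn(nbrs, ord, simplify = FALSE)
      for (S in subsets) {
        pr <- tryCatch(partial_rv(rv_matrix, i, j, S), error = function(e) NA_real_)
        if (!is.na(pr) && abs(pr) < epsilon) {
          adj[i, j] <- adj[j, i] <- FALSE
          break
        }
      }
    }
  }
  dimnames(adj) <- list(nm, nm)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Per-timepoint adjusted R-squared between two layers' log2FC profiles
#'
#' For every timepoint, regresses layer B's log2FC on layer A's over
#' their shared features and reports the adjusted coefficient of
#' determination 1 - (1 - R^2)(n - 1)/(n - 2).
#'
#' @param lfc_A,lfc_B feature x (T-1) log2FC matrices
#'   (from [log2fc_profile()]); rows are matched by name.
#' @return numeric vector of length T-1 (named by timepoint).
#' @export
per_timepoint_r2 <- function(lfc_A, lfc_B) {
  shared <- intersect(rownames(lfc_A), rownames(lfc_B))
  if (length(shared) < 3L) stop("need at least 3 shared features")
  A <- lfc_A[shared, , drop = FALSE]
  B <- lfc_B[shared, , drop = FALSE]
  n <- length(shared)
  vapply(seq_len(ncol(A)), function(tt) {
    x <- A[, tt]; y <- B[, tt]
    if (stats::var(x) == 0) stop("zero variance in predictor at timepoint ", tt)
    r2 <- suppressWarnings(stats::cor(x, y)^2)
    if (is.na(r2)) r2 <- 0                      # zero-variance response
    1 - (1 - r2) * (n - 1) / (n - 2)
  }, 1.0) -> out
  names(out) <- colnames(A)
  out
}

#' Per-feature Pearson correlation of log2FC profiles between layers
#'
#' Correlates, feature by feature, the (T-1)-long log2FC profiles of
#' the two layers over their shared features. Zero-variance profiles
#' give `NA` with an attribute counting them; such features are
#' excluded from downstream class assignment.
#'
#' @param lfc_A,lfc_B feature x (T-1) log2FC matrices.
#' @return named numeric vector of PCCs (possibly `NA`), attribute
#'   `n_zero_variance`.
#' @export
pairwise_gene_pcc <- function(lfc_A, lfc_B) {
  shared <- intersect(rownames(lfc_A), rownames(lfc_B))
  if (!length(shared)) return(structure(numeric(0), n_zero_variance = 0L))
  r <- vapply(shared, function(g) {
    a <- lfc_A[g, ]; b <- lfc_B[g, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 1.0)
  structure(r, n_zero_variance = sum(is.na(r)))
}
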