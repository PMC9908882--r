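#' Quality control, imputation and normalization of an omics layer
#'
#' Applies the standard proteomics-style preparation chain to a
#' log2-intensity layer: (1) drop features observed in fewer than
#' `min_valid_fraction` of samples; (2) impute remaining missing values,
#' either by local least squares (LLS) regression on the `k` most
#' correlated complete features, or by the half-minimum rule (half the
#' feature's observed minimum on the linear scale, i.e. observed log2
#' minimum minus 1 -- the below-limit-of-detection convention for
#' metabolite data); (3) optional quantile normalization across samples;
#' (4) optional zero-centering of every feature within each replicate
#' block, which removes block-level batch effects from balanced designs;
#' (5) optional replicate-outlier masking (metabolomics rule): within a
#' feature/timepoint triplet, replicate values deviating by at least one
#' SD from the replicate mean are masked and re-imputed by half-minimum.
#'
#' @param matrix an [omics_matrix()] on the log2 scale.
#' @param min_valid_fraction minimum fraction of non-missing samples a
#'   feature needs to be retained (default 0.70).
#' @param impute_method `"lls"` or `"half_minimum"`.
#' @param k number of correlated complete features used by LLS
#'   (default 10). When fewer complete features exist the function
#'   falls back to half-minimum with a warning.
#' @param quantile_normalize logical, quantile-normalize samples.
#' @param zero_center logical, zero-center features per replicate block.
#' @param metab_sd_outlier logical, apply the replicate SD outlier rule.
#' @return a preprocessed `omics_matrix` without missing values.
#' @export
preprocess_omics <- function(matrix,
                             min_valid_fraction = 0.70,
                             impute_method = c("lls", "half_minimum"),
                             k = 10L,
                             quantile_normalize = TRUE,
                             zero_center = TRUE,
                             metab_sd_outlier = FALSE) {
  stopifnot(inherits(matrix, "omics_matrix"))
  impute_method <- match.arg(impute_method)
  V <- matrix$values
  keep <- rowMeans(!is.na(V)) >= min_valid_fraction
  V <- V[keep, , drop = FALSE]
  if (!nrow(V)) stop("no features pass the valid-value filter")

  if (metab_sd_outlier) {
    V <- mask_replicate_outliers(V, matrix$sample_meta)
  }
  all_na <- rowSums(!is.na(V)) == 0L
  if (any(all_na)) V <- V[!all_na, , drop = FALSE]  # never impute from nothing

  if (anyNA(V)) {
    V <- switch(impute_method,
                half_minimum = impute_half_minimum(V),
                lls = impute_lls(V, k = k))
  }
  if (quantile_normalize) {
    V <- limma::normalizeQuantiles(V)
  }
  if (zero_center) {
    for (r in unique(matrix$sample_meta$replicate)) {
      idx <- which(matrix$sample_meta$replicate == r)
      V[, idx] <- V[, idx] - rowMeans(V[, idx, drop = FALSE])
    }
  }
  omics_matrix(V, matrix$layer, matrix$sample_meta)
}

#' Half-minimum imputation
#'
#' Missing entries of a feature are set to half the feature's observed
#' minimum on the linear scale; on the log2 scale this is the observed
#' minimum minus 1.
#'
#' @param V numeric matrix (features x samples) with `NA`s.
#' @return matrix with missing entries filled.
#' @export
impute_half_minimum <- function(V) {
  for (i in which(rowSums(is.na(V)) > 0L)) {
    V[i, is.na(V[i, ])] <- min(V[i, ], na.rm = TRUE) - 1
  }
  V
}

#' Local least squares (LLS) imputation
#'
#' Each incomplete feature is regressed (ordinary least squares, over
#' its observed samples) on the `k` complete features with the highest
#' absolute Pearson correlation to it; missing entries are filled with
#' the fitted values. With fewer than `k` complete features the
#' function falls back to half-minimum imputation with a warning.
#'
#' @param V numeric matrix (features x samples) with `NA`s.
#' @param k number of predictor features (default 10).
#' @return matrix with missing entries filled.
#' @export
impute_lls <- function(V, k = 10L) {
  complete <- which(rowSums(is.na(V)) == 0L)
  if (length(complete) < k) {
    warning("fewer than k=", k, " complete features; falling back to half-minimum")
    return(impute_half_minimum(V))
  }
  Vc <- V[complete, , drop = FALSE]
  for (i in which(rowSums(is.na(V)) > 0L)) {
    obs <- which(!is.na(V[i, ]))
    r <- suppressWarnings(
      as.vector(stats::cor(V[i, obs], t(Vc[, obs, drop = FALSE]))))
    r[is.na(r)] <- 0
    nb <- order(abs(r), decreasing = TRUE)[seq_len(k)]
    X <- cbind(1, t(Vc[nb, , drop = FALSE]))
    fit <- stats::lm.fit(X[obs, , drop = FALSE], V[i, obs])
    mis <- which(is.na(V[i, ]))
    V[i, mis] <- X[mis, , drop = FALSE] %*% fit$coefficients
  }
  V
}

# metabolomics replicate-outlier rule: within each feature x timepoint
# group, mask values >= 1 SD away from the group mean (SD over replicates)
mask_replicate_outliers <- function(V, sample_meta) {
  for (tp in unique(sample_meta$timepoint)) {
    idx <- which(sample_meta$timepoint == tp)
    if (length(idx) < 3L) next
    sub <- V[, idx, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sd_ <- apply(sub, 1, stats::sd, na.rm = TRUE)
    bad <- abs(sub - mu) >= sd_ & !is.na(sub) & sd_ > 0
    bad[is.na(bad)] <- FALSE
    V[, idx][bad] <- NA
  }
  V
}

#' Per-timepoint log2 fold-change profile relative to the control
#'
#' Entry (v, i) is the replicate-mean log2 intensity of feature v at
#' timepoint i minus its replicate mean at the reference timepoint --
#' the log2 of the ratio of geometric means.
#'
#' @param matrix a preprocessed [omics_matrix()] (no missing values).
#' @param reference_timepoint index of the control (default 0).
#' @return numeric matrix, features x (T-1), columns `t1..t{T-1}`.
#' @export
log2fc_profile <- function(matrix, reference_timepoint = 0L) {
  stopifnot(inherits(matrix, "omics_matrix"))
  sm <- matrix$sample_meta
  tps <- sort(unique(sm$timepoint))
  if (!reference_timepoint %in% tps) stop("reference timepoint absent")
  means <- vapply(tps, function(tp) {
    rowMeans(matrix$values[, sm$timepoint == tp, drop = FALSE])
  }, numeric(nrow(matrix$values)))
  if (!is.matrix(means)) means <- matrix(means, nrow = 1)   # single feature
  ref <- means[, which(tps == reference_timepoint)]
  out <- means[, tps != reference_timepoint, drop = FALSE] - ref
  colnames(out) <- paste0("t", tps[tps != reference_timepoint])
  rownames(out) <- rownames(matrix$values)
  out
}
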