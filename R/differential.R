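#' Two-step polynomial time-course differential selection
#'
#' Step 1 fits, per feature, an ordinary least-squares polynomial
#' regression of log2 intensity on the timepoint index grid
#' (0..T-1, degree `degree`), tests the full model against the
#' intercept-only model with an F-test, and adjusts the p-values across
#' the layer's features with the Benjamini-Hochberg procedure. Step 2,
#' run on the features passing the step-1 FDR gate, performs backward
#' elimination of polynomial terms at per-term level `alpha` and
#' records the coefficient of determination (r-squared) of the retained
#' model. A feature is selected when `adj_p <= alpha`, the step-2
#' r-squared is at least `r2_min`, and its maximum absolute log2
#' fold change versus the control reaches `lfc_min` (defaults 0.05 /
#' 0.6 / 1).
#'
#' A perfectly flat feature (zero residual and zero model variance) is
#' assigned p = 1 by convention and never selected.
#'
#' @param matrix a preprocessed [omics_matrix()] (no missing values).
#' @param degree polynomial degree (default 3).
#' @param alpha FDR level for step 1 and per-term level for step 2.
#' @param r2_min minimum step-2 r-squared for selection.
#' @param lfc_min minimum max-|log2FC| versus the control for selection.
#' @return a `de_result`: data.frame with columns `feature`,
#'   `F_statistic`, `p_value`, `adj_p`, `r_squared`, `max_abs_log2fc`,
#'   `selected`, plus attribute `lfc` (the feature x (T-1) log2FC
#'   profile matrix) and `params`.
#' @export
select_differential <- function(matrix, degree = 3L, alpha = 0.05,
                                r2_min = 0.6, lfc_min = 1) {
  stopifnot(inherits(matrix, "omics_matrix"))
  sm <- matrix$sample_meta
  tps <- sort(unique(sm$timepoint))
  if (length(tps) < degree + 2L) {
    stop("need at least degree + 2 distinct timepoints")
  }
  tt <- sm$timepoint
  X <- stats::model.matrix(~ stats::poly(tt, degree, raw = TRUE))
  n <- nrow(X)
  Y <- t(matrix$values)                     # samples x features
  p_terms <- degree

  qrX <- qr(X)
  res <- qr.resid(qrX, Y)
  rss1 <- colSums(res^2)
  rss0 <- colSums(sweep(Y, 2, colMeans(Y))^2)
  df2 <- n - p_terms - 1L
  Fstat <- ((rss0 - rss1) / p_terms) / (rss1 / df2)
  pval <- stats::pf(Fstat, p_terms, df2, lower.tail = FALSE)
  flat <- rss0 < 1e-12                       # no variance at all: p := 1
  pval[flat] <- 1; Fstat[flat] <- NA_real_
  exact <- !flat & rss1 < 1e-12              # perfect polynomial fit
  pval[exact] <- 0; Fstat[exact] <- Inf
  adj_p <- stats::p.adjust(pval, method = "BH")

  lfc <- log2fc_profile(matrix, reference_timepoint = min(tps))
  max_lfc <- apply(abs(lfc), 1, max)

  r2 <- rep(NA_real_, ncol(Y))
  pass1 <- which(adj_p <= alpha & !flat)
  for (j in pass1) {
    r2[j] <- backward_r2(X, Y[, j], alpha)
  }
  sel <- !is.na(r2) & adj_p <= alpha & r2 >= r2_min & max_lfc >= lfc_min
  sel[is.na(sel)] <- FALSE

  out <- data.frame(feature = matrix$feature_ids,
                    F_statistic = Fstat, p_value = pval, adj_p = adj_p,
                    r_squared = r2, max_abs_log2fc = max_lfc,
                    selected = sel, stringsAsFactors = FALSE)
  attr(out, "lfc") <- lfc
  attr(out, "params") <- list(degree = degree, alpha = alpha,
                              r2_min = r2_min, lfc_min = lfc_min)
  class(out) <- c("de_result", "data.frame")
  out
}

# backward elimination of polynomial terms at per-term level alpha;
# returns the R^2 of the retained model (0 when all terms are dropped)
backward_r2 <- function(X, y, alpha) {
  terms <- seq_len(ncol(X) - 1L) + 1L       # columns beyond intercept
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12) return(0)
  repeat {
    if (!length(terms)) return(0)
    Xk <- X[, c(1L, terms), drop = FALSE]
    fit <- stats::lm.fit(Xk, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - length(terms) - 1L
    if (rss < 1e-12 || df <= 0) return(1 - rss / tss)
    sigma2 <- rss / df
    XtXi <- chol2inv(chol(crossprod(Xk)))
    se <- sqrt(diag(XtXi) * sigma2)
    tv <- fit$coefficients / se
    pv <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
    pv_terms <- pv[-1L]
    worst <- which.max(pv_terms)
    if (pv_terms[worst] > alpha) {
      terms <- terms[-worst]
    } else {
      return(1 - rss / tss)
    }
  }
}

#' Write a differential-selection result as TSV
#' @param de a `de_result` from [select_differential()].
#' @param path output path.
#' @param provenance optional `# `-comment header lines.
#' @export
write_de_tsv <- function(de, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  lfc <- attr(de, "lfc")
  colnames(lfc) <- paste0("log2fc_", colnames(lfc))
  utils::write.table(cbind(de, lfc), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
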