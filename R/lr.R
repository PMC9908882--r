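#' Identify regulated ligand-receptor pairs
#'
#' Searches a ligand-receptor database against the secretome (ligands)
#' and membrane/surfaceome layers (receptors). Only genes confidently
#' measured (adjusted p-value below `p_max`) in their home layer are
#' considered. For each retained pair the combined log2FC
#' C = L_log2FC + R_log2FC is computed per timepoint relative to the
#' control; a pair is regulated when |C| >= `c_min` at one or more
#' timepoints, with the sign of C giving the direction. When a
#' receptor is measured in both membrane layers the one with the
#' smaller p-value is used (ties broken by layer name).
#'
#' @param sec_de `de_result` of the secretome (ligand) layer.
#' @param mem_de,glyco_de `de_result`s of the receptor layers (either
#'   may be `NULL`).
#' @param lr_db data.frame with columns `ligand`, `receptor`
#'   (duplicate rows are deduplicated).
#' @param p_max maximum adjusted p-value for a confident measurement
#'   (default 0.01).
#' @param c_min combined log2FC threshold (default 1).
#' @param codirectional if `TRUE`, additionally require
#'   sign(L) == sign(R) at the qualifying timepoint (default `FALSE`).
#' @return data.frame with one row per regulated (pair, timepoint):
#'   `ligand`, `receptor`, `receptor_layer`, `timepoint`, `L_lfc`,
#'   `R_lfc`, `C`, `direction`, `L_p`, `R_p`. Attribute `n_skipped`
#'   counts db pairs whose ligand or receptor was not confidently
#'   measured.
#' @export
find_regulated_lr <- function(sec_de, mem_de = NULL, glyco_de = NULL,
                              lr_db, p_max = 0.01, c_min = 1,
                              codirectional = FALSE) {
  lr_db <- unique(lr_db[, c("ligand", "receptor")])
  lr_db <- lr_db[order(lr_db$ligand, lr_db$receptor), , drop = FALSE]
  get_stats <- function(de) {
    if (is.null(de)) return(NULL)
    list(p = stats::setNames(de$adj_p, de$feature), lfc = attr(de, "lfc"))
  }
  sec <- get_stats(sec_de)
  rec_layers <- Filter(Negate(is.null),
                       list(GLYCO = get_stats(glyco_de), MEM = get_stats(mem_de)))
  rows <- list(); n_skipped <- 0L
  for (k in seq_len(nrow(lr_db))) {
    L <- lr_db$ligand[k]; R <- lr_db$receptor[k]
    if (!(L %in% names(sec$p)) || is.na(sec$p[L]) || sec$p[L] >= p_max) {
      n_skipped <- n_skipped + 1L; next
    }
    # candidate receptor layers where R is confidently measured
    cand <- names(rec_layers)[vapply(rec_layers, function(s) {
      R %in% names(s$p) && !is.na(s$p[R]) && s$p[R] < p_max
    }, TRUE)]
    if (!length(cand)) { n_skipped <- n_skipped + 1L; next }
    ps <- vapply(cand, function(nm) rec_layers[[nm]]$p[R], 1.0)
    use <- sort(cand[ps == min(ps)])[1]        # smallest p, tie by layer name
    rs <- rec_layers[[use]]
    Llfc <- sec$lfc[L, ]; Rlfc <- rs$lfc[R, ]
    C <- Llfc + Rlfc
    hit <- abs(C) >= c_min
    if (codirectional) hit <- hit & (sign(Llfc) == sign(Rlfc))
    if (!any(hit)) next
    tp <- which(hit)
    rows[[length(rows) + 1L]] <- data.frame(
      ligand = L, receptor = R, receptor_layer = use,
      timepoint = colnames(sec$lfc)[tp],
      L_lfc = Llfc[tp], R_lfc = Rlfc[tp], C = C[tp],
      direction = ifelse(C[tp] >= c_min, "up", "down"),
      L_p = unname(sec$p[L]), R_p = unname(rs$p[R]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ligand = character(0), receptor = character(0),
               receptor_layer = character(0), timepoint = character(0),
               L_lfc = numeric(0), R_lfc = numeric(0), C = numeric(0),
               direction = character(0), L_p = numeric(0), R_p = numeric(0))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Score ligand-receptor crosstalk between cell clusters
#'
#' For every ordered cluster pair (x, y), including x = y, the score of
#' an L-R pair is the product of the mean ligand expression in the
#' sender cluster x and the mean receptor expression in the receiver
#' cluster y. Pairs whose ligand or receptor is absent from the
#' cluster table are skipped (counted).
#'
#' @param pairs data.frame with columns `ligand`, `receptor`
#'   (deduplicated), e.g. from [find_regulated_lr()].
#' @param clusters genes x clusters matrix of nonnegative cluster-mean
#'   expression.
#' @return data.frame `ligand`, `receptor`, `sender`, `receiver`,
#'   `score`, sorted by decreasing score; attribute `n_skipped`.
#' @export
score_cluster_crosstalk <- function(pairs, clusters) {
  if (!ncol(clusters) || !nrow(clusters)) stop("empty cluster table")
  pairs <- unique(pairs[, c("ligand", "receptor")])
  ok <- pairs$ligand %in% rownames(clusters) & pairs$receptor %in% rownames(clusters)
  n_skipped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  cl <- colnames(clusters)
  grid <- expand.grid(sender = cl, receiver = cl, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    data.frame(ligand = pairs$ligand[k], receptor = pairs$receptor[k],
               sender = grid$sender, receiver = grid$receiver,
               score = clusters[pairs$ligand[k], grid$sender] *
                       clusters[pairs$receptor[k], grid$receiver],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ligand = character(0), receptor = character(0),
               sender = character(0), receiver = character(0),
               score = numeric(0))
  out <- out[order(-out$score, out$ligand, out$sender, out$receiver), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Ligand-receptor co-occurrence correlation across samples
#'
#' Generic validation utility: Pearson correlation between ligand and
#' receptor expression across the samples of any cohort-style matrix.
#'
#' @param expression_table samples x genes numeric matrix.
#' @param pairs data.frame with columns `ligand`, `receptor`.
#' @return data.frame `ligand`, `receptor`, `pcc` (`NA` when a gene is
#'   absent or has zero variance).
#' @export
lr_cooccurrence_pcc <- function(expression_table, pairs) {
  if (nrow(expression_table) < 3L) stop("need at least 3 samples")
  pcc <- vapply(seq_len(nrow(pairs)), function(k) {
    L <- pairs$ligand[k]; R <- pairs$receptor[k]
    if (!(L %in% colnames(expression_table)) ||
        !(R %in% colnames(expression_table))) return(NA_real_)
    x <- expression_table[, L]; y <- expression_table[, R]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 1.0)
  data.frame(ligand = pairs$ligand, receptor = pairs$receptor, pcc = pcc,
             stringsAsFactors = FALSE)
}
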