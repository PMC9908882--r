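#' Construct an omics layer matrix
#'
#' An `omics_matrix` holds one measurement layer of a perturbation time
#' course: a features x samples matrix of log2 intensities together with
#' the timepoint/replicate annotation of every sample column. Columns are
#' named `t{k}_r{j}` (timepoint index `k`, 0 = untreated control;
#' replicate index `j`, 1-based).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   `NA` entries are allowed (missing measurements); all present values
#'   must be finite. Row names are the feature identifiers.
#' @param layer character scalar, the layer name (e.g. `"WCP"`, `"PHOS"`).
#' @param sample_meta optional data.frame with columns `sample`,
#'   `timepoint` (integer, 0-based) and `replicate` (integer, 1-based).
#'   When `NULL`, it is parsed from column names of the form `t{k}_r{j}`.
#'
#' @return An object of class `omics_matrix` with elements `layer`,
#'   `values`, `sample_meta` and `feature_ids`.
#' @export
omics_matrix <- function(values, layer, sample_meta = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) {
    stop("'values' must have feature identifiers as row names")
  }
  if (is.null(sample_meta)) {
    sample_meta <- parse_sample_names(colnames(values))
  }
  stopifnot(all(c("sample", "timepoint", "replicate") %in% names(sample_meta)))
  if (nrow(sample_meta) != ncol(values)) {
    stop("sample_meta must describe every column of 'values'")
  }
  present <- values[!is.na(values)]
  if (any(!is.finite(present))) {
    stop("non-finite values present in '", layer, "'")
  }
  tp <- sort(unique(sample_meta$timepoint))
  if (length(tp) < 2L) {
    stop("an omics_matrix needs at least two distinct timepoints")
  }
  structure(
    list(layer = as.character(layer), values = values,
         sample_meta = sample_meta, feature_ids = rownames(values)),
    class = "omics_matrix")
}

parse_sample_names <- function(x) {
  if (is.null(x)) stop("columns must be named t{k}_r{j} when sample_meta is absent")
  m <- regmatches(x, regexec("^t([0-9]+)_r([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed sample names: ", paste(x[bad], collapse = ", "))
  }
  data.frame(
    sample = x,
    timepoint = vapply(m, function(g) as.integer(g[2]), 1L),
    replicate = vapply(m, function(g) as.integer(g[3]), 1L),
    stringsAsFactors = FALSE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer %s: %d features x %d samples (%d timepoints x %d replicates), %.1f%% missing\n",
              x$layer, nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$timepoint)),
              length(unique(x$sample_meta$replicate)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Number of timepoints of an omics matrix
#' @param x an `omics_matrix`.
#' @return integer count of distinct timepoints.
#' @export
n_timepoints <- function(x) length(unique(x$sample_meta$timepoint))

#' Write an omics layer to TSV
#'
#' Rows are features, columns are `t{k}_r{j}` sample IDs; a `feature`
#' column holds identifiers. Provenance lines may be prepended as
#' `#`-comments.
#'
#' @param x an `omics_matrix`.
#' @param path output file path.
#' @param provenance optional character vector written as leading
#'   `# `-prefixed comment lines.
#' @export
write_omics_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics layer from TSV
#'
#' @param path TSV written by [write_omics_tsv()] (leading `#` comment
#'   lines are skipped).
#' @param layer layer name to attach; defaults to the file base name.
#' @return an `omics_matrix`.
#' @export
read_omics_tsv <- function(path, layer = NULL) {
  if (is.null(layer)) layer <- toupper(sub("\\.tsv$", "", basename(path)))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  storage.mode(vals) <- "double"
  omics_matrix(vals, layer)
}
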