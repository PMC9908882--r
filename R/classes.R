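#' Assign a regulatory class from cross-layer correlations
#'
#' Classifies a gene from the Pearson correlations of its log2FC
#' profiles between pairs of proteomic layers: Class II-B if any pair
#' is anticorrelated (r <= -0.4) -- this test takes precedence --
#' else Class I if all pairs are concordant (r >= 0.4), else Class
#' II-A (uncorrelated). `NA` correlations (zero-variance profiles) are
#' dropped; a gene with only `NA` pairs is unclassifiable.
#'
#' @param pcc_by_pair numeric vector of per-layer-pair PCCs.
#' @param r_high concordance cutoff (default 0.4).
#' @param r_low anticorrelation cutoff (default -0.4).
#' @return `"I"`, `"II-A"` or `"II-B"`.
#' @export
assign_class <- function(pcc_by_pair, r_high = 0.4, r_low = -0.4) {
  r <- pcc_by_pair[!is.na(pcc_by_pair)]
  if (!length(r)) stop("all pair correlations are NA; gene unclassifiable")
  if (any(r <= r_low)) return("II-B")
  if (all(r >= r_high)) return("I")
  "II-A"
}

#' Classify all genes shared across proteomic layers
#'
#' Computes per-gene cross-layer PCCs with [pairwise_gene_pcc()] for
#' every pair of the given layers and applies [assign_class()] to
#' genes present in at least `min_layers` layers.
#'
#' @param lfc_list named list of feature x (T-1) log2FC matrices (one
#'   per proteomic layer).
#' @param min_layers minimum number of layers a gene must appear in
#'   (default 2).
#' @param r_high,r_low class cutoffs, see [assign_class()].
#' @return data.frame with columns `gene`, `class`, `n_layer_pairs`.
#' @export
classify_genes <- function(lfc_list, min_layers = 2L,
                           r_high = 0.4, r_low = -0.4) {
  stopifnot(length(lfc_list) >= 2L, !is.null(names(lfc_list)))
  layers <- names(lfc_list)
  cnt <- table(unlist(lapply(lfc_list, rownames)))
  genes <- sort(names(cnt)[cnt >= min_layers])
  pccs <- list()
  for (i in seq_len(length(layers) - 1L)) for (j in (i + 1L):length(layers)) {
    r <- pairwise_gene_pcc(lfc_list[[i]], lfc_list[[j]])
    if (length(r)) pccs[[paste(layers[i], layers[j], sep = "|")]] <- r
  }
  rows <- lapply(genes, function(g) {
    r <- unlist(lapply(pccs, function(v) unname(v[g])))
    r <- r[!is.na(r)]
    if (!length(r)) return(NULL)
    data.frame(gene = g, class = assign_class(r, r_high, r_low),
               n_layer_pairs = length(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0), class = character(0),
                                      n_layer_pairs = integer(0))
  out
}

#' Fraction of genes maintaining their class between two classifications
#'
#' @param classes_A,classes_B named character vectors (or data.frames
#'   from [classify_genes()]) of class labels.
#' @return list with `fraction_maintained` (overall) and `per_class`
#'   (named vector over classes of A).
#' @export
class_persistence <- function(classes_A, classes_B) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$class, x$gene) else x
  }
  a <- as_vec(classes_A); b <- as_vec(classes_B)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("no shared classified genes")
  same <- a[shared] == b[shared]
  per <- tapply(same, a[shared], mean)
  list(fraction_maintained = mean(same), per_class = per, n_shared = length(shared))
}

#' Fraction of differential genes discordant with a reference layer
#'
#' Among differentially expressed genes of a layer, the fraction whose
#' log2FC-profile correlation with the reference layer does not exceed
#' `r_cut` -- genes regulated in the layer without corresponding
#' whole-cell changes. Genes with `NA` correlation (zero-variance
#' reference profile: the gene does not move in the reference) count
#' as discordant.
#'
#' @param de_genes character vector of differential genes in the layer.
#' @param pcc_vs_reference named PCC vector (e.g. from
#'   [pairwise_gene_pcc()] against the reference layer).
#' @param r_cut discordance cutoff (default 0.1).
#' @return scalar fraction in \[0, 1\].
#' @export
concordance_fraction <- function(de_genes, pcc_vs_reference, r_cut = 0.1) {
  if (!length(de_genes)) stop("empty differential gene set")
  r <- pcc_vs_reference[de_genes]
  mean(is.na(r) | r <= r_cut)
}

#' Protein-phosphosite concordance
#'
#' Correlates each phosphosite's log2FC profile with its parent
#' protein's and summarizes the fractions of poorly correlated
#' (r < `r_poor`) and opposite-trending (r <= `r_opposite`) sites.
#' Sites without a mapped, measured protein are excluded (counted).
#'
#' @param psite_lfc site x (T-1) log2FC matrix.
#' @param protein_lfc protein x (T-1) log2FC matrix.
#' @param site_to_protein_map data.frame with columns `site`, `protein`.
#' @param r_poor,r_opposite summary cutoffs (defaults 0.4 and -0.1).
#' @return list with `pcc` (named per-site vector), `fraction_poor`,
#'   `fraction_opposite`, `n_unmapped`.
#' @export
protein_phospho_concordance <- function(psite_lfc, protein_lfc,
                                        site_to_protein_map,
                                        r_poor = 0.4, r_opposite = -0.1) {
  map <- site_to_protein_map
  sites <- intersect(rownames(psite_lfc), map$site)
  prot <- map$protein[match(sites, map$site)]
  ok <- prot %in% rownames(protein_lfc)
  n_unmapped <- nrow(psite_lfc) - sum(ok)
  sites <- sites[ok]; prot <- prot[ok]
  r <- vapply(seq_along(sites), function(i) {
    a <- psite_lfc[sites[i], ]; b <- protein_lfc[prot[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 1.0)
  names(r) <- sites
  ok_r <- r[!is.na(r)]
  list(pcc = r,
       fraction_poor = mean(ok_r < r_poor),
       fraction_opposite = mean(ok_r <= r_opposite),
       n_unmapped = n_unmapped)
}

#' KSEA-style kinase activity z-scores with EMT stage aggregation
#'
#' For each kinase with at least `m_min` mapped substrate sites among
#' the regulated phosphosites, computes per timepoint the
#' mean-enrichment z-score z = (mean(substrate lfc) - mean(all lfc)) *
#' sqrt(m) / sd(all lfc), where the background is the full regulated
#' set. Absolute z-scores are then summed within the three EMT stage
#' bins of the 10-point grid: E = \{t1, t2\} (4 h, day 1), E/M =
#' \{t3, t4, t5\} (days 2-4), M = \{t6..t9\} (days 5-12).
#'
#' @param psite_lfc regulated site x timepoint log2FC matrix
#'   (columns t1..t9).
#' @param kinase_substrate_map data.frame with columns `kinase`, `site`.
#' @param m_min minimum substrate count (default 3).
#' @param stages named list mapping stage name to column indices;
#'   default the ternary EMT binning above.
#' @return data.frame: `kinase`, `m`, one `z_t*` column per timepoint,
#'   and `stage_*` columns of summed |z|.
#' @export
kinase_activity <- function(psite_lfc, kinase_substrate_map, m_min = 3L,
                            stages = list(E = 1:2, EM = 3:5, M = 6:9)) {
  bg_mean <- colMeans(psite_lfc)
  bg_sd <- apply(psite_lfc, 2, stats::sd)
  if (any(bg_sd == 0)) stop("zero background SD at some timepoint")
  map <- kinase_substrate_map[kinase_substrate_map$site %in% rownames(psite_lfc), ]
  kin <- split(map$site, map$kinase)
  kin <- kin[vapply(kin, length, 1L) >= m_min]
  rows <- lapply(names(kin), function(k) {
    s <- unique(kin[[k]]); m <- length(s)
    z <- (colMeans(psite_lfc[s, , drop = FALSE]) - bg_mean) * sqrt(m) / bg_sd
    stage_sums <- vapply(stages, function(ix) {
      ix <- ix[ix <= length(z)]
      sum(abs(z[ix]))
    }, 1.0)
    cbind(data.frame(kinase = k, m = m, stringsAsFactors = FALSE),
          as.data.frame(t(stats::setNames(z, paste0("z_", colnames(psite_lfc))))),
          as.data.frame(t(stats::setNames(stage_sums, paste0("stage_", names(stages))))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no kinase reaches the minimum substrate count")
  out[order(out$kinase), , drop = FALSE]
}
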