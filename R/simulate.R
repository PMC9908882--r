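#' Simulation configuration for synthetic multi-omics time courses
#'
#' Describes a TGF-beta-style EMT induction experiment: `n_timepoints`
#' sampling times (index 0 = untreated control, then 4 h and a daily
#' grid out to day 12) measured in `n_replicates` biological replicates
#' across several omics layers with partially overlapping feature sets.
#' Temporal signal comes from latent programs with switch-like
#' transitions (defaults: an E -> E/M switch at index 3 and an
#' E/M -> M switch at index 6 of the 10-point grid).
#'
#' @param n_timepoints number of timepoints (default 10; index 0 is the
#'   control).
#' @param n_replicates biological replicates per timepoint (default 3).
#' @param layers list of layer descriptors, each a list with `name`,
#'   `n_features`, `overlap_fraction` (fraction of features drawn from
#'   the shared core gene universe), logical `proteomic`, `kind`
#'   (`"generic"`, `"phospho"` or `"metabolite"`), and optional
#'   `censor_quantile` (left-censor values below this quantile to
#'   missing, emulating limit-of-detection dropout in metabolite-style
#'   layers; default 0 = off).
#' @param latent_programs list of `{switch_time, sharpness, amplitude}`
#'   programs; `sharpness = Inf` gives a hard step at `switch_time`.
#' @param noise_sd additive Gaussian noise SD on the log2 scale.
#' @param class_fractions length-3 numeric, proportions of planted
#'   Class I / II-A / II-B genes among differential core genes
#'   (defaults follow the empirical 1424/2775/1204 split).
#' @param frac_differential proportion of features with a nonzero
#'   temporal effect. When 0 the simulation is fully null: no class
#'   genes and no regulated ligand-receptor pairs are planted.
#' @param lr_config list `n_pairs`, `n_planted_regulated`: size of the
#'   ligand-receptor database and number of planted regulated pairs.
#' @param network_config list `n_nodes`, `n_edges`, `cascade_length`,
#'   `root_names` for the scaffold interactome generator.
#' @param n_core_genes size of the shared core gene universe.
#' @param batch_sd SD of the per-replicate-block feature offsets
#'   (batch effects removed downstream by zero-centering).
#' @param missing_fraction proportion of entries masked missing
#'   uniformly at random.
#' @param phos_coupled_fraction fraction of phosphosites whose profile
#'   tracks the parent protein (the rest get orthogonal site-level
#'   regulation).
#'
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 10L,
                       n_replicates = 3L,
                       layers = default_layers(),
                       latent_programs = list(
                         list(switch_time = 3, sharpness = Inf, amplitude = 2),
                         list(switch_time = 6, sharpness = Inf, amplitude = -1.5)),
                       noise_sd = 0.25,
                       class_fractions = c(I = 0.26, `II-A` = 0.52, `II-B` = 0.22),
                       frac_differential = 0.3,
                       lr_config = list(n_pairs = 20L, n_planted_regulated = 5L),
                       network_config = list(n_nodes = 40L, n_edges = 90L,
                                             cascade_length = 4L,
                                             root_names = c("TGFBR1", "TGFBR2")),
                       n_core_genes = 120L,
                       batch_sd = 0.2,
                       missing_fraction = 0.02,
                       phos_coupled_fraction = 0.5) {
  cfg <- list(n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates),
              layers = layers, latent_programs = latent_programs,
              noise_sd = noise_sd, class_fractions = class_fractions,
              frac_differential = frac_differential, lr_config = lr_config,
              network_config = network_config,
              n_core_genes = as.integer(n_core_genes),
              batch_sd = batch_sd, missing_fraction = missing_fraction,
              phos_coupled_fraction = phos_coupled_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_layers <- function() {
  list(
    list(name = "MRNA",    n_features = 260L, overlap_fraction = 0.8, proteomic = FALSE, kind = "generic"),
    list(name = "WCP",     n_features = 260L, overlap_fraction = 0.8, proteomic = TRUE,  kind = "generic"),
    list(name = "NUC",     n_features = 180L, overlap_fraction = 0.7, proteomic = TRUE,  kind = "generic"),
    list(name = "MEM",     n_features = 180L, overlap_fraction = 0.7, proteomic = TRUE,  kind = "generic"),
    list(name = "SEC",     n_features = 140L, overlap_fraction = 0.7, proteomic = TRUE,  kind = "generic"),
    list(name = "GLYCO",   n_features = 140L, overlap_fraction = 0.7, proteomic = TRUE,  kind = "generic"),
    list(name = "PHOS",    n_features = 200L, overlap_fraction = 0.8, proteomic = FALSE, kind = "phospho"),
    list(name = "METABOL", n_features = 60L,  overlap_fraction = 0.0, proteomic = FALSE, kind = "metabolite"))
}

validate_sim_config <- function(cfg) {
  T <- cfg$n_timepoints
  stopifnot(T >= 2L, cfg$n_replicates >= 1L)
  fr <- c(cfg$frac_differential, cfg$missing_fraction,
          cfg$phos_coupled_fraction, cfg$class_fractions,
          vapply(cfg$layers, function(l) l$overlap_fraction, 1.0))
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1")
  }
  for (p in cfg$latent_programs) {
    if (p$switch_time < 1 || p$switch_time > T - 1) {
      stop("switch_time must lie within [1, n_timepoints - 1]")
    }
  }
  nc <- cfg$network_config
  if (nc$n_edges < nc$cascade_length) stop("n_edges must be >= cascade_length")
  if (nc$cascade_length > nc$n_nodes - 1L) stop("cascade_length > n_nodes - 1")
  if (!length(nc$root_names)) stop("root_names must be non-empty")
  invisible(cfg)
}

# lfc profile (length T, entry 1 = t0 = 0) of one latent program
program_profile <- function(prog, T) {
  t <- 0:(T - 1)
  if (is.infinite(prog$sharpness)) {
    p <- ifelse(t >= prog$switch_time, prog$amplitude, 0)
  } else {
    p <- prog$amplitude * stats::plogis(prog$sharpness * (t - prog$switch_time + 0.5))
    p <- p - p[1]
  }
  p
}

# k mutually orthogonal, centered length-m vectors scaled to max|.| = amp.
# Exact zero pairwise correlation by Gram-Schmidt on centered draws.
orthogonal_profiles <- function(k, m, amp) {
  stopifnot(k < m)
  V <- matrix(stats::rnorm(k * m), nrow = m)
  V <- sweep(V, 2, colMeans(V))
  for (j in seq_len(k)) {
    if (j > 1) {
      for (i in seq_len(j - 1)) {
        V[, j] <- V[, j] - sum(V[, j] * V[, i]) / sum(V[, i]^2) * V[, i]
      }
    }
  }
  apply(V, 2, function(v) v / max(abs(v)) * amp)
}

#' Simulate a multi-layer omics time course with planted ground truth
#'
#' Generates one `omics_matrix` per configured layer. Differential core
#' genes shared by >= 2 proteomic layers carry planted regulatory
#' classes: Class I genes share one latent temporal profile across all
#' their layers, Class II-B genes have the profile sign-flipped in one
#' designated layer, and Class II-A genes carry exactly orthogonal
#' (zero-correlation) profiles between layers. Ligand/receptor genes
#' (`LIG*` in SEC, `REC*` in MEM/GLYCO) implement the planted crosstalk
#' pairs. Phosphosites are named `<gene>_S<k>` and either track their
#' parent protein or carry independent site-level regulation.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical `(config, seed)` give identical
#'   output.
#' @return list with `layers` (named list of `omics_matrix`) and
#'   `truth` (differential features per layer, class labels, planted
#'   log2FC profiles, ligand-receptor database and planted pairs,
#'   phosphosite coupling, site-to-protein map).
#' @export
simulate_multiomics <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  T <- config$n_timepoints
  R <- config$n_replicates
  core <- sprintf("G%06d", seq_len(config$n_core_genes))
  lr <- make_lr_db(config)

  lay_names <- vapply(config$layers, `[[`, "", "name")
  prot <- vapply(config$layers, function(l) isTRUE(l$proteomic), TRUE)

  # feature sets per layer
  next_private <- config$n_core_genes
  feats <- list()
  for (l in config$layers) {
    n_core_l <- min(round(l$overlap_fraction * l$n_features), length(core))
    core_l <- sort(sample(core, n_core_l))
    n_priv <- l$n_features - n_core_l
    if (l$kind == "metabolite") {
      priv <- sprintf("MET:M%04d", seq_len(l$n_features))
      core_l <- character(0)
    } else {
      priv <- sprintf("G%06d", next_private + seq_len(n_priv))
      next_private <- next_private + n_priv
    }
    feats[[l$name]] <- c(core_l, priv)
  }
  # append ligand/receptor genes to their home layers
  has_lr_layers <- all(c("SEC", "MEM", "GLYCO") %in% lay_names)
  if (!has_lr_layers) lr <- list(db = lr$db[0, ], n_planted = 0L)
  if (nrow(lr$db)) {
    feats[["SEC"]] <- c(feats[["SEC"]], lr$db$ligand)
    feats[["MEM"]] <- c(feats[["MEM"]], lr$db$receptor[lr$db$receptor_layer == "MEM"])
    feats[["GLYCO"]] <- c(feats[["GLYCO"]], lr$db$receptor[lr$db$receptor_layer == "GLYCO"])
  }
  # phospho layer measures sites on its sampled genes
  phos_idx <- which(vapply(config$layers, function(l) l$kind == "phospho", TRUE))
  site_map <- NULL
  for (i in phos_idx) {
    nm <- config$layers[[i]]$name
    genes <- feats[[nm]]
    sites <- paste0(genes, "_S", sample(1:999, length(genes), replace = TRUE))
    site_map <- rbind(site_map, data.frame(site = sites, protein = genes,
                                           stringsAsFactors = FALSE))
    feats[[nm]] <- sites
  }

  # shared-core class structure on genes in >= 2 proteomic layers
  prot_feats <- feats[lay_names[prot]]
  core_presence <- sapply(prot_feats, function(f) core %in% f)
  shared <- core[rowSums(core_presence) >= 2L]
  if (length(shared) < 2L) {
    stop("overlap_fraction too low: < 2 shared genes between proteomic layers")
  }
  n_diff_shared <- round(config$frac_differential * length(shared))
  class_genes <- if (n_diff_shared > 0) sort(sample(shared, n_diff_shared)) else character(0)
  cls <- character(0)
  if (length(class_genes)) {
    cls <- sample(names(config$class_fractions), length(class_genes),
                  replace = TRUE, prob = config$class_fractions)
    names(cls) <- class_genes
  }

  # planted lfc profiles per layer (rows = features, cols = t0..t{T-1})
  progs <- lapply(config$latent_programs, program_profile, T = T)
  amp_min <- min(vapply(progs, function(p) max(abs(p)), 1.0))
  pick_prog <- function(n) sample(seq_along(progs), n, replace = TRUE)

  lfc <- lapply(feats, function(f) {
    m <- matrix(0, length(f), T, dimnames = list(f, paste0("t", 0:(T - 1))))
    m
  })

  # class genes: per-layer profiles by class rule (proteomic layers + MRNA)
  class_layers <- c(lay_names[prot], intersect("MRNA", lay_names))
  for (g in class_genes) {
    in_layers <- class_layers[vapply(class_layers, function(nm) g %in% feats[[nm]], TRUE)]
    prot_in <- intersect(lay_names[prot], in_layers)
    base <- progs[[pick_prog(1)]]
    if (cls[g] == "I") {
      for (nm in in_layers) lfc[[nm]][g, ] <- base
    } else if (cls[g] == "II-B") {
      flip <- prot_in[length(prot_in)]   # designated anticorrelated layer
      for (nm in in_layers) lfc[[nm]][g, ] <- if (nm == flip) -base else base
    } else { # II-A: exactly orthogonal per-layer profiles over t1..t{T-1}
      P <- orthogonal_profiles(length(in_layers), T - 1L, 2)
      for (j in seq_along(in_layers)) lfc[[in_layers[j]]][g, -1] <- P[, j]
    }
  }

  # shared non-class core genes: one coherent profile wherever they occur
  # (cross-layer coherence is the norm; the planted classes are the
  # controlled exceptions)
  shared_rest <- setdiff(shared, class_genes)
  n_d_shared <- round(config$frac_differential * length(shared_rest))
  if (n_d_shared > 0) {
    chosen <- sort(sample(shared_rest, n_d_shared))
    pr <- pick_prog(length(chosen))
    sgn <- sample(c(-1, 1), length(chosen), replace = TRUE)
    gene_layers <- setdiff(lay_names, lay_names[phos_idx])
    for (j in seq_along(chosen)) {
      prof <- sgn[j] * progs[[pr[j]]]
      for (nm in gene_layers) {
        if (chosen[j] %in% feats[[nm]]) lfc[[nm]][chosen[j], ] <- prof
      }
    }
  }

  # remaining differential features per layer: latent-program profiles
  for (nm in lay_names) {
    f <- feats[[nm]]
    f_sites <- nm %in% lay_names[phos_idx]
    pool <- if (f_sites) f else setdiff(f, c(shared, lr$db$ligand, lr$db$receptor))
    n_d <- round(config$frac_differential * length(pool))
    if (n_d > 0) {
      chosen <- sample(pool, n_d)
      pr <- pick_prog(n_d)
      sgn <- sample(c(-1, 1), n_d, replace = TRUE)
      for (j in seq_along(chosen)) {
        lfc[[nm]][chosen[j], ] <- sgn[j] * progs[[pr[j]]]
      }
    }
  }

  # phospho sites: coupled sites inherit the parent protein's WCP profile
  phos_coupled <- NULL
  if (length(phos_idx) && "WCP" %in% lay_names) {
    for (i in phos_idx) {
      nm <- config$layers[[i]]$name
      sites <- feats[[nm]]
      parents <- site_map$protein[match(sites, site_map$site)]
      coupled <- stats::runif(length(sites)) < config$phos_coupled_fraction
      for (j in seq_along(sites)) {
        if (coupled[j] && parents[j] %in% rownames(lfc[["WCP"]])) {
          lfc[[nm]][sites[j], ] <- lfc[["WCP"]][parents[j], ]
        }
      }
      phos_coupled <- stats::setNames(coupled, sites)
    }
  }

  # planted regulated L-R pairs: step profiles on both partners
  n_plant <- if (config$frac_differential > 0) lr$n_planted else 0L
  if (n_plant > 0) {
    for (i in seq_len(n_plant)) {
      prof <- progs[[pick_prog(1)]]
      dirn <- sample(c(-1, 1), 1)
      lfc[["SEC"]][lr$db$ligand[i], ] <- dirn * prof
      rl <- lr$db$receptor_layer[i]
      lfc[[rl]][lr$db$receptor[i], ] <- dirn * prof * 0.75
    }
  }

  # assemble intensity matrices
  samp <- expand.grid(replicate = seq_len(R), timepoint = 0:(T - 1))
  samp <- samp[order(samp$timepoint, samp$replicate), , drop = FALSE]
  cn <- sprintf("t%d_r%d", samp$timepoint, samp$replicate)
  layers_out <- list()
  for (li in seq_along(config$layers)) {
    l <- config$layers[[li]]
    f <- feats[[l$name]]
    base <- stats::rnorm(length(f), mean = 25, sd = 2)
    batch <- matrix(stats::rnorm(length(f) * R, sd = config$batch_sd), ncol = R)
    V <- matrix(0, length(f), length(cn), dimnames = list(f, cn))
    for (ci in seq_along(cn)) {
      tp <- samp$timepoint[ci]; rp <- samp$replicate[ci]
      V[, ci] <- base + lfc[[l$name]][, tp + 1L] + batch[, rp] +
        stats::rnorm(length(f), sd = config$noise_sd)
    }
    if (config$missing_fraction > 0) {
      V[stats::runif(length(V)) < config$missing_fraction] <- NA
    }
    cq <- l$censor_quantile
    if (!is.null(cq) && cq > 0) {  # left-censoring for metabolite-style layers
      V[V < stats::quantile(V, cq, na.rm = TRUE)] <- NA
    }
    layers_out[[l$name]] <- omics_matrix(V, l$name)
  }

  diff_feats <- lapply(lfc, function(m) {
    rownames(m)[apply(abs(m), 1, max) > 0]
  })
  truth <- list(
    differential_features = diff_feats,
    class_label = cls,
    planted_lfc = lapply(lfc, function(m) m[, -1, drop = FALSE]),
    proteomic_layers = lay_names[prot],
    lr_db = lr$db,
    lr_planted = if (n_plant > 0) lr$db[seq_len(n_plant), c("ligand", "receptor")] else lr$db[0, c("ligand", "receptor")],
    phos_coupled = phos_coupled,
    site_map = site_map,
    # planted receptors carry 75% of the ligand amplitude; everything
    # else carries at least the smallest program amplitude
    effect_size = if (n_plant > 0) 0.75 * amp_min else amp_min)
  list(layers = layers_out, truth = truth)
}

make_lr_db <- function(config) {
  n <- config$lr_config$n_pairs
  np <- config$lr_config$n_planted_regulated
  if (np > n) stop("n_planted_regulated > n_pairs")
  db <- data.frame(
    ligand = sprintf("LIG%03d", seq_len(n)),
    receptor = sprintf("REC%03d", seq_len(n)),
    receptor_layer = rep(c("MEM", "GLYCO"), length.out = n),
    stringsAsFactors = FALSE)
  list(db = db, n_planted = as.integer(np))
}

#' Simulate a directed typed scaffold interactome with a planted cascade
#'
#' Plants a signaling cascade `root -> K1 -> ... -> K_L` (L =
#' `cascade_length` edges) below the first configured root, embedded in
#' random background edges. Background edges never point into the
#' cascade or the roots, so with a large prize scale the cascade prefix
#' of activated nodes is the unique optimal Steiner forest. Cascade
#' node `K_i` becomes differential (|log2FC| = 2 > 1) from timepoint
#' `min(i, T-1)` onward; the returned node-level log2FC table feeds
#' [cumulative_prizes()].
#'
#' @param config a [sim_config()]; uses `network_config`.
#' @param seed integer seed.
#' @return list with `interactome` (edge data.frame: source, target,
#'   type, sign) and `truth` (cascade nodes/edges, activation times,
#'   node x timepoint log2FC matrix, root names).
#' @export
simulate_interactome <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  nc <- config$network_config
  T <- config$n_timepoints
  roots <- nc$root_names
  L <- nc$cascade_length
  casc <- sprintf("K%02d", seq_len(L))
  n_bg_nodes <- nc$n_nodes - length(roots) - L
  if (n_bg_nodes < 0) stop("n_nodes too small for roots plus cascade")
  bg <- if (n_bg_nodes > 0) sprintf("N%03d", seq_len(n_bg_nodes)) else character(0)
  nodes <- c(roots, casc, bg)

  edge_types <- c("kinase->target", "TF->target", "TF->miRNA", "signaling",
                  "miRNA->gene", "gene->metabolite", "phosphatase->target")
  casc_edges <- data.frame(source = c(roots[1], casc[-L]), target = casc,
                           type = "signaling", sign = 1L,
                           stringsAsFactors = FALSE)
  n_bg <- nc$n_edges - L
  bg_edges <- NULL
  if (n_bg > 0) {
    if (!length(bg)) stop("background edges requested but no background nodes")
    # targets restricted to background nodes: the cascade stays the only
    # route to prized nodes
    src <- sample(nodes, 4 * n_bg, replace = TRUE)
    tgt <- sample(bg, 4 * n_bg, replace = TRUE)
    keep <- src != tgt
    bg_edges <- unique(data.frame(source = src[keep], target = tgt[keep],
                                  stringsAsFactors = FALSE))
    bg_edges <- utils::head(bg_edges, n_bg)
    bg_edges$type <- sample(edge_types, nrow(bg_edges), replace = TRUE)
    bg_edges$sign <- sample(c(-1L, 1L), nrow(bg_edges), replace = TRUE)
  }
  edges <- rbind(casc_edges, bg_edges)

  act <- pmin(seq_len(L), T - 1L)
  names(act) <- casc
  lfc <- matrix(0, length(nodes), T - 1L,
                dimnames = list(nodes, paste0("t", seq_len(T - 1L))))
  for (i in seq_len(L)) lfc[casc[i], act[i]:(T - 1L)] <- 2

  list(interactome = edges,
       truth = list(cascade_nodes = c(roots[1], casc),
                    cascade_edges = casc_edges[, c("source", "target")],
                    activation = act, lfc = lfc, roots = roots))
}

#' Simulate cluster-mean expression with planted sender/receiver pairs
#'
#' Emulates a per-cluster average expression table (as produced from a
#' clustered scRNA-seq experiment) over the ligand/receptor genes of the
#' configured database plus background genes. For each planted regulated
#' pair, one sender cluster gets an elevated ligand mean and one
#' receiver cluster an elevated receptor mean.
#'
#' @param config a [sim_config()]; uses `lr_config`.
#' @param seed integer seed.
#' @param n_clusters number of cell clusters (default 6).
#' @return list with `clusters` (genes x clusters matrix of nonnegative
#'   means) and `truth` (data.frame pair/ligand/receptor/sender/receiver).
#' @export
simulate_cluster_expression <- function(config, seed = 1L, n_clusters = 6L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  lr <- make_lr_db(config)
  genes <- c(lr$db$ligand, lr$db$receptor, sprintf("BGG%03d", 1:30))
  cl <- sprintf("C%02d", seq_len(n_clusters))
  M <- matrix(stats::rexp(length(genes) * n_clusters, rate = 2),
              nrow = length(genes), dimnames = list(genes, cl))
  np <- lr$n_planted
  truth <- data.frame(pair = integer(0), ligand = character(0),
                      receptor = character(0), sender = character(0),
                      receiver = character(0), stringsAsFactors = FALSE)
  if (np > 0) {
    send <- sample(cl, np, replace = TRUE)
    recv <- sample(cl, np, replace = TRUE)
    for (i in seq_len(np)) {
      M[lr$db$ligand[i], send[i]] <- M[lr$db$ligand[i], send[i]] + 4
      M[lr$db$receptor[i], recv[i]] <- M[lr$db$receptor[i], recv[i]] + 4
    }
    truth <- data.frame(pair = seq_len(np), ligand = lr$db$ligand[seq_len(np)],
                        receptor = lr$db$receptor[seq_len(np)],
                        sender = send, receiver = recv,
                        stringsAsFactors = FALSE)
  }
  list(clusters = M, truth = truth)
}
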