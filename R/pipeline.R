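#' Assemble a full pipeline run configuration
#'
#' Bundles the simulation block (or paths to layer TSVs), all stage
#' thresholds and the global seed. Threshold defaults are the
#' standard operating values of the workflow: differential selection
#' at adj. p <= 0.05, r^2 >= 0.6, |log2FC| >= 1; class cutoffs +-0.4;
#' discordance cutoff r <= 0.1; L-R confidence p < 0.01 and |C| >= 1;
#' skeleton epsilon 0.1; PCSF beta = 10, mu = 0, omega = 5, D = 5
#' rooted at TGFBR1/TGFBR2; KSEA substrate minimum 3.
#'
#' @param sim a [sim_config()] for simulated input, or `NULL` when
#'   `layer_paths` point at TSV files.
#' @param layer_paths named character vector of layer TSVs (ignored
#'   when `sim` is given).
#' @param seed global seed; per-stage child seeds are derived from it
#'   by stable hashing of the stage name.
#' @param out_dir output directory.
#' @param alpha,r2_min,lfc_min differential-selection thresholds.
#' @param degree polynomial degree of the time-course model.
#' @param r_high,r_low regulatory-class cutoffs.
#' @param r_cut discordance cutoff for [concordance_fraction()].
#' @param p_max,c_min L-R confidence and combined-log2FC thresholds.
#' @param epsilon skeleton removal threshold.
#' @param pcsf a [pcsf_params()].
#' @param m_min minimum kinase substrate count.
#' @param stages character vector of stage names to run (subset of
#'   simulate, de, topology, classes, lr, network, control).
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), layer_paths = NULL, seed = 1L,
                       out_dir = tempfile("emtomics_run_"),
                       alpha = 0.05, r2_min = 0.6, lfc_min = 1,
                       degree = 3L, r_high = 0.4, r_low = -0.4,
                       r_cut = 0.1, p_max = 0.01, c_min = 1,
                       epsilon = 0.1, pcsf = pcsf_params(), m_min = 3L,
                       stages = c("simulate", "de", "topology", "classes",
                                  "lr", "network", "control")) {
  stopifnot(alpha > 0, alpha <= 1, r2_min >= 0, r2_min <= 1, lfc_min >= 0,
            epsilon > 0, epsilon < 1, p_max > 0, c_min >= 0,
            inherits(pcsf, "pcsf_params"))
  structure(list(sim = sim, layer_paths = layer_paths, seed = as.integer(seed),
                 out_dir = out_dir, alpha = alpha, r2_min = r2_min,
                 lfc_min = lfc_min, degree = degree, r_high = r_high,
                 r_low = r_low, r_cut = r_cut, p_max = p_max, c_min = c_min,
                 epsilon = epsilon, pcsf = pcsf, m_min = m_min,
                 stages = stages),
            class = "run_config")
}

# stable per-stage child seed below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the full pipeline end-to-end
#'
#' Executes (optionally) simulation, preprocessing + differential
#' selection per layer, layer topology, regulatory classes, L-R
#' crosstalk, temporal network reconstruction and controllability on
#' the union of the per-timepoint forests, writing TSV/JSON/GraphML
#' artifacts and a JSON manifest with file hashes and a parameter
#' echo. Deterministic given the config and seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) list with in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) if (!quiet) message(sprintf(...))
  prov <- sprintf("emtomics %s seed=%d",
                  as.character(utils::packageVersion("emtomics")), config$seed)
  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- input layers ------------------------------------------------------
  if ("simulate" %in% config$stages && !is.null(config$sim)) {
    sim <- run_stage("simulate", function() {
      simulate_multiomics(config$sim, seed = stage_seed(config$seed, "simulate"))
    })
    layers <- sim$layers
    results$truth <- sim$truth
    log_line("simulate: %d layers", length(layers))
  } else {
    if (is.null(config$layer_paths)) stop("no simulation block and no layer paths")
    missing <- config$layer_paths[!file.exists(config$layer_paths)]
    if (length(missing)) stop("missing layer file(s): ", toString(missing))
    layers <- lapply(config$layer_paths, read_omics_tsv)
    names(layers) <- names(config$layer_paths)
  }

  # --- preprocess + differential selection -------------------------------
  de <- list()
  if ("de" %in% config$stages) {
    de <- run_stage("de", function() {
      lapply(layers, function(m) {
        pm <- preprocess_omics(m, impute_method = "half_minimum")
        select_differential(pm, degree = config$degree, alpha = config$alpha,
                            r2_min = config$r2_min, lfc_min = config$lfc_min)
      })
    })
    for (nm in names(de)) {
      write_de_tsv(de[[nm]], file.path(config$out_dir, paste0(tolower(nm), "_de.tsv")),
                   provenance = prov)
      log_line("de[%s]: %d features in, %d selected", nm,
               nrow(de[[nm]]), sum(de[[nm]]$selected))
    }
    results$de <- de
  }
  lfc_of <- function(nm) attr(de[[nm]], "lfc")

  # --- layer topology ----------------------------------------------------
  if ("topology" %in% config$stages && length(layers) >= 3) {
    topo <- run_stage("topology", function() {
      pre <- lapply(layers, function(m)
        preprocess_omics(m, impute_method = "half_minimum"))
      rv <- rv_matrix(pre)
      skel <- topology_skeleton(rv, epsilon = config$epsilon)
      list(rv = rv, skeleton = skel)
    })
    utils::write.table(topo$rv, file.path(config$out_dir, "rv_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    igraph::write_graph(topo$skeleton,
                        file.path(config$out_dir, "topology_skeleton.graphml"),
                        format = "graphml")
    log_line("topology: %d skeleton edges", igraph::ecount(topo$skeleton))
    results$topology <- topo
  }

  # --- regulatory classes ------------------------------------------------
  if ("classes" %in% config$stages && length(de)) {
    prot <- intersect(c("WCP", "NUC", "MEM", "SEC", "GLYCO", "EXOS"), names(de))
    if (length(prot) >= 2) {
      classes <- run_stage("classes", function() {
        classify_genes(stats::setNames(lapply(prot, lfc_of), prot),
                       r_high = config$r_high, r_low = config$r_low)
      })
      utils::write.table(classes, file.path(config$out_dir, "classes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line("classes: %d genes classified (%s)", nrow(classes),
               paste(names(table(classes$class)), table(classes$class),
                     sep = "=", collapse = ", "))
      results$classes <- classes
    }
  }

  # --- L-R crosstalk -----------------------------------------------------
  if ("lr" %in% config$stages && !is.null(results$truth) &&
      all(c("SEC", "MEM", "GLYCO") %in% names(de))) {
    lr <- run_stage("lr", function() {
      pairs <- find_regulated_lr(de[["SEC"]], de[["MEM"]], de[["GLYCO"]],
                                 lr_db = results$truth$lr_db,
                                 p_max = config$p_max, c_min = config$c_min)
      cl <- simulate_cluster_expression(config$sim,
                                        seed = stage_seed(config$seed, "clusters"))
      scores <- if (nrow(pairs)) score_cluster_crosstalk(pairs, cl$clusters) else NULL
      list(pairs = pairs, scores = scores)
    })
    utils::write.table(lr$pairs, file.path(config$out_dir, "lr_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("lr: %d regulated pair-timepoints", nrow(lr$pairs))
    results$lr <- lr
  }

  # --- temporal network --------------------------------------------------
  forests <- NULL
  if ("network" %in% config$stages && !is.null(config$sim)) {
    net <- run_stage("network", function() {
      si <- simulate_interactome(config$sim,
                                 seed = stage_seed(config$seed, "interactome"))
      inter <- assign_edge_weights(si$interactome)
      prizes <- cumulative_prizes(list(si$truth$lfc))
      params <- config$pcsf
      params$roots <- intersect(params$roots, c(inter$source, inter$target))
      if (!length(params$roots)) params$roots <- si$truth$roots
      series <- run_temporal_series(inter, prizes, params, mode = "heuristic")
      list(interactome = inter, prizes = prizes, series = series,
           truth = si$truth)
    })
    forests <- net$series$forests
    for (nm in names(forests)) {
      igraph::write_graph(forest_to_igraph(forests[[nm]]),
                          file.path(config$out_dir, paste0("forest_", nm, ".graphml")),
                          format = "graphml")
    }
    fa <- net$series$first_appearance
    utils::write.table(
      data.frame(node = names(fa), first_appearance_t = fa),
      file.path(config$out_dir, "forest_growth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("network: final forest %d nodes / %d edges",
             nrow(forests[[length(forests)]]$nodes),
             nrow(forests[[length(forests)]]$edges))
    results$network <- net
  }

  # --- controllability on the union of per-timepoint forests -------------
  if ("control" %in% config$stages && !is.null(forests)) {
    ctl <- run_stage("control", function() {
      union_edges <- unique(do.call(rbind, lapply(forests, function(f)
        f$edges[, c("source", "target")])))
      classify_nodes(union_edges)
    })
    utils::write.table(ctl, file.path(config$out_dir, "control.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("control: N_D=%d, %.1f%% controllers", attr(ctl, "N_D"),
             100 * controller_fraction(ctl))
    results$control <- ctl
  }

  # --- manifest ----------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    tool = "emtomics",
    version = as.character(utils::packageVersion("emtomics")),
    seed = config$seed,
    params = list(alpha = config$alpha, r2_min = config$r2_min,
                  lfc_min = config$lfc_min, r_high = config$r_high,
                  r_low = config$r_low, r_cut = config$r_cut,
                  p_max = config$p_max, c_min = config$c_min,
                  epsilon = config$epsilon,
                  beta = config$pcsf$beta, mu = config$pcsf$mu,
                  omega = config$pcsf$omega, D = config$pcsf$D,
                  roots = config$pcsf$roots, m_min = config$m_min),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
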