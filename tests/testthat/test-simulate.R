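test_that("simulation is deterministic given (config, seed)", {
  cfg <- sim_config()
  a <- simulate_multiomics(cfg, seed = 42)
  b <- simulate_multiomics(cfg, seed = 42)
  expect_identical(lapply(a$layers, `[[`, "values"),
                   lapply(b$layers, `[[`, "values"))
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_interactome(cfg, 7)$interactome,
                   simulate_interactome(cfg, 7)$interactome)
  expect_identical(simulate_cluster_expression(cfg, 9)$clusters,
                   simulate_cluster_expression(cfg, 9)$clusters)
})

test_that("zero-noise planted switch gives exact replicate-mean log2FC", {
  cfg <- sim_config(noise_sd = 0, missing_fraction = 0, batch_sd = 0,
                    latent_programs = list(list(switch_time = 2, sharpness = Inf,
                                                amplitude = 2)),
                    frac_differential = 0.5)
  sim <- simulate_multiomics(cfg, seed = 1)
  lfc <- log2fc_profile(sim$layers$WCP)
  planted <- sim$truth$planted_lfc$WCP
  diff_w <- intersect(rownames(lfc), sim$truth$differential_features$WCP)
  expect_gt(length(diff_w), 0)
  # every planted differential feature reproduces its planted profile exactly
  expect_equal(lfc[diff_w, ], planted[diff_w, ], tolerance = 1e-12)
  # the step program: 0 before t2, amplitude 2 from t2 on (for step-profile genes)
  step_genes <- diff_w[abs(planted[diff_w, "t1"]) < 1e-12 &
                         abs(abs(planted[diff_w, "t9"]) - 2) < 1e-12]
  expect_gt(length(step_genes), 0)
  g <- step_genes[1]
  expect_equal(unname(lfc[g, "t1"]), 0)
  expect_equal(abs(unname(lfc[g, c("t2", "t5", "t9")])), rep(2, 3))
})

test_that("null configuration plants nothing", {
  cfg <- sim_config(frac_differential = 0)
  sim <- simulate_multiomics(cfg, seed = 3)
  expect_true(all(lengths(sim$truth$differential_features) == 0))
  expect_length(sim$truth$class_label, 0)
  expect_equal(nrow(sim$truth$lr_planted), 0)
})

test_that("planted class structure has exact zero-noise correlations", {
  cfg <- sim_config(noise_sd = 0, missing_fraction = 0, batch_sd = 0)
  sim <- simulate_multiomics(cfg, seed = 11)
  truth <- sim$truth
  prot <- truth$proteomic_layers
  for (g in names(truth$class_label)) {
    in_layers <- prot[vapply(prot, function(nm)
      g %in% rownames(truth$planted_lfc[[nm]]), TRUE)]
    pr <- utils::combn(in_layers, 2, simplify = FALSE)
    r <- vapply(pr, function(pair) {
      cor(truth$planted_lfc[[pair[1]]][g, ], truth$planted_lfc[[pair[2]]][g, ])
    }, 1.0)
    cl <- truth$class_label[[g]]
    if (cl == "I") expect_true(all(r > 1 - 1e-9))
    if (cl == "II-B") expect_true(any(r < -1 + 1e-9))
    if (cl == "II-A") expect_true(all(abs(r) < 1e-9))
  }
})

test_that("planted differential amplitudes respect the stated effect size", {
  cfg <- sim_config()
  sim <- simulate_multiomics(cfg, seed = 5)
  for (nm in names(sim$truth$differential_features)) {
    d <- sim$truth$differential_features[[nm]]
    if (!length(d)) next
    m <- apply(abs(sim$truth$planted_lfc[[nm]][d, , drop = FALSE]), 1, max)
    expect_true(all(m >= sim$truth$effect_size - 1e-9))
  }
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(frac_differential = 1.2), "fractions")
  expect_error(sim_config(latent_programs = list(
    list(switch_time = 0, sharpness = Inf, amplitude = 1))), "switch_time")
  expect_error(sim_config(network_config = list(
    n_nodes = 10L, n_edges = 2L, cascade_length = 4L, root_names = "R")),
    "n_edges")
  expect_error(sim_config(network_config = list(
    n_nodes = 4L, n_edges = 9L, cascade_length = 4L, root_names = "R")),
    "cascade_length")
  expect_error(sim_config(lr_config = list(n_pairs = 3L, n_planted_regulated = 5L)) |>
                 simulate_multiomics(seed = 1), "n_planted")
})

test_that("forced cascade topology is the exact path", {
  cfg <- sim_config(network_config = list(n_nodes = 5L, n_edges = 4L,
                                          cascade_length = 4L,
                                          root_names = "TGFBR1"))
  si <- simulate_interactome(cfg, seed = 2)
  expect_equal(nrow(si$interactome), 4)
  expect_equal(si$interactome$source, c("TGFBR1", "K01", "K02", "K03"))
  expect_equal(si$interactome$target, c("K01", "K02", "K03", "K04"))
  expect_true(all(si$interactome$type %in% c("kinase->target", "TF->target",
                                             "TF->miRNA", "signaling",
                                             "miRNA->gene", "gene->metabolite",
                                             "phosphatase->target")))
})

test_that("cluster expression plants elevated sender/receiver means", {
  cfg <- sim_config()
  sc <- simulate_cluster_expression(cfg, seed = 4)
  expect_true(all(sc$clusters >= 0))
  for (i in seq_len(nrow(sc$truth))) {
    row <- sc$truth[i, ]
    expect_gte(sc$clusters[row$ligand, row$sender], 4)
    expect_gte(sc$clusters[row$receptor, row$receiver], 4)
  }
})
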