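test_that("class rule and its precedence", {
  expect_equal(assign_class(c(0.8, 0.6, 0.9)), "I")
  expect_equal(assign_class(c(0.8, -0.5)), "II-B")
  expect_equal(assign_class(c(0.1, 0.3)), "II-A")
  # anticorrelation takes precedence even with other high pairs
  expect_equal(assign_class(c(0.9, 0.95, -0.41)), "II-B")
  # boundary values: r = 0.4 counts as concordant, r = -0.4 as anticorrelated
  expect_equal(assign_class(c(0.4, 0.4)), "I")
  expect_equal(assign_class(c(-0.4)), "II-B")
  # NA pairs are dropped; all-NA is an error
  expect_equal(assign_class(c(NA, 0.5)), "I")
  expect_error(assign_class(c(NA_real_, NA_real_)), "unclassifiable")
  # invariant to pair order and to duplicated non-boundary values
  expect_equal(assign_class(c(0.6, 0.8)), assign_class(c(0.8, 0.6)))
  expect_equal(assign_class(c(0.1, 0.3, 0.3)), assign_class(c(0.1, 0.3)))
})

test_that("class persistence is 1 for identical inputs and ~1/3 under permutation", {
  a <- setNames(sample(c("I", "II-A", "II-B"), 3000, replace = TRUE),
                sprintf("g%04d", 1:3000))
  expect_equal(class_persistence(a, a)$fraction_maintained, 1)
  set.seed(10)
  b <- setNames(sample(c("I", "II-A", "II-B"), 3000, replace = TRUE),
                names(a))
  expect_equal(class_persistence(a, b)$fraction_maintained, 1 / 3,
               tolerance = 0.05)
  d <- setNames(a[1:5], paste0("other", 1:5))
  expect_error(class_persistence(a[1:5], d), "no shared")
})

test_that("discordance fraction counts low-correlation DE genes", {
  genes <- paste0("g", 1:10)
  all_one <- setNames(rep(1, 10), genes)
  expect_equal(concordance_fraction(genes, all_one), 0)
  all_zero <- setNames(rep(0, 10), genes)
  expect_equal(concordance_fraction(genes, all_zero), 1)
  mixed <- setNames(c(rep(0, 3), rep(1, 7)), genes)
  expect_equal(concordance_fraction(genes, mixed), 0.3)
  # monotone non-decreasing in r_cut
  set.seed(2)
  r <- setNames(runif(50, -1, 1), paste0("g", 1:50))
  cuts <- seq(-1, 1, by = 0.25)
  vals <- vapply(cuts, function(ct) concordance_fraction(names(r), r, ct), 1.0)
  expect_true(all(diff(vals) >= 0))
  expect_error(concordance_fraction(character(0), all_one), "empty")
})

test_that("protein-phosphosite concordance counts the two fractions", {
  prof <- matrix(rnorm(9), 1, 9, dimnames = list("P1", paste0("t", 1:9)))
  sites <- rbind(P1_S1 = prof[1, ], P1_S2 = -prof[1, ])
  map <- data.frame(site = c("P1_S1", "P1_S2"), protein = "P1")
  res <- protein_phospho_concordance(sites, prof, map)
  expect_equal(unname(res$pcc["P1_S1"]), 1)
  expect_equal(unname(res$pcc["P1_S2"]), -1)
  expect_equal(res$fraction_poor, 0.5)       # only the flipped site
  expect_equal(res$fraction_opposite, 0.5)
})

test_that("planted coupled/independent phosphosite mixture is recovered", {
  cfg <- sim_config(noise_sd = 0, missing_fraction = 0, batch_sd = 0)
  sim <- simulate_multiomics(cfg, seed = 31)
  ph <- sim$truth$planted_lfc$PHOS
  wcp <- sim$truth$planted_lfc$WCP
  res <- protein_phospho_concordance(ph, wcp, sim$truth$site_map)
  r <- res$pcc[!is.na(res$pcc)]
  coupled <- sim$truth$phos_coupled[names(r)]
  # every coupled site with a moving parent correlates perfectly
  expect_true(all(r[coupled] > 1 - 1e-9))
})

test_that("kinase z-scores have the analytic mean shift", {
  set.seed(7)
  z <- replicate(100, {
    lfc <- matrix(rnorm(5016), ncol = 1,
                  dimnames = list(paste0("s", 1:5016), "t1"))
    lfc[1:16, 1] <- lfc[1:16, 1] + 1
    ka <- kinase_activity(lfc, data.frame(kinase = "K1",
                                          site = paste0("s", 1:16)),
                          stages = list(E = 1))
    ka$z_t1
  })
  expect_equal(mean(z), 4, tolerance = 0.35)
  # null substrates: z near 0
  set.seed(8)
  lfc <- matrix(rnorm(500), ncol = 1,
                dimnames = list(paste0("s", 1:500), "t1"))
  ka0 <- kinase_activity(lfc, data.frame(kinase = "K1", site = paste0("s", 1:20)),
                         stages = list(E = 1))
  expect_lt(abs(ka0$z_t1), 3)
})

test_that("kinase scores are invariant to a global location shift", {
  set.seed(9)
  lfc <- matrix(rnorm(300 * 9), 300, 9,
                dimnames = list(paste0("s", 1:300), paste0("t", 1:9)))
  map <- data.frame(kinase = "K1", site = paste0("s", 1:10))
  a <- kinase_activity(lfc, map)
  b <- kinase_activity(lfc + 5, map)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("stage sums follow the ternary EMT binning", {
  lfc <- matrix(0, 40, 9, dimnames = list(paste0("s", 1:40), paste0("t", 1:9)))
  set.seed(11)
  lfc[] <- rnorm(length(lfc), sd = 0.1)
  lfc[1:5, 3] <- lfc[1:5, 3] + 5               # activity only at t3
  map <- data.frame(kinase = "K1", site = paste0("s", 1:5))
  ka <- kinase_activity(lfc, map)
  # t3 belongs to the E/M bin (days 2-4); its |z| dominates that sum
  expect_equal(ka$stage_EM, sum(abs(unlist(ka[paste0("z_t", 3:5)]))))
  expect_gt(ka$stage_EM, ka$stage_E)
  expect_gt(ka$stage_EM, ka$stage_M)
  # substrate-count floor
  expect_error(kinase_activity(lfc, map[1:2, ], m_min = 3),
               "minimum substrate")
  expect_error(kinase_activity(matrix(1, 3, 2,
                                      dimnames = list(letters[1:3], c("t1", "t2"))),
                               map), "zero background SD")
})

test_that("classify_genes + planted truth round-trips at zero noise", {
  cfg <- sim_config(noise_sd = 0, missing_fraction = 0, batch_sd = 0)
  sim <- simulate_multiomics(cfg, seed = 13)
  lfcs <- sim$truth$planted_lfc[sim$truth$proteomic_layers]
  cl <- classify_genes(lfcs)
  truth <- sim$truth$class_label
  shared <- intersect(cl$gene, names(truth))
  expect_gt(length(shared), 10)
  expect_equal(cl$class[match(shared, cl$gene)], unname(truth[shared]))
})
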