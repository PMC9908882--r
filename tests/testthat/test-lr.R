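lfc_mat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  m
}

test_that("combined log2FC thresholding finds regulated pairs", {
  sec <- make_de(c(L1 = 0.001, L2 = 0.001),
                 lfc_mat(L1 = c(0, 0, 0, 0.6, 0), L2 = c(0, 0, 0, 0.6, 0)))
  mem <- make_de(c(R1 = 0.001, R2 = 0.001),
                 lfc_mat(R1 = c(0, 0, 0, 0.5, 0), R2 = c(0, 0, 0, 0.3, 0)))
  db <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  out <- find_regulated_lr(sec, mem_de = mem, lr_db = db)
  expect_equal(out$ligand, "L1")               # C = 1.1 at t4
  expect_equal(out$C, 1.1)
  expect_equal(out$direction, "up")
  expect_equal(out$timepoint, "t4")            # L2/R2: C = 0.9 < 1, dropped
  # direction down for negative combined change
  sec2 <- make_de(c(L1 = 0.001), lfc_mat(L1 = c(-0.7, 0, 0, 0, 0)))
  mem2 <- make_de(c(R1 = 0.001), lfc_mat(R1 = c(-0.7, 0, 0, 0, 0)))
  dn <- find_regulated_lr(sec2, mem_de = mem2,
                          lr_db = data.frame(ligand = "L1", receptor = "R1"))
  expect_equal(dn$direction, "down")
})

test_that("confidence filter and receptor-layer tie-break", {
  sec <- make_de(c(L1 = 0.001), lfc_mat(L1 = c(1, 0, 0)))
  memp <- make_de(c(R1 = 0.005), lfc_mat(R1 = c(2, 0, 0)))
  glyp <- make_de(c(R1 = 0.002), lfc_mat(R1 = c(5, 0, 0)))
  db <- data.frame(ligand = "L1", receptor = "R1")
  both <- find_regulated_lr(sec, mem_de = memp, glyco_de = glyp, lr_db = db)
  expect_equal(both$receptor_layer, "GLYCO")   # smaller p wins
  expect_equal(both$R_lfc, 5)
  # not confidently measured: skipped and counted
  weak <- make_de(c(R1 = 0.5), lfc_mat(R1 = c(9, 0, 0)))
  none <- find_regulated_lr(sec, mem_de = weak, lr_db = db)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_skipped"), 1L)
})

test_that("output is invariant to db row order and monotone in c_min", {
  set.seed(14)
  genesL <- paste0("L", 1:6); genesR <- paste0("R", 1:6)
  lfcL <- matrix(rnorm(6 * 9), 6, 9, dimnames = list(genesL, paste0("t", 1:9)))
  lfcR <- matrix(rnorm(6 * 9), 6, 9, dimnames = list(genesR, paste0("t", 1:9)))
  sec <- make_de(setNames(rep(0.001, 6), genesL), lfcL)
  mem <- make_de(setNames(rep(0.001, 6), genesR), lfcR)
  db <- data.frame(ligand = genesL, receptor = genesR)
  a <- find_regulated_lr(sec, mem_de = mem, lr_db = db, c_min = 1)
  b <- find_regulated_lr(sec, mem_de = mem, lr_db = db[sample(6), ], c_min = 1)
  expect_equal(a, b, ignore_attr = TRUE)
  loose <- find_regulated_lr(sec, mem_de = mem, lr_db = db, c_min = 0.5)
  key <- function(d) paste(d$ligand, d$timepoint)
  expect_true(all(key(a) %in% key(loose)))
  # codirectionality flag restricts to sign-matching L and R
  cd <- find_regulated_lr(sec, mem_de = mem, lr_db = db, codirectional = TRUE)
  expect_true(all(sign(cd$L_lfc) == sign(cd$R_lfc)))
})

test_that("cluster crosstalk score is the product of sender/receiver means", {
  cl <- matrix(0, 2, 3, dimnames = list(c("Lg", "Rc"), c("c1", "c2", "c3")))
  cl["Lg", "c1"] <- 4; cl["Rc", "c2"] <- 3
  sc <- score_cluster_crosstalk(data.frame(ligand = "Lg", receptor = "Rc"), cl)
  expect_equal(sc$score[1], 12)
  expect_equal(sc$sender[1], "c1"); expect_equal(sc$receiver[1], "c2")
  expect_true(all(sc$score[-1] == 0))
  expect_equal(nrow(sc), 9)                    # ordered pairs incl. self-pairs
  # absent gene: skipped with count
  sc2 <- score_cluster_crosstalk(data.frame(ligand = "nope", receptor = "Rc"), cl)
  expect_equal(nrow(sc2), 0)
  expect_equal(attr(sc2, "n_skipped"), 1L)
  expect_error(score_cluster_crosstalk(data.frame(ligand = "Lg", receptor = "Rc"),
                                       cl[, 0]), "empty")
})

test_that("planted sender/receiver pair tops the crosstalk ranking", {
  cfg <- sim_config()
  sc <- simulate_cluster_expression(cfg, seed = 17)
  truth1 <- sc$truth[1, ]
  ranked <- score_cluster_crosstalk(
    data.frame(ligand = truth1$ligand, receptor = truth1$receptor), sc$clusters)
  expect_equal(ranked$sender[1], truth1$sender)
  expect_equal(ranked$receiver[1], truth1$receiver)
})

test_that("co-occurrence correlation across samples", {
  set.seed(15)
  n <- 200
  lig <- rnorm(n)
  tab <- cbind(A = lig, B = 2 * lig, C = rnorm(n), D = -lig + rnorm(n, sd = 1e-6))
  pairs <- data.frame(ligand = c("A", "A", "A"), receptor = c("B", "C", "D"))
  r <- lr_cooccurrence_pcc(tab, pairs)
  expect_equal(r$pcc[1], 1, tolerance = 1e-12)
  expect_lt(abs(r$pcc[2]), 0.2)
  expect_lt(r$pcc[3], -0.99)
  expect_error(lr_cooccurrence_pcc(tab[1:2, ], pairs), "3 samples")
})

test_that("planted regulated pairs are recovered exactly at zero noise", {
  cfg <- sim_config(noise_sd = 0, missing_fraction = 0, batch_sd = 0)
  sim <- simulate_multiomics(cfg, seed = 19)
  de <- lapply(sim$layers[c("SEC", "MEM", "GLYCO")], function(m)
    select_differential(preprocess_omics(m, impute_method = "half_minimum",
                                         quantile_normalize = FALSE)))
  out <- find_regulated_lr(de$SEC, de$MEM, de$GLYCO, sim$truth$lr_db)
  got <- unique(out[, c("ligand", "receptor")])
  expect_setequal(paste(got$ligand, got$receptor),
                  paste(sim$truth$lr_planted$ligand,
                        sim$truth$lr_planted$receptor))
})
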