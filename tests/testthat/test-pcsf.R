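test_that("edge weights are reciprocal outdegrees", {
  el <- data.frame(source = c("x", "x", "x", "x", "y"),
                   target = c("a", "b", "c", "d", "a"))
  iw <- assign_edge_weights(el)
  expect_equal(iw$weight[iw$source == "x"], rep(0.25, 4))
  expect_equal(iw$cost[iw$source == "x"], rep(0.75, 4))
  expect_equal(iw$weight[iw$source == "y"], 1)
  expect_equal(iw$cost[iw$source == "y"], 0)
  # per-source normalization on a random graph
  set.seed(20)
  rg <- random_pcsf_instance(20)$interactome
  sums <- tapply(rg$weight[!duplicated(rg[, c("source", "target")])],
                 rg$source[!duplicated(rg[, c("source", "target")])], sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # self-loops dropped, typed duplicates deduplicated
  el2 <- data.frame(source = c("a", "a", "a"), target = c("a", "b", "b"),
                    type = c("signaling", "TF->target", "TF->target"))
  iw2 <- assign_edge_weights(el2)
  expect_equal(nrow(iw2), 1)
  expect_error(assign_edge_weights(data.frame(source = c("a", NA),
                                              target = c("b", "c"))),
               "malformed")
})

test_that("cumulative prizes follow the strict-threshold union rule", {
  lfc <- matrix(0, 1, 9, dimnames = list("v", paste0("t", 1:9)))
  lfc["v", 3] <- 1.2
  p <- cumulative_prizes(list(lfc))
  expect_equal(unname(p["v", ]), c(0, 0, 1, 1, 1, 1, 1, 1, 1))
  # max |lfc| across p-sites of one protein
  site <- matrix(0, 2, 9, dimnames = list(c("P_S1", "P_S2"), paste0("t", 1:9)))
  site["P_S1", 2] <- 0.8; site["P_S2", 2] <- -1.5
  p2 <- cumulative_prizes(list(site))
  expect_equal(rownames(p2), "P")
  expect_equal(unname(p2["P", ]), c(0, 1, 1, 1, 1, 1, 1, 1, 1))
  # |lfc| exactly 1 does not qualify (strict inequality)
  lfc3 <- matrix(1, 1, 9, dimnames = list("w", paste0("t", 1:9)))
  expect_true(all(cumulative_prizes(list(lfc3)) == 0))
  # monotone by construction
  set.seed(22)
  big <- matrix(rnorm(50 * 9, sd = 1.2), 50, 9,
                dimnames = list(paste0("g", 1:50), paste0("t", 1:9)))
  ps <- cumulative_prizes(list(big))
  expect_true(all(apply(ps, 1, function(x) all(diff(x) >= 0))))
})

test_that("the three-node toy instance solves as enumerated", {
  el <- data.frame(source = c("R", "a"), target = c("a", "b"))
  inter <- assign_edge_weights(el)
  inter$cost <- c(0.5, 0.5)
  pp <- pcsf_params(beta = 10, omega = 5, D = 5, roots = "R")
  f <- solve_pcsf(inter, c(b = 1), pp, mode = "exact")
  expect_setequal(f$nodes$node, c("R", "a", "b"))
  expect_equal(f$objective, 6)
  expect_equal(f$kappa, 1)
  expect_equal(forest_objective(f, c(b = 1), pp, inter), 6)
  # beta = 5: connecting (cost 6) loses to paying the prize (5)
  f2 <- solve_pcsf(inter, c(b = 1), pcsf_params(beta = 5, omega = 5, roots = "R"),
                   mode = "exact")
  expect_equal(nrow(f2$nodes), 0)
  expect_equal(f2$objective, 5)
  # no prizes: empty forest, f = 0
  f0 <- solve_pcsf(inter, c(b = 0), pp, mode = "exact")
  expect_equal(nrow(f0$edges), 0)
  expect_equal(f0$objective, 0)
})

test_that("both roots used gives two trees and 2*omega in the objective", {
  el <- data.frame(source = c("A", "B"), target = c("p", "q"))
  inter <- assign_edge_weights(el)
  pp <- pcsf_params(beta = 10, omega = 2, roots = c("A", "B"))
  f <- solve_pcsf(inter, c(p = 1, q = 1), pp, mode = "exact")
  expect_equal(f$kappa, 2)
  expect_equal(f$objective, 2 * 2)             # costs 0 (outdeg 1), 2 trees
  expect_error(solve_pcsf(inter, c(p = 1),
                          pcsf_params(roots = "missing"), mode = "exact"),
               "absent")
})

test_that("depth bound excludes prized nodes that are too deep", {
  el <- data.frame(source = c("R", "a", "b"), target = c("a", "b", "c"))
  inter <- assign_edge_weights(el)
  pr <- c(c = 1)
  deep <- solve_pcsf(inter, pr, pcsf_params(D = 2, roots = "R", omega = 1),
                     mode = "exact")
  expect_false("c" %in% deep$nodes$node)       # c sits at depth 3
  ok <- solve_pcsf(inter, pr, pcsf_params(D = 3, roots = "R", omega = 1),
                   mode = "exact")
  expect_true("c" %in% ok$nodes$node)
  expect_true(all(ok$nodes$depth <= 3))
})

test_that("exact solver matches the independent subset-enumeration oracle", {
  for (s in 1:25) {
    inst <- random_pcsf_instance(s, max_nodes = 6L, max_edges = 8L)
    pp <- pcsf_params(roots = inst$roots[1])
    fe <- solve_pcsf(inst$interactome, inst$prizes, pp, mode = "exact")
    expect_equal(fe$objective,
                 bf_pcsf_objective(inst$interactome, inst$prizes, pp),
                 tolerance = 1e-9, label = paste("seed", s))
    expect_equal(forest_objective(fe, inst$prizes, pp, inst$interactome),
                 fe$objective, tolerance = 1e-9)
  }
})

test_that("hub penalty mu enters the objective and the oracle agrees", {
  for (s in 1:10) {
    inst <- random_pcsf_instance(s + 200, max_nodes = 6L, max_edges = 8L)
    pp <- pcsf_params(mu = 0.5, roots = inst$roots[1])
    fe <- solve_pcsf(inst$interactome, inst$prizes, pp, mode = "exact")
    expect_equal(fe$objective,
                 bf_pcsf_objective(inst$interactome, inst$prizes, pp),
                 tolerance = 1e-9, label = paste("mu seed", s))
  }
})

test_that("forest_objective rejects invalid certificates", {
  el <- data.frame(source = c("R", "a"), target = c("a", "b"))
  inter <- assign_edge_weights(el)
  pp <- pcsf_params(roots = "R")
  f <- solve_pcsf(inter, c(b = 1), pp, mode = "exact")
  broken <- f; broken$edges <- f$edges[-1, , drop = FALSE]
  expect_error(forest_objective(broken, c(b = 1), pp, inter), "forest")
  deep <- f; deep$params$D <- 5
  pp0 <- pp; pp0$D <- 0
  expect_error(forest_objective(f, c(b = 1), pp0, inter), "depth")
})

test_that("temporal series grows monotonically with cumulative prizes", {
  cfg <- sim_config(network_config = list(n_nodes = 12L, n_edges = 16L,
                                          cascade_length = 4L,
                                          root_names = c("TGFBR1", "TGFBR2")))
  si <- simulate_interactome(cfg, seed = 23)
  inter <- assign_edge_weights(si$interactome)
  pr <- cumulative_prizes(list(si$truth$lfc))
  ser <- run_temporal_series(inter, pr, pcsf_params(), mode = "exact")
  sizes <- vapply(ser$forests, function(f) nrow(f$nodes), 1L)
  expect_true(all(diff(sizes) >= 0))
  expect_true(all(ser$first_appearance >= 1))
  # prizes only late: early forests empty
  late <- matrix(0, 1, 9, dimnames = list("K01", paste0("t", 1:9)))
  late["K01", 9] <- 2
  ser2 <- run_temporal_series(inter, cumulative_prizes(list(late)),
                              pcsf_params(), mode = "exact")
  expect_true(all(vapply(ser2$forests[1:8], function(f) nrow(f$nodes), 1L) == 0))
  expect_gt(nrow(ser2$forests[["t9"]]$nodes), 0)
})

test_that("causal edge merge recomputes weights on the union", {
  el <- data.frame(source = c("x", "x"), target = c("a", "b"))
  inter <- assign_edge_weights(el)
  expect_equal(inter$weight, c(0.5, 0.5))
  # empty merge: unchanged weights
  same <- merge_causal_edges(inter, NULL)
  expect_equal(same$weight, inter$weight)
  # appending one more edge out of x lowers all of x's weights
  merged <- merge_causal_edges(inter, data.frame(source = "x", target = "c",
                                                 sign = 1L))
  expect_equal(merged$weight[merged$source == "x"], rep(1 / 3, 3))
  # opposite-sign duplicate: both kept and flagged
  confl <- merge_causal_edges(assign_edge_weights(
    data.frame(source = "x", target = "a", type = "signaling", sign = 1L)),
    data.frame(source = "x", target = "a", type = "signaling", sign = -1L))
  expect_equal(nrow(confl), 2)
  expect_false(is.null(attr(confl, "sign_conflicts")))
})
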