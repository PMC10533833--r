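test_that("independent nodes give a near-empty network", {
  false_edges <- 0; total <- 0
  for (s in 1:5) {
    set.seed(40 + s)
    x <- matrix(rnorm(2000 * 10), 2000, 10)
    colnames(x) <- paste0("g", 1:10)
    net <- estimate_mgm(x, gauss_roster(10))
    false_edges <- false_edges + sum(net$weights[upper.tri(net$weights)] != 0)
    total <- total + 45
  }
  expect_lt(false_edges / total, 0.05)
})

test_that("planted gaussian partial correlations are recovered", {
  p <- 3
  w <- weights_from_edges(p, rbind(c(1, 2, 0.4), c(2, 3, 0.4)))
  truth <- true_network(gauss_roster(p), w)
  absent_zero <- 0
  for (s in 1:5) {
    x <- gauss_wave(truth, 5000, seed = 50 + s)
    net <- estimate_mgm(x, truth$roster)
    expect_lt(max(abs(net$weights - oracle_pcor(truth))), 0.05)
    absent_zero <- absent_zero + (net$weights[1, 3] == 0)
  }
  expect_gte(absent_zero / 5, 0.8)
})

test_that("binary node with planted logistic dependence is detected", {
  r <- node_roster(c("b1", "g1", "g2", "g3"),
                   c("binary", rep("gaussian", 3)))
  for (s in 1:5) {
    set.seed(60 + s)
    n <- 2000
    g <- matrix(rnorm(n * 3), n, 3)
    b <- rbinom(n, 1, plogis(-0.5 + 1.0 * g[, 1]))
    x <- cbind(b1 = b, g1 = g[, 1], g2 = g[, 2], g3 = g[, 3])
    net <- estimate_mgm(x, r)
    expect_gt(net$weights["b1", "g1"], 0)
  }
})

test_that("AND-rule network is a subgraph of the OR-rule network", {
  nets <- default_true_networks()
  pan <- sample_panel(nets[1], 300, 1, burn_in = 50, seed = 77)
  x <- as.matrix(pan[, nets[[1]]$roster$code])
  a <- estimate_mgm(x, nets[[1]]$roster, rule = "AND")
  o <- estimate_mgm(x, nets[[1]]$roster, rule = "OR")
  expect_true(all(o$weights[a$weights != 0] != 0))
})

test_that("estimate is invariant to permuting input rows", {
  truth <- chain_truth(5, 0.3)
  x <- gauss_wave(truth, 800, seed = 12)
  set.seed(1)
  net1 <- estimate_mgm(x, truth$roster)
  net2 <- estimate_mgm(x[sample(nrow(x)), ], truth$roster)
  expect_equal(net1$weights, net2$weights, tolerance = 1e-8)
})

test_that("constant columns and small n are flagged", {
  x <- cbind(g1 = rnorm(100), g2 = rep(2, 100), g3 = rnorm(100))
  expect_error(estimate_mgm(x, gauss_roster(3)), "g2")
  truth <- chain_truth(3)
  xs <- gauss_wave(truth, 40, seed = 2)
  expect_warning(estimate_mgm(xs, truth$roster), "< 50")
})

test_that("glasso returns an empty network for independent data", {
  set.seed(14)
  x <- matrix(rnorm(2000 * 6), 2000, 6)
  colnames(x) <- paste0("g", 1:6)
  g <- estimate_ebic_glasso(x)
  expect_lt(max(abs(coef(g)[upper.tri(coef(g))])), 0.01)
  # full-shrinkage limit is exactly empty
  g2 <- estimate_ebic_glasso(x, lambdas = 10)
  expect_true(all(coef(g2)[upper.tri(coef(g2))] == 0))
})

test_that("glasso recovers a chain graph", {
  truth <- chain_truth(5, 0.3)
  orc <- oracle_pcor(truth)
  for (s in 1:3) {
    x <- gauss_wave(truth, 5000, seed = 80 + s)
    g <- estimate_ebic_glasso(x)
    w <- coef(g)
    on_chain <- abs(w[cbind(1:4, 2:5)] - orc[cbind(1:4, 2:5)])
    expect_lt(max(on_chain), 0.05)
    off <- w; off[cbind(1:4, 2:5)] <- 0; off[cbind(2:5, 1:4)] <- 0
    expect_lt(max(abs(off)), 0.05)
  }
})

test_that("nodewise and glasso estimates agree in sign on strong edges", {
  truth <- chain_truth(6, 0.3)
  x <- gauss_wave(truth, 5000, seed = 91)
  m <- estimate_mgm(x, truth$roster)
  g <- estimate_ebic_glasso(x)
  strong <- abs(oracle_pcor(truth)) >= 0.2
  expect_true(all(sign(m$weights[strong]) == sign(coef(g)[strong])))
})

test_that("display threshold is boundary-inclusive and non-destructive", {
  w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  w["a", "b"] <- w["b", "a"] <- 0.14
  w["a", "c"] <- w["c", "a"] <- 0.15
  w["b", "c"] <- w["c", "b"] <- 0.34
  shown <- threshold_for_display(w, 0.15)
  expect_setequal(shown$weight, c(0.15, 0.34))
  expect_equal(nrow(threshold_for_display(w, 0)), 3)
})
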