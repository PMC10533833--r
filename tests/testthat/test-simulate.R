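test_that("empty network yields independent nodes", {
  truth <- true_network(gauss_roster(3), matrix(0, 3, 3))
  x <- gauss_wave(truth, 5000, seed = 7, burn_in = 50)
  r <- cor(x)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("chain weights reproduce the oracle partial correlations", {
  truth <- chain_truth(3, 0.3)
  x <- gauss_wave(truth, 5000, seed = 8)
  emp <- -cov2cor(solve(cov(x)))
  diag(emp) <- 0
  expect_lt(max(abs(emp - oracle_pcor(truth))), 0.03)
})

test_that("binary marginal matches logistic(threshold)", {
  r <- node_roster(c("b1", "g1", "g2"), c("binary", "gaussian", "gaussian"))
  truth <- true_network(r, matrix(0, 3, 3),
                        thresholds = c(b1 = -0.5, g1 = 0, g2 = 0))
  pan <- sample_panel(list(truth), 10000, 1, within_person_sd = 0,
                      burn_in = 30, seed = 3)
  target <- plogis(-0.5)
  se <- sqrt(target * (1 - target) / 10000)
  expect_lt(abs(mean(pan$b1) - target), 3 * se)
})

test_that("planted dependence is symmetric between regression directions", {
  truth <- chain_truth(2 + 1, 0.35)  # g1-g2, g2-g3
  x <- gauss_wave(truth, 2000, seed = 5)
  b12 <- coef(lm(x[, 2] ~ x[, 1] + x[, 3]))[2]
  b21 <- coef(lm(x[, 1] ~ x[, 2] + x[, 3]))[2]
  expect_gt(b12, 0)
  expect_gt(b21, 0)
})

test_that("visit counts follow the requested distribution", {
  truth <- list(chain_truth(3), chain_truth(3), chain_truth(3),
                chain_truth(3))
  vd <- c(54, 130, 189, 259) / 632
  pan <- sample_panel(truth, 632, vd, within_person_sd = 0, burn_in = 5,
                      seed = 9)
  counts <- table(factor(table(pan$participant_id), levels = 1:4))
  # multinomial sampling check plus the expected total row count (1917)
  expect_gt(suppressWarnings(
    chisq.test(counts, p = vd)$p.value), 1e-4)
  expect_lt(abs(nrow(pan) - 1917), 80)
  expect_false(any(duplicated(pan[, c("participant_id", "wave")])))
})

test_that("participant intercepts create cross-wave correlation", {
  truth <- list(chain_truth(3), chain_truth(3))
  icc_of <- function(sdv) {
    pan <- sample_panel(truth, 800, c(0, 1), within_person_sd = sdv,
                        burn_in = 30, seed = 21)
    wide <- merge(pan[pan$wave == 1, c("participant_id", "g1")],
                  pan[pan$wave == 2, c("participant_id", "g1")],
                  by = "participant_id")
    cor(wide[[2]], wide[[3]])
  }
  expect_gt(icc_of(0.8), 0.2)
  expect_lt(abs(icc_of(0)), 0.1)
})

test_that("belief values are truncated to their scale range", {
  r <- node_roster("lik1", "gaussian", 1, 7)
  truth <- true_network(r, matrix(0, 1, 1), thresholds = c(lik1 = 6.5))
  pan <- sample_panel(list(truth), 500, 1, within_person_sd = 0,
                      burn_in = 10, seed = 2)
  expect_true(all(pan$lik1 >= 1 & pan$lik1 <= 7))
  expect_gt(mean(pan$lik1 == 7), 0.1)  # upper truncation actually binds
})

test_that("plant_edge_change edits only the requested waves", {
  nets <- list(chain_truth(4), chain_truth(4))
  same <- plant_edge_change(nets, c("g1", "g3"), 0, waves = 1:2)
  expect_equal(same[[1]]$weights, nets[[1]]$weights)
  mod <- plant_edge_change(nets, c("g1", "g3"), 0.4, waves = 2)
  expect_equal(mod[[1]]$weights["g1", "g3"], 0)
  expect_equal(mod[[2]]$weights["g1", "g3"], 0.4)
  expect_equal(mod[[2]]$weights["g3", "g1"], 0.4)
  expect_error(plant_edge_change(nets, c("g1", "g1"), 0.1, 1), "self-loop")
})

test_that("generator rejects invalid inputs", {
  r <- gauss_roster(3)
  w <- matrix(0, 3, 3); w[1, 2] <- 0.3  # asymmetric
  expect_error(true_network(r, w), "symmetric")
  truth <- chain_truth(3)
  expect_error(sample_panel(list(truth), 10, 1, burn_in = 0), "burn_in")
  expect_error(sample_panel(list(truth), 10, c(0.5, 0.4)),
               "one probability per wave|sum to 1")
})

test_that("panel and true-network files round-trip", {
  nets <- default_true_networks()
  pan <- sample_panel(nets, 60, burn_in = 20, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_panel(pan, f)
  pan2 <- read_panel(f)
  expect_equal(as.data.frame(pan2), as.data.frame(pan), tolerance = 1e-12)
  fe <- tempfile(fileext = ".csv"); fm <- tempfile(fileext = ".json")
  write_true_network(nets[[2]], fe, fm)
  back <- read_true_network(fe, fm, nets[[2]]$roster)
  expect_equal(back$weights, nets[[2]]$weights)
  expect_equal(back$thresholds, nets[[2]]$thresholds)
  expect_equal(back$wave, 2L)
})
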