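test_that("identical groups give zero statistics and p = 1", {
  truth <- chain_truth(5, 0.3)
  x <- gauss_wave(truth, 300, seed = 15)
  res <- nct(x, x, permutations = 200, seed = 3)
  expect_equal(res$gs_statistic, 0)
  expect_equal(res$m_statistic, 0)
  expect_equal(res$gs_p, 1)
  expect_equal(res$structure_p, 1)
  expect_true(all(res$edges$p > 0 & res$edges$p <= 1))
})

test_that("the test is symmetric in group labels and seed-reproducible", {
  truth <- chain_truth(5, 0.3)
  xa <- gauss_wave(truth, 260, seed = 16)
  xb <- gauss_wave(plant_edge_change(list(truth), c("g1", "g4"), 0.35,
                                     1)[[1]], 300, seed = 17)
  r1 <- nct(xa, xb, permutations = 200, seed = 7)
  r2 <- nct(xb, xa, permutations = 200, seed = 7)
  expect_equal(r1$gs_statistic, r2$gs_statistic)
  expect_equal(r1$m_statistic, r2$m_statistic)
  expect_equal(r1$gs_p, r2$gs_p)
  expect_equal(r1$structure_p, r2$structure_p)
  expect_equal(r1$global_strength_a, r2$global_strength_b)
  d1 <- r1$edges; d2 <- r2$edges
  expect_equal(d1$p, d2$p)
  expect_equal(d1$diff, -d2$diff)
  r3 <- nct(xa, xb, permutations = 200, seed = 7)
  expect_identical(r1, r3)          # bit-reproducible under a fixed seed
  # +1 continuity: p can never be 0
  expect_true(all(c(r1$gs_p, r1$structure_p, r1$edges$p) >= 1 / 201))
})

test_that("a planted edge change is detected and localized", {
  truth <- chain_truth(6, 0.3)
  changed <- plant_edge_change(list(truth), c("g2", "g5"), 0.4, 1)[[1]]
  rejections <- 0; localized <- 0
  for (s in 1:8) {
    xa <- gauss_wave(truth, 500, seed = 600 + s)
    xb <- gauss_wave(changed, 500, seed = 700 + s)
    res <- nct(xa, xb, permutations = 200, seed = s)
    rejections <- rejections + (res$structure_p < 0.05)
    top <- res$edges[which.min(res$edges$p_holm), ]
    localized <- localized +
      (top$node_i == "g2" && top$node_j == "g5")
  }
  expect_gte(rejections, 5)          # majority of replicates reject
  expect_gte(localized, 5)           # planted edge carries the signal
  # annotated hybrid report points in the planted direction
  xa <- gauss_wave(truth, 500, seed = 991)
  xb <- gauss_wave(changed, 500, seed = 992)
  res <- nct(xa, xb, permutations = 200, seed = 11)
  ma <- estimate_mgm(xa, truth$roster)
  mb <- estimate_mgm(xb, truth$roster)
  rep <- hybrid_difference_report(res, ma, mb)
  if (nrow(rep$all)) {
    planted <- rep$all[rep$all$node_i == "g2" & rep$all$node_j == "g5", ]
    if (nrow(planted)) expect_gt(planted$mgm_diff, 0)
  }
})

test_that("hybrid report separates machine output from the display list", {
  fake <- structure(list(edges = data.frame(
    node_i = c("g1", "g1", "g2"), node_j = c("g2", "g3", "g3"),
    diff = c(0.3, 0.1, 0.0), p = c(0.001, 0.002, 0.8),
    p_holm = c(0.003, 0.006, 0.8))), class = "nct_result")
  w <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  wa <- w; wb <- w
  wb["g1", "g2"] <- wb["g2", "g1"] <- 0.4    # big difference
  wb["g1", "g3"] <- wb["g3", "g1"] <- 0.1    # sub-threshold difference
  out <- expect_silent(hybrid_difference_report(fake, wa, wb))
  expect_equal(nrow(out$all), 2)
  expect_equal(nrow(out$display), 1)
  expect_equal(out$display$node_j, "g2")
  expect_equal(out$all$mgm_diff[out$all$node_j == "g3"], 0.1)
  # significant edge absent from both mixed networks is flagged
  fake2 <- fake
  fake2$edges$p_holm <- c(0.003, 0.5, 0.5)
  expect_warning(out2 <- hybrid_difference_report(fake2, wa, wa),
                 "absent")
  expect_true(out2$all$absent_in_both)
  # no significant edges -> empty display list
  fake3 <- fake
  fake3$edges$p_holm <- rep(0.9, 3)
  out3 <- hybrid_difference_report(fake3, wa, wb)
  expect_equal(nrow(out3$display), 0)
})

test_that("the pairwise schedule mirrors a planted wave-1 to wave-2 shift", {
  base <- chain_truth(6, 0.3)
  nets <- list(base, base, base, base)
  nets <- plant_edge_change(nets, c("g1", "g4"), 0.45, waves = 2:4)
  pan <- sample_panel(nets, 1400, rep(0.25, 4), within_person_sd = 0,
                      burn_in = 80, seed = 33)
  res <- nct_pairwise_schedule(pan, permutations = 200, seed = 19)
  expect_named(res, c("T1-T4", "T1-T2", "T2-T3", "T3-T4"))
  expect_lt(res[["T1-T2"]]$structure_p, 0.05)
  expect_lt(res[["T1-T4"]]$structure_p, 0.05)
  expect_gt(res[["T2-T3"]]$structure_p, 0.05)
  expect_gt(res[["T3-T4"]]$structure_p, 0.05)
  pan3 <- pan[pan$wave != 2, ]
  attr(pan3, "roster") <- attr(pan, "roster")
  expect_error(nct_pairwise_schedule(pan3, permutations = 200),
               "missing wave: 2")
})

test_that("overlapping participant ids raise a warning", {
  truth <- chain_truth(4, 0.3)
  x <- gauss_wave(truth, 200, seed = 44)
  expect_warning(
    nct(x, x[1:150, ], permutations = 200, seed = 1,
        id_a = 1:200, id_b = 1:150),
    "share participant ids")
})
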