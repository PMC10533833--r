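test_that("strength sums absolute incident weights", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.5
  s <- strength(w)
  expect_equal(s$strength[s$node == "A"], 0.5)
  expect_equal(s$strength[s$node == "C"], 0)
  w["B", "C"] <- w["C", "B"] <- -0.3
  s2 <- strength(w)
  expect_equal(s2$strength[s2$node == "B"], 0.8)
  expect_equal(global_strength(w), 0.8)
})

test_that("handshake identity holds exactly on random networks", {
  set.seed(101)
  for (i in 1:100) {
    w <- random_network(sample(4:12, 1))
    expect_lt(abs(sum(strength(w)$strength) - 2 * global_strength(w)),
              1e-12)
  }
})

test_that("average shortest path length follows 1/|w| distances", {
  two <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  two["A", "B"] <- two["B", "A"] <- 0.5
  expect_equal(average_shortest_path_length(two)$aspl, 2)
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  expect_equal(average_shortest_path_length(tri)$aspl, 1)
  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- 0.5
  path["b", "c"] <- path["c", "b"] <- 0.5
  # oracle by hand Dijkstra: d(a,b) = d(b,c) = 2, d(a,c) = 4
  expect_equal(average_shortest_path_length(path)$aspl, (2 + 2 + 4) / 3)
  expect_error(average_shortest_path_length(path * 0), "no edges")
  disc <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  disc["a", "b"] <- disc["b", "a"] <- 1
  disc["c", "d"] <- disc["d", "c"] <- 1
  out <- average_shortest_path_length(disc)
  expect_equal(out$n_disconnected_pairs, 8)
})

test_that("walktrap never merges disjoint components", {
  w <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  w[1:3, 1:3] <- 0.4; w[4:6, 4:6] <- 0.4
  diag(w) <- 0
  memb <- panelnet:::walktrap_membership(w)
  expect_equal(length(unique(memb[1:3])), 1)
  expect_equal(length(unique(memb[4:6])), 1)
  expect_false(memb[1] == memb[4])
})

two_clique_truth <- function() {
  p <- 8
  edges <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)))
  # 0.25 keeps the gaussian block of I - W positive definite
  true_network(gauss_roster(p),
               weights_from_edges(p, cbind(edges, 0.25)))
}

test_that("planted cliques are recovered as consensus communities", {
  truth <- two_clique_truth()
  x <- gauss_wave(truth, 2000, seed = 71)
  cc <- consensus_communities(x, truth$roster, iterations = 100, seed = 2)
  cl <- cc$consensus_clusters
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])
  expect_gt(min(cc$co_membership[1:4, 1:4]), 0.9)
  expect_lt(max(cc$co_membership[1:4, 5:8]), 0.1)
  expect_true(all(diag(cc$co_membership) == 1))
})

test_that("consensus communities are invariant to node relabeling", {
  truth <- two_clique_truth()
  x <- gauss_wave(truth, 2000, seed = 72)
  perm <- c(3, 7, 1, 5, 8, 2, 6, 4)
  roster_p <- truth$roster[perm, ]
  cc1 <- consensus_communities(x, truth$roster, iterations = 100, seed = 4)
  cc2 <- consensus_communities(x[, perm], roster_p, iterations = 100,
                               seed = 4)
  co2_back <- cc2$co_membership[truth$roster$code, truth$roster$code]
  expect_equal(co2_back, cc1$co_membership, tolerance = 0.1)
  same1 <- outer(cc1$consensus_clusters, cc1$consensus_clusters, "==")
  cl2 <- cc2$consensus_clusters[truth$roster$code]
  same2 <- outer(cl2, cl2, "==")
  expect_equal(same1, same2)
})

test_that("noise data collapses to singletons at a strict threshold", {
  set.seed(5)
  x <- matrix(rnorm(200 * 6), 200, 6)
  colnames(x) <- paste0("g", 1:6)
  cc <- consensus_communities(x, gauss_roster(6), iterations = 100,
                              seed = 3)
  expect_gte(sum(table(cc$consensus_clusters) == 1), 4)
})

test_that("community preconditions are enforced", {
  x <- matrix(rnorm(100 * 3), 100, 3)
  colnames(x) <- paste0("g", 1:3)
  expect_error(consensus_communities(x, gauss_roster(3), iterations = 50),
               ">= 100")
  expect_error(consensus_communities(x, gauss_roster(3), threshold = 0.4),
               "threshold")
})
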