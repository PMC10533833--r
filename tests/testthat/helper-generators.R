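# Shared fixture builders: small gaussian rosters, planted networks, and a
# marginal-logistic panel generator for the GEE suite.

gauss_roster <- function(p, prefix = "g") {
  node_roster(paste0(prefix, seq_len(p)), "gaussian")
}

# Symmetric weight matrix from an edge list (i, j, w).
weights_from_edges <- function(p, edges) {
  w <- matrix(0, p, p)
  for (k in seq_len(nrow(edges))) {
    w[edges[k, 1], edges[k, 2]] <- edges[k, 3]
    w[edges[k, 2], edges[k, 1]] <- edges[k, 3]
  }
  w
}

chain_truth <- function(p, w = 0.3) {
  idx <- cbind(seq_len(p - 1), 2:p, w)
  true_network(gauss_roster(p), weights_from_edges(p, idx))
}

# One-wave gaussian sample from a planted truth, as a plain matrix.
gauss_wave <- function(truth, n, seed, burn_in = 100) {
  pan <- sample_panel(list(truth), n, 1, within_person_sd = 0,
                      burn_in = burn_in, seed = seed)
  as.matrix(pan[, truth$roster$code, drop = FALSE])
}

# Panel of repeated binary outcomes with an exact marginal logistic trend
# (Gaussian copula with exchangeable latent correlation), so the GEE
# estimand equals the generating log-odds increment.
marginal_logistic_panel <- function(n, beta0, beta1, rho, seed,
                                    n_waves = 4) {
  set.seed(seed)
  R <- matrix(rho, n_waves, n_waves); diag(R) <- 1
  z <- matrix(rnorm(n * n_waves), n) %*% chol(R)
  pmat <- plogis(beta0 + beta1 *
                   matrix(seq_len(n_waves), n, n_waves, byrow = TRUE))
  y <- (pnorm(z) < pmat) * 1
  data.frame(participant_id = rep(seq_len(n), each = n_waves),
             wave = rep(seq_len(n_waves), n), y = as.vector(t(y)))
}

# Random sparse symmetric weight matrix for identity checks.
random_network <- function(p, density = 0.3) {
  w <- matrix(0, p, p)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < density, runif(sum(ut), -0.5, 0.5), 0)
  w[ut] <- vals
  w <- w + t(w)
  dimnames(w) <- list(paste0("n", 1:p), paste0("n", 1:p))
  w
}
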