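# Study-condition defaults and the Gibbs panel generator.

# Wave-linear target marginal means for the gaussian belief nodes
# (endpoints follow the cohort's descriptive tables; age standardized).
default_gaussian_targets <- function() {
  ends <- rbind(
    age = c(0, 0), riskHIV = c(1.9, 1.7),
    prep1 = c(4.6, 4.8), prep2 = c(4.6, 4.8), prep3 = c(4.3, 4.5),
    prep4 = c(4.8, 5.3), prep5 = c(5.4, 5.9), prep6 = c(3.4, 3.4),
    prep7 = c(2.9, 4.1), prep8 = c(4.1, 4.3), prep9 = c(4.1, 4.4),
    prep10 = c(4.1, 4.2), prep11 = c(2.9, 2.5), prep12 = c(4.5, 4.7),
    prep13 = c(3.1, 3.9), prep14 = c(4.8, 5.1), prep15 = c(3.5, 4.6),
    prep16 = c(5.5, 5.3), prep17 = c(4.5, 4.3), prep18 = c(4.0, 4.4),
    prep19 = c(4.4, 4.8), prep20 = c(4.4, 4.9), prep21 = c(4.3, 4.7),
    vls1 = c(4.6, 5.0), vls2 = c(4.8, 4.9), vls3 = c(3.9, 4.0),
    vls4 = c(3.5, 3.4), vls5 = c(3.8, 3.7), vls6 = c(3.2, 3.2),
    vls7 = c(2.7, 2.8), vls8 = c(2.9, 3.2), vls9 = c(3.7, 3.5))
  colnames(ends) <- c("t1", "t4")
  ends
}

# Binary marginal targets per wave (PrEP rising, VLS flat, steady partner flat).
default_binary_targets <- function() {
  rbind(PrEP = c(0.10, 0.22, 0.25, 0.31),
        VLS = c(0.07, 0.09, 0.08, 0.09),
        sp = c(0.65, 0.65, 0.65, 0.65))
}

# Constant belief-belief backbone edges (code_i, code_j, weight).
default_backbone_edges <- function() {
  e <- rbind(
    c("prep1", "prep17", 0.25), c("prep2", "prep3", 0.30),
    c("prep4", "prep5", 0.30), c("prep4", "prep6", -0.20),
    c("prep7", "prep10", 0.20), c("prep8", "prep9", 0.30),
    c("prep9", "prep10", 0.25), c("prep1", "prep11", -0.25),
    c("prep12", "prep14", 0.30), c("prep13", "prep14", 0.25),
    c("prep15", "prep18", 0.30), c("prep15", "prep16", 0.25),
    c("prep17", "prep18", 0.20), c("prep19", "prep20", 0.20),
    c("prep20", "prep21", 0.35), c("prep5", "riskHIV", 0.15),
    c("vls1", "vls2", 0.30), c("vls2", "vls3", 0.30),
    c("vls3", "vls4", 0.20), c("vls4", "vls5", 0.25),
    c("vls6", "vls8", 0.30), c("vls7", "vls8", 0.25),
    c("vls9", "vls3", 0.25), c("vls9", "vls4", 0.20),
    c("vls5", "vls9", 0.20), c("prep19", "vls4", 0.15),
    c("prep4", "vls3", 0.15), c("prep13", "vls7", 0.20),
    c("prep14", "vls8", 0.20), c("sp", "age", 0.10),
    c("sp", "VLS", 0.10))
  data.frame(i = e[, 1], j = e[, 2], w = as.numeric(e[, 3]),
             stringsAsFactors = FALSE)
}

# Wave-specific uptake-related edges mirroring the reported direct
# correlates of PrEP and VLS use (weights per wave T1..T4).
default_uptake_edges <- function() {
  e <- list(
    list("PrEP", "prep13", c(0.34, 0.18, 0.30, 0.27)),
    list("PrEP", "prep9",  c(0.48, 0.20, 0.12, 0.34)),
    list("PrEP", "prep1",  c(0.14, 0.32, 0.21, 0.00)),
    list("PrEP", "prep11", c(0.26, 0.00, 0.27, 0.07)),
    list("PrEP", "age",    c(0.26, 0.14, 0.20, 0.00)),
    list("PrEP", "VLS",    c(0.09, 0.09, 0.38, 0.38)),
    list("PrEP", "prep8",  c(0.00, 0.00, 0.00, 0.12)),
    list("PrEP", "prep10", c(0.00, 0.00, 0.00, 0.34)),
    list("PrEP", "sp",     c(0.00, 0.00, 0.00, -0.18)),
    list("PrEP", "prep7",  c(0.11, 0.11, 0.00, 0.00)),
    list("PrEP", "prep4",  c(0.08, 0.16, 0.00, 0.00)),
    list("VLS", "vls5",    c(0.00, 0.00, 0.11, 0.24)),
    list("VLS", "vls8",    c(0.25, 0.23, 0.00, 0.00)),
    list("VLS", "prep8",   c(0.00, 0.00, 0.00, -0.11)),
    list("VLS", "prep15",  c(0.00, 0.00, 0.00, 0.21)),
    list("VLS", "prep14",  c(0.00, 0.00, 0.00, -0.13)),
    list("VLS", "vls3",    c(0.00, 0.00, 0.00, 0.14)),
    list("VLS", "age",     c(0.00, 0.00, 0.00, 0.14)),
    # belief-side change: affordability and efficacy concerns co-occur
    # only at the first wave, so the continuous networks also shift
    # between waves 1 and 2 (and hence 1 vs 4) but not later
    list("prep4", "prep7", c(0.35, 0.00, 0.00, 0.00)))
  e
}

#' Default per-wave ground-truth networks of the emulated cohort
#'
#' Four pairwise MRFs over the default 35-node roster. Belief-belief
#' backbone edges are constant across waves; uptake-related edges change
#' across waves (most of the change between waves 1 and 2 and at wave 4),
#' mirroring the temporal pattern of the cohort the generator emulates.
#' Thresholds are solved by a mean-field calibration so that marginal means
#' of gaussian nodes track the descriptive targets and binary prevalences
#' track the uptake targets (PrEP rising from about 10\% to about 31\%).
#'
#' @param roster a roster; defaults to \code{\link{make_default_roster}}.
#' @param within_person_sd participant-intercept SD assumed by the
#'   prevalence calibration (match the value passed to
#'   \code{\link{sample_panel}}).
#' @return list of four \code{\link{true_network}} objects.
#' @export
default_true_networks <- function(roster = make_default_roster(),
                                  within_person_sd = 0.8) {
  p <- nrow(roster)
  targ_g <- default_gaussian_targets()
  targ_b <- default_binary_targets()
  backbone <- default_backbone_edges()
  uptake <- default_uptake_edges()
  lapply(1:4, function(wave) {
    w <- matrix(0, p, p, dimnames = list(roster$code, roster$code))
    for (k in seq_len(nrow(backbone))) {
      w[backbone$i[k], backbone$j[k]] <- backbone$w[k]
      w[backbone$j[k], backbone$i[k]] <- backbone$w[k]
    }
    for (ed in uptake) {
      w[ed[[1]], ed[[2]]] <- ed[[3]][wave]
      w[ed[[2]], ed[[1]]] <- ed[[3]][wave]
    }
    # wave-linear gaussian means between the t1 and t4 endpoints
    mu_g <- targ_g[, "t1"] + (wave - 1) / 3 * (targ_g[, "t4"] - targ_g[, "t1"])
    mu_b <- targ_b[, wave]
    mu <- setNames(numeric(p), roster$code)
    mu[names(mu_g)] <- mu_g
    mu[names(mu_b)] <- mu_b
    g <- roster$family == "gaussian"
    tau <- setNames(numeric(p), roster$code)
    # gaussian: tau_g = (I - W_gg) mu_g - W_gb mu_b
    tau[g] <- (diag(sum(g)) - w[g, g]) %*% mu[g] - w[g, !g] %*% mu[!g]
    # binary: logit(target) scaled by the logistic-normal attenuation
    # factor (the linear predictor fluctuates with neighbour values and
    # the participant intercept), minus the mean-field neighbour term
    vx <- ifelse(g, 1 + within_person_sd^2, mu * (1 - mu))
    v_lp <- drop((w[!g, , drop = FALSE]^2) %*% vx) + within_person_sd^2
    tau[!g] <- qlogis(mu[!g]) * sqrt(1 + 0.346 * v_lp) -
      w[!g, , drop = FALSE] %*% mu
    true_network(roster, w, tau, gaussian_sd = 1, wave = wave)
  })
}

#' Gibbs-sample a multi-wave mixed questionnaire panel
#'
#' Per participant, the number of attended visits is drawn from
#' \code{visit_distribution} and that many waves are chosen uniformly
#' without replacement (non-monotone attendance). Per attended wave, node
#' values are drawn by Gibbs sampling from the wave's pairwise MRF: each
#' gaussian node from a normal with mean threshold + participant intercept +
#' weighted neighbours (SD \code{gaussian_sd}), each binary node from a
#' Bernoulli with the same linear predictor on the logit scale. Participant
#' intercepts (one per participant per node, SD \code{within_person_sd}) are
#' drawn once and shared across waves, inducing within-person correlation.
#' Gaussian belief values are truncated to their scale range after sampling.
#' A condomless-anal-sex indicator \code{cas} and a condom-use indicator are
#' drawn per wave from configurable logistic models on PrEP and VLS.
#'
#' @param networks list of \code{\link{true_network}}, one per wave.
#' @param n_participants number of unique participants.
#' @param visit_distribution probabilities over 1..length(networks) visits;
#'   defaults to the emulated cohort's printed visit-count distribution.
#' @param within_person_sd SD of the participant-by-node intercepts.
#' @param burn_in Gibbs sweeps before the retained draw (must be positive).
#' @param seed integer seed; all randomness flows from it.
#' @param cas_model coefficients (intercept, PrEP, VLS) of the logistic
#'   model generating \code{cas}.
#' @param condom_model coefficients (intercept, PrEP, VLS) generating
#'   \code{condom}.
#' @return A \code{panel_data} data frame: \code{participant_id},
#'   \code{wave}, one column per roster node, \code{cas}, \code{condom};
#'   the roster is attached as attribute \code{"roster"}.
#' @export
sample_panel <- function(networks, n_participants = 632,
                         visit_distribution = c(54, 130, 189, 259) / 632,
                         within_person_sd = 0.8, burn_in = 200, seed = 1,
                         cas_model = c(-0.5, 1, 1),
                         condom_model = c(0.6, -0.8, 0)) {
  n_waves <- length(networks)
  if (length(visit_distribution) != n_waves) {
    stop("visit_distribution must have one probability per wave")
  }
  if (abs(sum(visit_distribution) - 1) > 1e-8) {
    stop("visit_distribution must sum to 1")
  }
  if (burn_in <= 0) stop("burn_in must be positive")
  roster <- networks[[1]]$roster
  for (net in networks) check_symmetric(net$weights)
  p <- nrow(roster)
  g <- roster$family == "gaussian"

  with_seed(seed, {
    n_visits <- sample.int(n_waves, n_participants, replace = TRUE,
                           prob = visit_distribution)
    attend <- matrix(FALSE, n_participants, n_waves)
    for (i in seq_len(n_participants)) {
      attend[i, sample.int(n_waves, n_visits[i])] <- TRUE
    }
    intercepts <- matrix(rnorm(n_participants * p, sd = within_person_sd),
                         n_participants, p, dimnames = list(NULL, roster$code))
    rows <- vector("list", n_waves)
    for (wave in seq_len(n_waves)) {
      net <- networks[[wave]]
      ids <- which(attend[, wave])
      m <- length(ids)
      if (m == 0L) next
      b <- intercepts[ids, , drop = FALSE]
      tau <- net$thresholds
      w <- net$weights
      # initialize at the mean-field state
      x <- matrix(0, m, p, dimnames = list(NULL, roster$code))
      x[, g] <- matrix(rep(tau[g], each = m), m) + b[, g]
      x[, !g] <- matrix(rbinom(m * sum(!g), 1,
                               plogis(rep(tau[!g], each = m))), m)
      for (sweep in seq_len(burn_in)) {
        for (j in seq_len(p)) {
          eta <- tau[j] + b[, j] + x[, -j, drop = FALSE] %*% w[j, -j]
          if (g[j]) {
            x[, j] <- rnorm(m, eta, net$gaussian_sd)
          } else {
            x[, j] <- rbinom(m, 1, plogis(eta))
          }
        }
      }
      # truncate gaussian belief values to their scale range
      for (j in which(g)) {
        lo <- roster$lower[j]; hi <- roster$upper[j]
        if (!is.na(lo)) x[, j] <- pmin(pmax(x[, j], lo), hi)
      }
      prep <- if ("PrEP" %in% colnames(x)) x[, "PrEP"] else 0
      vls <- if ("VLS" %in% colnames(x)) x[, "VLS"] else 0
      eta_cas <- cas_model[1] + cas_model[2] * prep + cas_model[3] * vls
      eta_con <- condom_model[1] + condom_model[2] * prep +
        condom_model[3] * vls
      rows[[wave]] <- data.frame(participant_id = ids, wave = wave,
                                 x, check.names = FALSE,
                                 cas = rbinom(m, 1, plogis(eta_cas)),
                                 condom = rbinom(m, 1, plogis(eta_con)))
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$participant_id, out$wave), ]
    rownames(out) <- NULL
    attr(out, "roster") <- roster
    class(out) <- c("panel_data", "data.frame")
    out
  })
}

#' Write / read a panel as long-format CSV
#'
#' Header: \code{participant_id,wave,<node codes...>,cas,condom}.
#'
#' @param panel a \code{panel_data} data frame.
#' @param path CSV file path.
#' @param roster roster to attach on read (defaults to the default roster).
#' @return \code{read_panel} returns a \code{panel_data}.
#' @export
write_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, roster = make_default_roster()) {
  out <- read.csv(path, check.names = FALSE)
  missing <- setdiff(roster$code, names(out))
  if (length(missing)) {
    stop("panel file lacks roster columns: ", paste(missing, collapse = ", "))
  }
  attr(out, "roster") <- roster
  class(out) <- c("panel_data", "data.frame")
  out
}

# Extract the node-value matrix for one wave (complete cases only).
wave_matrix <- function(panel, wave, roster = attr(panel, "roster")) {
  rows <- panel$wave == wave
  x <- as.matrix(as.data.frame(panel)[rows, roster$code, drop = FALSE])
  x[complete.cases(x), , drop = FALSE]
}
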