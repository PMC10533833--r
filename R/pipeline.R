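# End-to-end study orchestration: simulate/load -> descriptives -> trends
# -> per-wave networks -> bootstrap accuracy -> communities -> centrality
# -> pairwise NCT -> CAS sensitivity, with deterministic staged seeding.

#' Build and validate a study configuration
#'
#' @param mode \code{"simulate"} or \code{"load"}.
#' @param panel_path CSV path of a long-format panel (load mode).
#' @param n_participants,visit_distribution,within_person_sd,burn_in
#'   simulation block, passed to \code{\link{sample_panel}}.
#' @param networks per-wave \code{\link{true_network}} list (simulate
#'   mode); default \code{\link{default_true_networks}}.
#' @param gamma_mgm,gamma_glasso,rule,n_lambda estimation block.
#' @param bootstrap_B,drop_fractions,stability_B bootstrap block.
#' @param community_iterations,community_threshold community block.
#' @param nct_permutations,nct_n_lambda comparison block.
#' @param display_cut display threshold for reported edge lists.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived by
#'   \code{\link{stage_seed}}.
#' @param stages character subset of stages to run.
#' @return a validated \code{study_config} list.
#' @export
study_config <- function(mode = c("simulate", "load"), panel_path = NULL,
                         n_participants = 632,
                         visit_distribution = c(54, 130, 189, 259) / 632,
                         within_person_sd = 0.8, burn_in = 200,
                         networks = NULL, gamma_mgm = 0.25,
                         gamma_glasso = 0.5, rule = "AND", n_lambda = 50,
                         bootstrap_B = 250,
                         drop_fractions = seq(0.1, 0.7, 0.1),
                         stability_B = 100, community_iterations = 250,
                         community_threshold = 0.9,
                         nct_permutations = 1000, nct_n_lambda = 30,
                         display_cut = 0.15, out_dir = tempfile("study"),
                         seed = 1,
                         stages = c("data", "describe", "trends",
                                    "networks", "bootstrap", "stability",
                                    "communities", "nct", "sensitivity")) {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(panel_path) || !file.exists(panel_path)) {
      stop("load mode requires an existing panel_path")
    }
  }
  if (seed != round(seed)) stop("seed must be an integer")
  stages <- union("data", match.arg(stages, several.ok = TRUE))
  structure(list(mode = mode, panel_path = panel_path,
                 n_participants = n_participants,
                 visit_distribution = visit_distribution,
                 within_person_sd = within_person_sd, burn_in = burn_in,
                 networks = networks, gamma_mgm = gamma_mgm,
                 gamma_glasso = gamma_glasso, rule = rule,
                 n_lambda = n_lambda, bootstrap_B = bootstrap_B,
                 drop_fractions = drop_fractions,
                 stability_B = stability_B,
                 community_iterations = community_iterations,
                 community_threshold = community_threshold,
                 nct_permutations = nct_permutations,
                 nct_n_lambda = nct_n_lambda, display_cut = display_cut,
                 out_dir = out_dir, seed = as.integer(seed),
                 stages = stages),
            class = "study_config")
}

#' Keep only participant-waves reporting condomless anal sex
#'
#' @param panel a panel with a \code{cas} column.
#' @return the cas = 1 subset, attributes preserved.
#' @export
filter_cas <- function(panel) {
  if (!"cas" %in% names(panel)) stop("cas column missing")
  out <- panel[panel$cas == 1, , drop = FALSE]
  attr(out, "roster") <- attr(panel, "roster")
  class(out) <- class(panel)
  out
}

#' CAS-restriction sensitivity analysis for one wave
#'
#' Re-estimates the mixed network on the CAS-reporting subset of the wave
#' and tests structure invariance of the full wave versus the subset with
#' the permutation comparison test on the continuous nodes.
#'
#' @param panel a panel data frame.
#' @param wave wave to restrict (default 4, the most recent).
#' @param roster node roster; default from the panel.
#' @param gamma_mgm,gamma_glasso,rule,n_lambda,permutations,nct_n_lambda
#'   estimation and test controls.
#' @param seed integer seed.
#' @return list with \code{network_full}, \code{network_cas}, \code{nct},
#'   \code{n_full}, \code{n_cas}.
#' @export
run_cas_sensitivity <- function(panel, wave = 4,
                                roster = attr(panel, "roster"),
                                gamma_mgm = 0.25, gamma_glasso = 0.5,
                                rule = "AND", n_lambda = 50,
                                permutations = 1000, nct_n_lambda = 30,
                                seed = 1) {
  if (!wave %in% panel$wave) stop("wave ", wave, " absent from panel")
  full_rows <- panel[panel$wave == wave, , drop = FALSE]
  cas_rows <- full_rows[full_rows$cas == 1, , drop = FALSE]
  if (nrow(cas_rows) < 50) {
    stop("CAS subset has ", nrow(cas_rows), " rows (< 50); aborting")
  }
  xf <- as.matrix(as.data.frame(full_rows)[, roster$code])
  xc <- as.matrix(as.data.frame(cas_rows)[, roster$code])
  net_full <- estimate_mgm(xf, roster, gamma = gamma_mgm, rule = rule,
                           n_lambda = n_lambda)
  net_cas <- estimate_mgm(xc, roster, gamma = gamma_mgm, rule = rule,
                          n_lambda = n_lambda)
  cont <- gaussian_codes(roster)
  res <- nct(xf[, cont], xc[, cont], permutations = permutations,
             gamma = gamma_glasso, n_lambda = nct_n_lambda,
             seed = stage_seed(seed, "cas-nct"),
             id_a = full_rows$participant_id,
             id_b = cas_rows$participant_id)
  list(network_full = net_full, network_cas = net_cas, nct = res,
       n_full = nrow(xf), n_cas = nrow(xc))
}

#' Run the full study pipeline
#'
#' Executes the stages in the analysis order — panel acquisition,
#' descriptive tables, GEE trend models, per-wave network estimation with
#' centrality and path length, bootstrap edge accuracy, case-dropping
#' stability, consensus communities, the pairwise comparison schedule, and
#' the CAS sensitivity analysis — writing each stage's outputs before the
#' next begins and recording a manifest (versions, seeds, per-stage wall
#' time, files). A stage failure aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config a \code{\link{study_config}}.
#' @return A \code{study_results} list: \code{panel}, per-wave
#'   \code{networks}, \code{centrality}, \code{bootstraps},
#'   \code{stability}, \code{communities}, \code{aspl}; global
#'   \code{uptake}, \code{beliefs}, \code{trends}, \code{nct},
#'   \code{sensitivity}, \code{manifest}.
#' @export
run_full_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("panelnet")),
                   r_version = R.version.string, seed = config$seed,
                   stages = list(), files = character(0))
  results <- list()
  out_file <- function(...) file.path(config$out_dir, paste0(...))
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({fun(); TRUE},
                   error = function(e) {
                     stop("stage '", name, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    manifest$stages[[name]] <<- list(
      seed = stage_seed(config$seed, name),
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    invisible(ok)
  }
  record <- function(path) {
    manifest$files <<- c(manifest$files, basename(path))
  }

  run_stage("data", function() {
    roster <- make_default_roster()
    if (config$mode == "simulate") {
      networks <- config$networks %||% default_true_networks(roster)
      panel <- sample_panel(networks,
                            n_participants = config$n_participants,
                            visit_distribution = config$visit_distribution,
                            within_person_sd = config$within_person_sd,
                            burn_in = config$burn_in,
                            seed = stage_seed(config$seed, "data"))
      results$true_networks <<- networks
    } else {
      panel <- read_panel(config$panel_path, roster)
    }
    write_panel(panel, out_file("panel.csv")); record("panel.csv")
    write_roster(roster, out_file("roster.json")); record("roster.json")
    results$panel <<- panel
  })
  panel <- results$panel
  roster <- attr(panel, "roster")
  waves <- sort(unique(panel$wave))

  run_stage("describe", function() {
    results$uptake <<- describe_uptake(panel)
    results$beliefs <<- describe_beliefs(panel)
    write.csv(results$uptake, out_file("uptake.csv"), row.names = FALSE)
    write.csv(results$beliefs, out_file("beliefs.csv"), row.names = FALSE)
    record("uptake.csv"); record("beliefs.csv")
  })

  run_stage("trends", function() {
    rows <- list()
    for (oc in c("PrEP", "VLS", "condom")) {
      tr <- fit_gee_trend(panel, oc, "binomial")
      rows[[oc]] <- data.frame(outcome = oc, family = "binomial",
                               effect = tr$effect, ci_low = tr$ci_low,
                               ci_high = tr$ci_high, p = tr$p_value,
                               n_obs = tr$n_obs,
                               n_clusters = tr$n_clusters)
    }
    for (oc in gaussian_codes(roster)) {
      tr <- fit_gee_trend(panel, oc, "gaussian")
      rows[[oc]] <- data.frame(outcome = oc, family = "gaussian",
                               effect = tr$effect, ci_low = tr$ci_low,
                               ci_high = tr$ci_high, p = tr$p_value,
                               n_obs = tr$n_obs,
                               n_clusters = tr$n_clusters)
    }
    results$trends <<- do.call(rbind, c(rows, make.row.names = FALSE))
    write.csv(results$trends, out_file("trends.csv"), row.names = FALSE)
    record("trends.csv")
  })

  run_stage("networks", function() {
    nets <- list(); cent <- list(); aspl <- list()
    for (wv in waves) {
      x <- wave_matrix(panel, wv, roster)
      net <- estimate_mgm(x, roster, gamma = config$gamma_mgm,
                          rule = config$rule, n_lambda = config$n_lambda)
      nets[[as.character(wv)]] <- net
      cent[[as.character(wv)]] <- strength(net)
      aspl[[as.character(wv)]] <- average_shortest_path_length(net)
      write_edge_list(net, out_file("network_w", wv, ".csv"))
      write_weight_matrix(net, out_file("matrix_w", wv, ".csv"))
      write_graphml(net, out_file("network_w", wv, ".graphml"))
      write.csv(cent[[as.character(wv)]],
                out_file("centrality_w", wv, ".csv"), row.names = FALSE)
      record(paste0("network_w", wv, ".csv"))
      record(paste0("matrix_w", wv, ".csv"))
      record(paste0("network_w", wv, ".graphml"))
      record(paste0("centrality_w", wv, ".csv"))
    }
    results$networks <<- nets
    results$centrality <<- cent
    results$aspl <<- aspl
  })

  run_stage("bootstrap", function() {
    boots <- list()
    for (wv in waves) {
      x <- wave_matrix(panel, wv, roster)
      bt <- bootstrap_edges(x, roster, B = config$bootstrap_B,
                            seed = stage_seed(config$seed,
                                              paste0("bootstrap-", wv)),
                            keep_resamples = FALSE,
                            gamma = config$gamma_mgm, rule = config$rule,
                            n_lambda = config$n_lambda)
      boots[[as.character(wv)]] <- bt
      write.csv(bt$summary, out_file("bootstrap_w", wv, ".csv"),
                row.names = FALSE)
      record(paste0("bootstrap_w", wv, ".csv"))
    }
    results$bootstraps <<- boots
  })

  run_stage("stability", function() {
    stab <- list()
    for (wv in waves) {
      x <- wave_matrix(panel, wv, roster)
      st <- casedrop_strength_stability(
        x, roster, drop_fractions = config$drop_fractions,
        B = config$stability_B,
        seed = stage_seed(config$seed, paste0("stability-", wv)),
        gamma = config$gamma_mgm, rule = config$rule,
        n_lambda = config$n_lambda)
      stab[[as.character(wv)]] <- st
      write.csv(st$summary, out_file("stability_w", wv, ".csv"),
                row.names = FALSE)
      record(paste0("stability_w", wv, ".csv"))
    }
    results$stability <<- stab
  })

  run_stage("communities", function() {
    comm <- list()
    for (wv in waves) {
      x <- wave_matrix(panel, wv, roster)
      cc <- consensus_communities(
        x, roster, iterations = config$community_iterations,
        threshold = config$community_threshold,
        seed = stage_seed(config$seed, paste0("communities-", wv)),
        gamma = config$gamma_mgm, rule = config$rule,
        n_lambda = config$n_lambda)
      comm[[as.character(wv)]] <- cc
      write_communities(cc, out_file("communities_w", wv, ".json"))
      record(paste0("communities_w", wv, ".json"))
    }
    results$communities <<- comm
  })

  run_stage("nct", function() {
    res <- nct_pairwise_schedule(panel, roster,
                                 permutations = config$nct_permutations,
                                 gamma = config$gamma_glasso,
                                 n_lambda = config$nct_n_lambda,
                                 seed = config$seed)
    results$nct <<- res
    for (nm in names(res)) {
      write_nct(res[[nm]], out_file("nct_", nm, ".json"))
      record(paste0("nct_", nm, ".json"))
    }
  })

  run_stage("sensitivity", function() {
    sens <- suppressWarnings(run_cas_sensitivity(
      panel, wave = max(waves), roster = roster,
      gamma_mgm = config$gamma_mgm, gamma_glasso = config$gamma_glasso,
      rule = config$rule, n_lambda = config$n_lambda,
      permutations = config$nct_permutations,
      nct_n_lambda = config$nct_n_lambda,
      seed = stage_seed(config$seed, "sensitivity")))
    results$sensitivity <<- sens
    write_nct(sens$nct, out_file("sensitivity_nct.json"))
    record("sensitivity_nct.json")
  })

  results$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  class(results) <- "study_results"
  results
}

#' @export
#' @method print study_results
print.study_results <- function(x, ...) {
  cat("Study results:\n")
  if (!is.null(x$panel)) {
    cat("  panel:", length(unique(x$panel$participant_id)),
        "participants,", nrow(x$panel), "visits\n")
  }
  if (!is.null(x$networks)) {
    cat("  networks:", length(x$networks), "waves; global strength:",
        paste(vapply(x$networks,
                     function(n) signif(global_strength(n), 3), 0),
              collapse = ", "), "\n")
  }
  if (!is.null(x$nct)) {
    cat("  NCT structure p:",
        paste(names(x$nct), vapply(x$nct,
                                   function(r) signif(r$structure_p, 3), 0),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
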