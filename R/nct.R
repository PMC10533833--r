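# Permutation network comparison test on the continuous-variable networks:
# global-strength invariance, structure invariance (maximum edge
# difference), and edge-wise differences with Holm correction.

nct_stats <- function(wa, wb) {
  gs_a <- sum(abs(wa[upper.tri(wa)]))
  gs_b <- sum(abs(wb[upper.tri(wb)]))
  d <- wb - wa
  list(gs_a = gs_a, gs_b = gs_b, gs = abs(gs_a - gs_b),
       m = max(abs(d[upper.tri(d)])), edge = abs(d[upper.tri(d)]))
}

#' Network comparison test between two groups
#'
#' Estimates an EBIC-glasso partial-correlation network per group over the
#' shared continuous nodes, then builds the permutation null by pooling
#' rows, randomly re-splitting into the original group sizes, and
#' re-estimating both networks per permutation. Reports the
#' global-strength difference test, the structure-invariance test (maximum
#' absolute edge difference), and edge-wise difference tests with Holm
#' correction. P-values use the +1 continuity convention
#' \eqn{(1 + \#\{perm \ge obs\})/(1 + P)} and are therefore in (0, 1].
#'
#' @param wave_data_a,wave_data_b matrices or data frames of continuous
#'   node values, same columns.
#' @param permutations number of permutations (>= 200).
#' @param gamma EBIC hyperparameter of the per-group glasso (default 0.5).
#' @param seed integer seed; the test is bit-reproducible given the seed.
#' @param n_lambda glasso path length used inside the test (default 30).
#' @param id_a,id_b optional participant ids; overlapping ids raise a
#'   warning (groups are treated as independent).
#' @return An \code{nct_result}: \code{global_strength_a/b},
#'   \code{gs_statistic}, \code{gs_p}, \code{m_statistic},
#'   \code{structure_p}, per-edge table \code{edges} (node_i, node_j,
#'   diff = b minus a, p, p_holm), \code{permutations}, \code{seed}.
#' @export
nct <- function(wave_data_a, wave_data_b, permutations = 1000, gamma = 0.5,
                seed = 1, n_lambda = 30, id_a = NULL, id_b = NULL) {
  if (permutations < 200) stop("permutations must be >= 200")
  xa <- as.matrix(wave_data_a); xb <- as.matrix(wave_data_b)
  if (!identical(colnames(xa), colnames(xb))) {
    stop("groups must share the continuous roster")
  }
  if (!is.null(id_a) && !is.null(id_b) && length(intersect(id_a, id_b))) {
    warning("groups share participant ids; treated as independent groups")
  }
  # canonical internal order (larger group first, content tie-break) so
  # that swapping the group labels cannot change the permutation stream
  # or any statistic
  swapped <- if (nrow(xa) != nrow(xb)) {
    nrow(xa) < nrow(xb)
  } else {
    da <- as.numeric(xa); db <- as.numeric(xb)
    i <- which(da != db)[1]
    !is.na(i) && da[i] < db[i]
  }
  x1 <- if (swapped) xb else xa
  x2 <- if (swapped) xa else xb
  est <- function(x) coef(estimate_ebic_glasso(x, gamma = gamma,
                                               n_lambda = n_lambda))
  w1 <- est(x1); w2 <- est(x2)
  obs <- nct_stats(w1, w2)
  n1 <- nrow(x1); pool <- rbind(x1, x2); n <- nrow(pool)
  ge_gs <- 0L; ge_m <- 0L
  ge_edge <- numeric(length(obs$edge))
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      idx <- sample.int(n, n1)
      s <- nct_stats(est(pool[idx, , drop = FALSE]),
                     est(pool[-idx, , drop = FALSE]))
      ge_gs <- ge_gs + (s$gs >= obs$gs)
      ge_m <- ge_m + (s$m >= obs$m)
      ge_edge <- ge_edge + (s$edge >= obs$edge)
    }
  })
  gs_p <- (1 + ge_gs) / (1 + permutations)
  structure_p <- (1 + ge_m) / (1 + permutations)
  edge_p <- (1 + ge_edge) / (1 + permutations)
  ut <- which(upper.tri(w1), arr.ind = TRUE)
  dmat <- w2 - w1
  if (swapped) dmat <- -dmat  # report b minus a in the caller's order
  edges <- data.frame(node_i = rownames(w1)[ut[, 1]],
                      node_j = colnames(w1)[ut[, 2]],
                      diff = dmat[ut], p = edge_p,
                      p_holm = p.adjust(edge_p, "holm"), row.names = NULL)
  gsa <- if (swapped) obs$gs_b else obs$gs_a
  gsb <- if (swapped) obs$gs_a else obs$gs_b
  structure(list(global_strength_a = gsa, global_strength_b = gsb,
                 gs_statistic = obs$gs, gs_p = gs_p,
                 m_statistic = obs$m, structure_p = structure_p,
                 edges = edges, permutations = permutations, seed = seed,
                 network_a = if (swapped) w2 else w1,
                 network_b = if (swapped) w1 else w2),
            class = "nct_result")
}

#' @export
#' @method print nct_result
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$permutations, " permutations):\n",
      "  global strength: ", signif(x$global_strength_a, 4), " vs ",
      signif(x$global_strength_b, 4), "  |diff| = ",
      signif(x$gs_statistic, 3), ", p = ", signif(x$gs_p, 3), "\n",
      "  structure (max edge diff): M = ", signif(x$m_statistic, 3),
      ", p = ", signif(x$structure_p, 3), "\n", sep = "")
  sig <- x$edges[x$edges$p_holm < 0.05, ]
  cat("  edges with Holm-adjusted p < 0.05:", nrow(sig), "\n")
  invisible(x)
}

#' Pairwise comparison schedule over four waves
#'
#' Runs \code{\link{nct}} on the four reported wave pairs (1,4), (1,2),
#' (2,3), (3,4) over the continuous roster subset, with per-pair seeds
#' derived from the master seed.
#'
#' @param panel a panel data frame covering waves 1..4.
#' @param roster node roster; default taken from the panel.
#' @param permutations,gamma,n_lambda passed to \code{\link{nct}}.
#' @param seed master seed.
#' @return named list of \code{nct_result} ("T1-T4", "T1-T2", "T2-T3",
#'   "T3-T4").
#' @export
nct_pairwise_schedule <- function(panel, roster = attr(panel, "roster"),
                                  permutations = 1000, gamma = 0.5,
                                  n_lambda = 30, seed = 1) {
  waves <- sort(unique(panel$wave))
  missing <- setdiff(1:4, waves)
  if (length(missing)) stop("missing wave: ", paste(missing, collapse = ", "))
  cont <- gaussian_codes(roster)
  xw <- lapply(1:4, function(wv) {
    wave_matrix(panel, wv, roster)[, cont, drop = FALSE]
  })
  pairs <- list(c(1, 4), c(1, 2), c(2, 3), c(3, 4))
  out <- lapply(pairs, function(pr) {
    nct(xw[[pr[1]]], xw[[pr[2]]], permutations = permutations,
        gamma = gamma, n_lambda = n_lambda,
        seed = stage_seed(seed, paste0("nct-", pr[1], "-", pr[2])))
  })
  names(out) <- vapply(pairs, function(pr) paste0("T", pr[1], "-T", pr[2]),
                       "")
  out
}

#' Hybrid report: NCT significance with mixed-network magnitudes
#'
#' Edges whose Holm-adjusted NCT p-value is below \code{alpha} are
#' annotated with the difference in the corresponding mixed-network edge
#' weights (b minus a). Magnitudes below \code{display_cut} are excluded
#' from the display list but retained in the machine output. A significant
#' edge absent from both mixed networks is annotated 0 and flagged.
#'
#' @param nct_result an \code{\link{nct}} result.
#' @param mgm_a,mgm_b \code{mgm_net} networks whose roster contains the
#'   NCT's continuous nodes.
#' @param display_cut display threshold (default 0.15).
#' @param alpha significance level for the Holm-adjusted p (default 0.05).
#' @return list with \code{all} (every significant edge, annotated) and
#'   \code{display} (the subset with |mgm difference| >= display_cut).
#' @export
hybrid_difference_report <- function(nct_result, mgm_a, mgm_b,
                                     display_cut = 0.15, alpha = 0.05) {
  wa <- net_weights(mgm_a); wb <- net_weights(mgm_b)
  cont <- unique(c(nct_result$edges$node_i, nct_result$edges$node_j))
  if (!all(cont %in% rownames(wa))) {
    stop("continuous roster is not a subset of the mixed roster")
  }
  sig <- nct_result$edges[nct_result$edges$p_holm < alpha, , drop = FALSE]
  if (nrow(sig)) {
    sig$mgm_diff <- mapply(function(i, j) wb[i, j] - wa[i, j],
                           sig$node_i, sig$node_j)
    sig$absent_in_both <- mapply(function(i, j) {
      wa[i, j] == 0 && wb[i, j] == 0
    }, sig$node_i, sig$node_j)
    if (any(sig$absent_in_both)) {
      warning(sum(sig$absent_in_both),
              " significant edge(s) absent from both mixed networks")
    }
  } else {
    sig$mgm_diff <- numeric(0)
    sig$absent_in_both <- logical(0)
  }
  list(all = sig,
       display = sig[abs(sig$mgm_diff) >= display_cut, , drop = FALSE])
}

#' Serialize an NCT result to JSON
#'
#' @param x an \code{nct_result}.
#' @param path output path.
#' @export
write_nct <- function(x, path) {
  jsonlite::write_json(
    list(global_strength_a = x$global_strength_a,
         global_strength_b = x$global_strength_b,
         gs_statistic = x$gs_statistic, gs_p = x$gs_p,
         m_statistic = x$m_statistic, structure_p = x$structure_p,
         permutations = x$permutations, seed = x$seed, edges = x$edges),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
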