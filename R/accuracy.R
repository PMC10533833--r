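# Bootstrap accuracy of edge weights and case-dropping stability of
# strength centrality.

edge_labels <- function(codes) {
  ut <- which(upper.tri(diag(length(codes))), arr.ind = TRUE)
  paste(codes[ut[, 1]], codes[ut[, 2]], sep = "--")
}

upper_vec <- function(w) w[upper.tri(w)]

#' Nonparametric bootstrap of edge weights
#'
#' Draws B resamples of participants with replacement, re-estimates the
#' mixed network on each, and reports per-edge quantile (percentile) 95\%
#' confidence intervals. By default resample-level estimation reuses a
#' lambda path derived from the full sample (EBIC selection still happens
#' per resample); set \code{reuse_lambda = FALSE} for full per-resample
#' path construction. Resamples with a constant column are skipped and
#' counted; a warning is raised if more than 5\% are skipped.
#'
#' @param wave_data complete node-value rows for one wave.
#' @param roster a \code{\link{node_roster}}.
#' @param B number of resamples (>= 100).
#' @param seed integer seed.
#' @param reuse_lambda reuse the full-sample lambda path bounds.
#' @param keep_resamples retain the full edge-by-resample matrix.
#' @param ... passed to \code{\link{estimate_mgm}}.
#' @return An \code{edge_bootstrap}: data frame \code{summary} with
#'   (node_i, node_j, estimate, boot_mean, ci_low, ci_high), the resample
#'   matrix (if kept), B, and the skip count.
#' @export
bootstrap_edges <- function(wave_data, roster, B = 1000, seed = 1,
                            reuse_lambda = TRUE, keep_resamples = TRUE,
                            ...) {
  if (B < 100) stop("B must be >= 100 for reported CIs")
  x <- as.matrix(as.data.frame(wave_data)[, roster$code, drop = FALSE])
  n <- nrow(x)
  full <- estimate_mgm(x, roster, ...)
  extra <- list(...)
  if (reuse_lambda && is.null(extra$lambda_grid)) {
    xs <- scale(x)
    lmax <- 0
    for (j in seq_len(ncol(xs))) {
      lmax <- max(lmax, max(abs(crossprod(xs[, -j], xs[, j]))) / n)
    }
    extra$lambda_grid <- lambda_path(lmax, extra$n_lambda %||% 50,
                                     extra$lambda_min_ratio %||% 0.01)
  }
  ne <- sum(upper.tri(full$weights))
  boot <- matrix(NA_real_, ne, B)
  rownames(boot) <- edge_labels(roster$code)
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      xb <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
      net <- if (any(apply(xb, 2L, sd) == 0)) NULL else {
        tryCatch(
          suppressWarnings(do.call(estimate_mgm,
                                   c(list(xb, roster), extra))),
          error = function(e) NULL)
      }
      if (is.null(net)) {
        skipped <- skipped + 1L
        next
      }
      boot[, b] <- upper_vec(net$weights)
    }
  })
  if (skipped > 0.05 * B) {
    warning(skipped, " of ", B, " resamples skipped (constant column)")
  }
  ok <- !is.na(boot[1, ])
  q <- t(apply(boot[, ok, drop = FALSE], 1L, quantile,
               probs = c(0.025, 0.975)))
  ut <- which(upper.tri(full$weights), arr.ind = TRUE)
  summ <- data.frame(node_i = roster$code[ut[, 1]],
                     node_j = roster$code[ut[, 2]],
                     estimate = upper_vec(full$weights),
                     boot_mean = rowMeans(boot[, ok, drop = FALSE]),
                     ci_low = q[, 1], ci_high = q[, 2], row.names = NULL)
  structure(list(summary = summ,
                 resamples = if (keep_resamples) boot[, ok, drop = FALSE],
                 B = B, n_used = sum(ok), skipped = skipped,
                 network = full),
            class = "edge_bootstrap")
}

#' @export
#' @method print edge_bootstrap
print.edge_bootstrap <- function(x, ...) {
  cat("Edge bootstrap: B =", x$B, "(", x$n_used, "used,", x$skipped,
      "skipped )\n")
  s <- x$summary[x$summary$estimate != 0, ]
  s <- s[order(-abs(s$estimate)), ]
  print(head(s, 10), row.names = FALSE, digits = 3)
  if (nrow(s) > 10) cat("...", nrow(s) - 10, "more nonzero edges\n")
  invisible(x)
}

#' Bootstrap test whether two edge weights differ
#'
#' Declares the edges distinct iff the bootstrap 95\% quantile interval of
#' the per-resample weight difference excludes zero.
#'
#' @param boot an \code{\link{bootstrap_edges}} result with resamples kept.
#' @param edge_a,edge_b length-2 character vectors of node codes.
#' @return list with \code{distinct} (logical), the difference interval,
#'   and the observed difference.
#' @export
edge_difference_test <- function(boot, edge_a, edge_b) {
  if (is.null(boot$resamples)) {
    stop("bootstrap was run with keep_resamples = FALSE")
  }
  find <- function(e) {
    lab <- c(paste(e[1], e[2], sep = "--"), paste(e[2], e[1], sep = "--"))
    i <- which(rownames(boot$resamples) %in% lab)
    if (length(i) != 1L) stop("edge not found: ", lab[1])
    i
  }
  ia <- find(edge_a); ib <- find(edge_b)
  d <- boot$resamples[ia, ] - boot$resamples[ib, ]
  ci <- quantile(d, c(0.025, 0.975), names = FALSE)
  list(distinct = ci[1] > 0 || ci[2] < 0, ci_low = ci[1], ci_high = ci[2],
       observed = boot$summary$estimate[ia] - boot$summary$estimate[ib])
}

#' Case-dropping stability of strength centrality
#'
#' For each drop fraction, draws B subsamples without replacement,
#' re-estimates the network, and correlates (Pearson) the subset strength
#' vector with the full-sample strength vector. The CS coefficient is the
#' largest drop fraction whose correlation is at least \code{cs_threshold}
#' in at least \code{cs_confidence} of subsamples (0 if none).
#'
#' @inheritParams bootstrap_edges
#' @param drop_fractions fractions of participants dropped.
#' @param cs_threshold correlation threshold (default 0.7).
#' @param cs_confidence required proportion of subsamples (default 0.95).
#' @return A \code{stability_result}: data frame \code{summary}
#'   (drop_fraction, mean_cor, q05_cor, prop_above), correlation matrix
#'   \code{correlations}, and \code{cs_coefficient}.
#' @export
casedrop_strength_stability <- function(wave_data, roster,
                                        drop_fractions = seq(0.1, 0.7, 0.1),
                                        B = 250, seed = 1,
                                        cs_threshold = 0.7,
                                        cs_confidence = 0.95, ...) {
  x <- as.matrix(as.data.frame(wave_data)[, roster$code, drop = FALSE])
  n <- nrow(x)
  if (min(floor((1 - drop_fractions) * n)) < 50) {
    stop("smallest retained subset below 50 rows")
  }
  full <- suppressWarnings(estimate_mgm(x, roster, ...))
  s0 <- strength(full)$strength
  cors <- matrix(NA_real_, length(drop_fractions), B,
                 dimnames = list(paste0("drop", drop_fractions), NULL))
  with_seed(seed, {
    for (fi in seq_along(drop_fractions)) {
      m <- floor((1 - drop_fractions[fi]) * n)
      for (b in seq_len(B)) {
        xb <- x[sample.int(n, m), , drop = FALSE]
        if (any(apply(xb, 2L, sd) == 0)) next
        net <- suppressWarnings(
          tryCatch(estimate_mgm(xb, roster, ...), error = function(e) NULL))
        if (is.null(net)) next
        sb <- strength(net)$strength
        if (sd(sb) > 0 && sd(s0) > 0) cors[fi, b] <- cor(sb, s0)
      }
    }
  })
  prop_above <- apply(cors, 1L, function(z) mean(z >= cs_threshold,
                                                 na.rm = TRUE))
  summ <- data.frame(drop_fraction = drop_fractions,
                     mean_cor = rowMeans(cors, na.rm = TRUE),
                     q05_cor = apply(cors, 1L, quantile, 0.05,
                                     na.rm = TRUE),
                     prop_above = prop_above, row.names = NULL)
  passing <- drop_fractions[!is.na(prop_above) &
                              prop_above >= cs_confidence]
  structure(list(summary = summ, correlations = cors,
                 cs_coefficient = if (length(passing)) max(passing) else 0,
                 cs_threshold = cs_threshold,
                 cs_confidence = cs_confidence, B = B),
            class = "stability_result")
}

#' @export
#' @method print stability_result
print.stability_result <- function(x, ...) {
  cat("Case-dropping stability of strength (B =", x$B, "):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("CS coefficient:", x$cs_coefficient, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
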