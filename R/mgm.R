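# Mixed graphical model: nodewise EBIC-penalized regressions over a mixed
# roster, symmetrized with the AND/OR rule.

#' Estimate a mixed graphical model for one wave
#'
#' For each node, fits an L1-penalized regression of that node on all
#' others (linear for gaussian nodes, logistic for binary nodes) over a
#' log-spaced lambda path, and selects the per-node lambda minimizing
#' \eqn{EBIC_\gamma = -2\,loglik + k \log n + 2\gamma k \log(p-1)} with k
#' the number of nonzero coefficients. An edge (i, j) is retained under the
#' AND rule iff both nodewise coefficients are nonzero (OR: either); its
#' weight is the mean of the two coefficients. Edges whose two coefficients
#' disagree in sign are dropped and recorded. All columns (binary included)
#' are standardized internally so cross-family weights share a scale;
#' gaussian-gaussian weights are then interpretable as (approximate)
#' partial correlations.
#'
#' By default the selected node regressions are refitted without penalty on
#' their EBIC-selected support before averaging (relaxed estimates), which
#' removes lasso shrinkage bias from the reported weights; set
#' \code{refit = FALSE} for the raw penalized coefficients.
#'
#' @param wave_data matrix or data frame of complete rows for one wave,
#'   columns named by roster codes.
#' @param roster a \code{\link{node_roster}}.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule \code{"AND"} (default) or \code{"OR"}.
#' @param lambda_grid optional fixed lambda vector used for every node
#'   (e.g. to reuse a path across bootstrap resamples); by default a
#'   per-node path of \code{n_lambda} values from lambda_max down to
#'   \code{lambda_min_ratio * lambda_max}.
#' @param n_lambda,lambda_min_ratio path controls (defaults 50 and 0.01).
#' @param refit logical; unpenalized refit on the selected support.
#' @return An \code{mgm_net} object with elements \code{weights}
#'   (symmetric, zero diagonal), \code{roster}, \code{rule}, \code{gamma},
#'   \code{lambda_selected}, \code{sign_conflicts}, \code{n}.
#' @export
estimate_mgm <- function(wave_data, roster, gamma = 0.25,
                         rule = c("AND", "OR"), lambda_grid = NULL,
                         n_lambda = 50, lambda_min_ratio = 0.01,
                         refit = TRUE) {
  rule <- match.arg(rule)
  x <- as.matrix(as.data.frame(wave_data)[, roster$code, drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (p < 3L) stop("need at least 3 nodes")
  if (n < 50L) warning("n = ", n, " < 50; estimates may be unstable")
  s <- apply(x, 2L, sd)
  if (any(s == 0)) {
    stop("constant column: ", paste(roster$code[s == 0], collapse = ", "))
  }
  xs <- scale(x)
  bmat <- matrix(0, p, p, dimnames = list(roster$code, roster$code))
  lambda_sel <- setNames(numeric(p), roster$code)
  for (j in seq_len(p)) {
    xj <- xs[, -j, drop = FALSE]
    fam <- if (roster$family[j] == "binary") "binomial" else "gaussian"
    yj <- if (fam == "binomial") x[, j] else xs[, j]
    fit <- if (is.null(lambda_grid)) {
      glmnet::glmnet(xj, yj, family = fam, nlambda = n_lambda,
                     lambda.min.ratio = lambda_min_ratio,
                     standardize = FALSE)
    } else {
      glmnet::glmnet(xj, yj, family = fam, lambda = lambda_grid,
                     standardize = FALSE)
    }
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    m2ll <- if (fam == "gaussian") n * log(pmax(dev, 1e-12) / n) else dev
    k <- fit$df
    ebic <- m2ll + k * log(n) + 2 * gamma * k * log(p - 1)
    best <- which.min(ebic)
    lambda_sel[j] <- fit$lambda[best]
    beta <- as.numeric(fit$beta[, best])
    if (refit && any(beta != 0)) {
      supp <- which(beta != 0)
      xr <- cbind(1, xj[, supp, drop = FALSE])
      rf <- tryCatch(suppressWarnings(
        stats::glm.fit(xr, yj,
                       family = if (fam == "binomial") binomial()
                                else gaussian())),
        error = function(e) NULL)
      if (!is.null(rf) && all(is.finite(rf$coefficients)) &&
          all(abs(rf$coefficients[-1]) < 20)) {
        beta[supp] <- rf$coefficients[-1]
      }
    }
    bmat[j, -j] <- beta
  }
  nz <- bmat != 0
  keep <- if (rule == "AND") nz & t(nz) else nz | t(nz)
  conflict <- keep & (bmat * t(bmat) < 0)
  w <- ifelse(keep & !conflict, (bmat + t(bmat)) / 2, 0)
  diag(w) <- 0
  ci <- which(conflict & upper.tri(conflict), arr.ind = TRUE)
  sign_conflicts <- data.frame(node_i = rownames(w)[ci[, 1]],
                               node_j = colnames(w)[ci[, 2]])
  structure(list(weights = w, roster = roster, rule = rule, gamma = gamma,
                 lambda_selected = lambda_sel,
                 sign_conflicts = sign_conflicts, n = n, refit = refit,
                 nodewise = bmat),
            class = "mgm_net")
}

net_weights <- function(x) {
  if (inherits(x, "mgm_net")) x$weights
  else if (inherits(x, "ggm_net")) x$pcor
  else if (is.matrix(x)) x
  else stop("not a network object")
}

#' @export
#' @method print mgm_net
print.mgm_net <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("Mixed graphical model (", x$rule, " rule, gamma = ", x$gamma,
      "): ", nrow(x$weights), " nodes, ", ne, " edges, n = ", x$n, "\n",
      sep = "")
  if (nrow(x$sign_conflicts)) {
    cat("  sign-conflicting edges dropped:", nrow(x$sign_conflicts), "\n")
  }
  invisible(x)
}

#' @export
#' @method summary mgm_net
summary.mgm_net <- function(object, ...) {
  w <- object$weights
  ut <- upper.tri(w)
  out <- list(nodes = nrow(w), edges = sum(w[ut] != 0),
              global_strength = sum(abs(w[ut])),
              mean_abs_weight = mean(abs(w[ut][w[ut] != 0])),
              sign_conflicts = nrow(object$sign_conflicts), n = object$n)
  class(out) <- "summary.mgm_net"
  out
}

#' @export
#' @method print summary.mgm_net
print.summary.mgm_net <- function(x, ...) {
  cat("Nodes:", x$nodes, " Edges:", x$edges,
      " Global strength:", signif(x$global_strength, 4),
      " Mean |w|:", signif(x$mean_abs_weight, 3), " n:", x$n, "\n")
  invisible(x)
}

#' @export
coef.mgm_net <- function(object, ...) object$weights

#' Plot a network as a weighted graph
#'
#' Edges below \code{cut} in absolute weight are omitted from the display
#' (the network itself is unchanged); positive edges are drawn blue,
#' negative red, width proportional to |weight|.
#'
#' @param x an \code{mgm_net} or \code{ggm_net}.
#' @param cut display threshold (default 0.15).
#' @param ... passed to \code{\link[igraph]{plot.igraph}}.
#' @export
plot.mgm_net <- function(x, cut = 0.15, ...) {
  w <- net_weights(x)
  w[abs(w) < cut] <- 0
  gr <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  sgn <- w[igraph::as_edgelist(gr)]
  igraph::plot.igraph(
    gr, edge.width = 4 * abs(igraph::E(gr)$weight),
    edge.color = ifelse(sgn >= 0, "steelblue", "firebrick"),
    vertex.size = 12, vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' @export
plot.ggm_net <- plot.mgm_net

#' Edges at or above a display threshold
#'
#' Reporting/visualization helper: returns the edges with
#' \eqn{|w| \ge cut}; the analysis network is unchanged.
#'
#' @param network an \code{mgm_net}, \code{ggm_net}, or weight matrix.
#' @param cut non-negative threshold, default 0.15 (boundary inclusive).
#' @return data frame (node_i, node_j, weight).
#' @export
threshold_for_display <- function(network, cut = 0.15) {
  stopifnot(cut >= 0)
  w <- net_weights(network)
  ut <- which(upper.tri(w) & abs(w) >= cut & w != 0, arr.ind = TRUE)
  out <- data.frame(node_i = rownames(w)[ut[, 1]],
                    node_j = colnames(w)[ut[, 2]],
                    weight = w[ut])
  out[order(-abs(out$weight)), , drop = FALSE]
}

#' Write a network as an edge-list CSV, a full matrix CSV, or GraphML
#'
#' @param network a network object or weight matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  write.csv(threshold_for_display(network, cut = 0), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_weight_matrix <- function(network, path) {
  w <- net_weights(network)
  write.csv(data.frame(node = rownames(w), w, check.names = FALSE), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  w <- net_weights(network)
  gr <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}
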