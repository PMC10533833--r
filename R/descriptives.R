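# Centrality, connectivity, path length and consensus communities.

#' Strength centrality
#'
#' Per-node strength: the sum of the absolute edge weights incident to the
#' node. Optionally z-standardized across nodes.
#'
#' @param network an \code{mgm_net}, \code{ggm_net}, or symmetric weight
#'   matrix.
#' @param standardized also return z-scored strength.
#' @return data frame (node, strength[, z]).
#' @export
strength <- function(network, standardized = FALSE) {
  w <- net_weights(network)
  check_symmetric(w)
  s <- rowSums(abs(w))
  out <- data.frame(node = rownames(w), strength = unname(s),
                    row.names = NULL)
  if (standardized) out$z <- as.numeric(scale(out$strength))
  out
}

#' Global strength (connectivity)
#'
#' Sum of absolute edge weights over all unordered node pairs.
#'
#' @inheritParams strength
#' @return a single number.
#' @export
global_strength <- function(network) {
  w <- net_weights(network)
  check_symmetric(w)
  sum(abs(w[upper.tri(w)]))
}

#' Average shortest path length over edge distances 1/|w|
#'
#' Dijkstra shortest paths with each edge's length taken as the reciprocal
#' of its absolute weight, averaged over all connected ordered pairs;
#' disconnected pairs are excluded and counted.
#'
#' @inheritParams strength
#' @return list with \code{aspl} and \code{n_disconnected_pairs}; the
#'   numeric value also prints via \code{aspl}.
#' @export
average_shortest_path_length <- function(network) {
  w <- net_weights(network)
  check_symmetric(w)
  if (all(w == 0)) stop("network has no edges")
  gr <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d <- igraph::distances(gr, weights = 1 / igraph::E(gr)$weight)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  list(aspl = mean(off[finite]),
       n_disconnected_pairs = 2L * sum(!finite))
}

#' Consensus communities by iterated walktrap on resampled networks
#'
#' Per iteration, participants are bootstrap-resampled, the mixed network
#' re-estimated, and walktrap (random-walk agglomerative modularity
#' clustering, walk length 4) run on the absolute edge weights. Pairwise
#' co-membership frequencies are accumulated across iterations; consensus
#' clusters are the connected components of the graph that keeps node
#' pairs co-assigned in more than \code{threshold} of iterations. Nodes in
#' no super-threshold pair become singletons. An iteration yielding an
#' empty network counts as an all-singleton partition.
#'
#' @param wave_data complete node-value rows for one wave.
#' @param roster a \code{\link{node_roster}}.
#' @param iterations number of resampled iterations (>= 100).
#' @param threshold co-membership frequency required, in (0.5, 1].
#' @param seed integer seed.
#' @param ... passed to \code{\link{estimate_mgm}} (e.g. \code{n_lambda}).
#' @return A \code{community_consensus}: \code{co_membership} (frequency
#'   matrix, unit diagonal), \code{consensus_clusters} (named integer
#'   vector), \code{iterations}, \code{threshold}.
#' @export
consensus_communities <- function(wave_data, roster, iterations = 1000,
                                  threshold = 0.9, seed = 1, ...) {
  if (iterations < 100) stop("iterations must be >= 100")
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  x <- as.matrix(as.data.frame(wave_data)[, roster$code, drop = FALSE])
  n <- nrow(x); p <- ncol(x)
  co <- matrix(0, p, p, dimnames = list(roster$code, roster$code))
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      xb <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
      net <- tryCatch(
        suppressWarnings(estimate_mgm(xb, roster, ...)),
        error = function(e) NULL)
      memb <- if (is.null(net) || all(net$weights == 0)) {
        seq_len(p)  # empty network: all singletons
      } else {
        walktrap_membership(net$weights)
      }
      co <- co + outer(memb, memb, "==")
    }
  })
  co <- co / iterations
  diag(co) <- 1
  keep <- co > threshold
  diag(keep) <- TRUE
  gr <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                            diag = FALSE)
  clusters <- igraph::components(gr)$membership
  names(clusters) <- roster$code
  structure(list(co_membership = co, consensus_clusters = clusters,
                 iterations = iterations, threshold = threshold),
            class = "community_consensus")
}

# Walktrap (walk length 4) on absolute edge weights; deterministic on a
# fixed graph. Isolated vertices stay in their own community.
walktrap_membership <- function(weights) {
  gr <- igraph::graph_from_adjacency_matrix(abs(weights),
                                            mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::membership(igraph::cluster_walktrap(gr, steps = 4))
}

#' @export
#' @method print community_consensus
print.community_consensus <- function(x, ...) {
  k <- max(x$consensus_clusters)
  sizes <- table(x$consensus_clusters)
  cat("Consensus communities (", x$iterations, " iterations, threshold ",
      x$threshold, "): ", k, " clusters (",
      sum(sizes == 1), " singletons)\n", sep = "")
  for (cl in seq_len(k)) {
    if (sizes[cl] > 1) {
      cat("  [", cl, "] ",
          paste(names(x$consensus_clusters)[x$consensus_clusters == cl],
                collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialize a consensus-community result to JSON
#'
#' @param x a \code{community_consensus}.
#' @param path output path.
#' @export
write_communities <- function(x, path) {
  jsonlite::write_json(
    list(iterations = x$iterations, threshold = x$threshold,
         clusters = split(names(x$consensus_clusters),
                          x$consensus_clusters),
         co_membership = as.data.frame(x$co_membership)),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
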