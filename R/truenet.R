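# Ground-truth pairwise Markov random fields used by the panel generator.

#' Construct a ground-truth pairwise MRF over a roster
#'
#' The generating model is a pairwise Markov random field over mixed nodes.
#' Each gaussian node has conditional distribution
#' N(threshold + participant intercept + sum_j w_ij x_j, gaussian_sd^2);
#' each binary node is Bernoulli with logit equal to the same linear
#' predictor. With a common conditional SD the gaussian block corresponds to
#' a Gaussian MRF with precision (I - W_gg) / sd^2, so planted
#' gaussian-gaussian weights equal partial correlations when sd = 1.
#'
#' @param roster a \code{\link{node_roster}}.
#' @param weights symmetric numeric matrix (zero diagonal) over the roster.
#' @param thresholds per-node intercepts (default 0).
#' @param gaussian_sd common conditional standard deviation of gaussian
#'   nodes before truncation to the scale range.
#' @param wave integer wave label.
#' @return A \code{true_network} object.
#' @export
true_network <- function(roster, weights, thresholds = NULL,
                         gaussian_sd = 1, wave = 1L) {
  p <- nrow(roster)
  check_symmetric(weights)
  if (nrow(weights) != p) stop("weight matrix dimension must equal roster size")
  dimnames(weights) <- list(roster$code, roster$code)
  if (is.null(thresholds)) thresholds <- setNames(numeric(p), roster$code)
  if (length(thresholds) != p) stop("thresholds must have one entry per node")
  names(thresholds) <- roster$code
  g <- roster$family == "gaussian"
  if (any(g)) {
    prec <- diag(sum(g)) - weights[g, g, drop = FALSE]
    ev <- min(eigen(prec, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0.05) {
      stop("gaussian block of I - W is (nearly) singular; min eigenvalue ",
           signif(ev, 3))
    }
  }
  structure(list(roster = roster, weights = weights,
                 thresholds = thresholds, gaussian_sd = gaussian_sd,
                 wave = as.integer(wave)),
            class = "true_network")
}

#' @export
#' @method print true_network
print.true_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("True MRF (wave ", x$wave, "): ", nrow(x$roster), " nodes, ", nz,
      " edges, |W| sum ", round(sum(abs(x$weights[upper.tri(x$weights)])), 2),
      "\n", sep = "")
  invisible(x)
}

# Oracle: partial correlations implied by the gaussian block (sd common).
# With conditional mean tau + W x and common sd, Theta = (I - W)/sd^2 and
# the partial correlation matrix equals W when all diagonal entries agree.
#' Oracle partial correlations of a gaussian-block ground truth
#'
#' @param net a \code{\link{true_network}}.
#' @return symmetric matrix of partial correlations over the gaussian nodes.
#' @export
oracle_pcor <- function(net) {
  g <- net$roster$family == "gaussian"
  prec <- diag(sum(g)) - net$weights[g, g, drop = FALSE]
  structure(precision_to_pcor(prec),
            dimnames = list(net$roster$code[g], net$roster$code[g]))
}

#' Add a weight change to selected waves
#'
#' Returns copies of the per-wave ground-truth networks with
#' \code{weights[edge]} incremented by \code{delta} on the listed waves only.
#'
#' @param networks list of \code{\link{true_network}}, one per wave.
#' @param edge length-2 character vector of node codes.
#' @param delta numeric change added to the edge weight.
#' @param waves integer indices into \code{networks} to modify.
#' @return list of \code{true_network}.
#' @export
plant_edge_change <- function(networks, edge, delta, waves) {
  stopifnot(length(edge) == 2L)
  if (edge[1] == edge[2]) stop("self-loop edges are not allowed")
  for (k in waves) {
    net <- networks[[k]]
    if (!all(edge %in% net$roster$code)) stop("edge nodes not in roster")
    w <- net$weights
    w[edge[1], edge[2]] <- w[edge[1], edge[2]] + delta
    w[edge[2], edge[1]] <- w[edge[1], edge[2]]
    networks[[k]] <- true_network(net$roster, w, net$thresholds,
                                  net$gaussian_sd, net$wave)
  }
  networks
}

#' Write / read a ground-truth network (edge list CSV + thresholds JSON)
#'
#' @param net a \code{\link{true_network}}.
#' @param edges_path CSV path for the edge list (node_i, node_j, weight).
#' @param meta_path JSON path for thresholds and metadata.
#' @param roster roster used when reading back.
#' @return \code{read_true_network} returns a \code{true_network}.
#' @export
write_true_network <- function(net, edges_path, meta_path) {
  ut <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  edges <- data.frame(node_i = rownames(net$weights)[ut[, 1]],
                      node_j = colnames(net$weights)[ut[, 2]],
                      weight = net$weights[ut])
  write.csv(edges, edges_path, row.names = FALSE)
  jsonlite::write_json(
    list(wave = net$wave, gaussian_sd = net$gaussian_sd,
         thresholds = as.list(net$thresholds)),
    meta_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(edges_path)
}

#' @rdname write_true_network
#' @export
read_true_network <- function(edges_path, meta_path, roster) {
  edges <- read.csv(edges_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  p <- nrow(roster)
  w <- matrix(0, p, p, dimnames = list(roster$code, roster$code))
  for (i in seq_len(nrow(edges))) {
    w[edges$node_i[i], edges$node_j[i]] <- edges$weight[i]
    w[edges$node_j[i], edges$node_i[i]] <- edges$weight[i]
  }
  true_network(roster, w, unlist(meta$thresholds)[roster$code],
               meta$gaussian_sd, meta$wave)
}
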