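# EBIC-regularized graphical lasso over the continuous node subset.

#' Estimate a partial-correlation network by EBIC graphical lasso
#'
#' Maximizes \eqn{\log\det\Theta - tr(S\Theta) - \lambda \|\Theta\|_{1,off}}
#' over a log-spaced lambda path on the sample correlation matrix, selects
#' lambda by \eqn{EBIC_\gamma = -2\,loglik + E \log n + 4\gamma E \log p}
#' (E = number of nonzero off-diagonal precision entries), and returns the
#' partial correlations \eqn{\rho_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}
#' \theta_{jj}}}.
#'
#' @param wave_data matrix or data frame of continuous columns (>= 3).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda number of path values (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#'   (the largest absolute off-diagonal sample correlation).
#' @param lambdas optional explicit lambda path (overrides the above).
#' @return A \code{ggm_net}: \code{pcor} (symmetric, zero diagonal),
#'   \code{theta}, \code{gamma}, \code{lambda_selected}, \code{ebic},
#'   \code{lambda_path}, \code{skipped} (non-converged lambdas), \code{n}.
#' @export
estimate_ebic_glasso <- function(wave_data, gamma = 0.5, n_lambda = 100,
                                 lambda_min_ratio = 0.01, lambdas = NULL) {
  x <- as.matrix(wave_data)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (p < 3L) stop("need at least 3 continuous nodes")
  s <- apply(x, 2L, sd)
  if (any(s == 0)) {
    stop("constant column: ", paste(colnames(x)[s == 0], collapse = ", "))
  }
  S <- cor(x)
  if (is.null(lambdas)) {
    lmax <- max(abs(S[upper.tri(S)]))
    if (lmax <= 0) lmax <- 0.1
    lambdas <- lambda_path(lmax, n_lambda, lambda_min_ratio)
  }
  lambdas <- sort(lambdas, decreasing = TRUE)
  fit <- glasso_path_cpp(S, lambdas)
  ebic <- rep(Inf, length(lambdas))
  for (m in seq_along(lambdas)) {
    if (!fit$converged[m]) next
    theta <- fit$theta[[m]]
    ld <- determinant(theta, logarithm = TRUE)
    if (ld$sign <= 0) next
    ll <- n / 2 * (as.numeric(ld$modulus) - sum(S * theta))
    E <- sum(theta[upper.tri(theta)] != 0)
    ebic[m] <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
  }
  if (all(!is.finite(ebic))) stop("graphical lasso failed at every lambda")
  best <- which.min(ebic)
  theta <- fit$theta[[best]]
  dimnames(theta) <- dimnames(S)
  pcor <- precision_to_pcor(theta)
  structure(list(pcor = pcor, theta = theta, gamma = gamma,
                 lambda_selected = lambdas[best], ebic = ebic,
                 lambda_path = lambdas,
                 skipped = lambdas[!fit$converged], n = n),
            class = "ggm_net")
}

#' @export
#' @method print ggm_net
print.ggm_net <- function(x, ...) {
  ne <- sum(x$pcor[upper.tri(x$pcor)] != 0)
  cat("EBIC glasso network (gamma = ", x$gamma, "): ", nrow(x$pcor),
      " nodes, ", ne, " edges, lambda = ", signif(x$lambda_selected, 3),
      ", n = ", x$n, "\n", sep = "")
  if (length(x$skipped)) {
    cat("  non-converged lambdas skipped:", length(x$skipped), "\n")
  }
  invisible(x)
}

#' @export
coef.ggm_net <- function(object, ...) object$pcor
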