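# Generalized estimating equations for repeated questionnaire waves.
# Logistic (uptake) and linear (beliefs) marginal models with exchangeable
# or independence working correlation and robust sandwich covariance.

# Core solver. x: model matrix, y: response, id: cluster labels (data must
# not need to be contiguous; we sort internally).
gee_solve <- function(x, y, id, family = c("binomial", "gaussian"),
                      corstr = c("exchangeable", "independence"),
                      maxit = 100, tol = 1e-10) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  ord <- order(id)
  x <- x[ord, , drop = FALSE]; y <- y[ord]; id <- id[ord]
  n <- length(y); q <- ncol(x)
  cl <- split(seq_len(n), id)
  fam <- if (family == "binomial") binomial() else gaussian()
  beta <- suppressWarnings(
    coef(stats::glm.fit(x, y, family = fam)))
  if (anyNA(beta)) stop("initial fit is rank deficient")
  alpha <- 0; phi <- 1
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- fam$linkinv(eta)
    vmu <- fam$variance(mu)
    dmu <- fam$mu.eta(eta)
    pr <- (y - mu) / sqrt(vmu)
    phi <- sum(pr^2) / (n - q)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni > 1L) {
          s <- sum(pr[ix])
          num <- num + (s^2 - sum(pr[ix]^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (npairs > q) num / ((npairs - q) * phi) else 0
      alpha <- max(min(alpha, 0.95), -0.95)
    }
    bread <- matrix(0, q, q)
    score <- numeric(q)
    for (ix in cl) {
      ni <- length(ix)
      d <- x[ix, , drop = FALSE] * dmu[ix]
      rs <- y[ix] - mu[ix]
      a <- sqrt(vmu[ix])
      if (corstr == "independence" || ni == 1L) {
        vinv_d <- d / (vmu[ix] * phi)
        vinv_r <- rs / (vmu[ix] * phi)
      } else {
        # closed-form inverse of the exchangeable correlation matrix
        c1 <- 1 / (1 - alpha)
        c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
        ds <- d / a; rss <- rs / a
        rinv_d <- c1 * ds - c2 * matrix(colSums(ds), ni, ncol(d),
                                        byrow = TRUE)
        rinv_r <- c1 * rss - c2 * sum(rss)
        vinv_d <- rinv_d / (a * phi)
        vinv_r <- rinv_r / (a * phi)
      }
      bread <- bread + crossprod(d, vinv_d)
      score <- score + drop(crossprod(d, vinv_r))
    }
    delta <- solve(bread, score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  if (max(abs(delta)) >= sqrt(tol)) {
    stop("GEE did not converge after ", maxit, " iterations")
  }
  # sandwich (robust) covariance
  eta <- drop(x %*% beta); mu <- fam$linkinv(eta)
  vmu <- fam$variance(mu); dmu <- fam$mu.eta(eta)
  bread <- matrix(0, q, q); meat <- matrix(0, q, q)
  for (ix in cl) {
    ni <- length(ix)
    d <- x[ix, , drop = FALSE] * dmu[ix]
    rs <- y[ix] - mu[ix]
    a <- sqrt(vmu[ix])
    if (corstr == "independence" || ni == 1L) {
      vinv_d <- d / (vmu[ix] * phi)
      vinv_r <- rs / (vmu[ix] * phi)
    } else {
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      ds <- d / a; rss <- rs / a
      rinv_d <- c1 * ds - c2 * matrix(colSums(ds), ni, ncol(d), byrow = TRUE)
      rinv_r <- c1 * rss - c2 * sum(rss)
      vinv_d <- rinv_d / (a * phi)
      vinv_r <- rinv_r / (a * phi)
    }
    bread <- bread + crossprod(d, vinv_d)
    u <- drop(crossprod(d, vinv_r))
    meat <- meat + tcrossprod(u)
  }
  binv <- solve(bread)
  vcov <- binv %*% meat %*% binv
  list(coefficients = setNames(beta, colnames(x)), vcov = vcov,
       alpha = alpha, phi = phi, n_obs = n, n_clusters = length(cl),
       iterations = it, family = family, corstr = corstr)
}

gee_wald <- function(fit, term) {
  est <- fit$coefficients[term]
  se <- sqrt(diag(fit$vcov))[term]
  z <- est / se
  list(estimate = est, se = se,
       ci_low = est - qnorm(0.975) * se,
       ci_high = est + qnorm(0.975) * se,
       p = 2 * pnorm(-abs(z)))
}

#' Test for linear trend over waves by GEE
#'
#' Fits a marginal intercept + time model (wave index 1..K as a numeric
#' covariate) with participants as clusters, solving the generalized
#' estimating equations with the chosen working correlation, and reports
#' robust (sandwich) Wald inference. For a binomial outcome the effect is
#' the odds ratio per subsequent wave, exp(coefficient), with an
#' exp-transformed Wald interval; for a gaussian outcome the effect is the
#' regression coefficient per wave.
#'
#' @param panel a panel data frame with \code{participant_id} and
#'   \code{wave}.
#' @param outcome outcome column name.
#' @param family \code{"binomial"} or \code{"gaussian"}.
#' @param working_correlation \code{"exchangeable"} (default) or
#'   \code{"independence"}.
#' @return A \code{gee_trend} object: outcome, family, effect, ci_low,
#'   ci_high, p_value, n_obs, n_clusters, plus the raw coefficient and the
#'   working-correlation estimate.
#' @export
fit_gee_trend <- function(panel, outcome,
                          family = c("binomial", "gaussian"),
                          working_correlation = c("exchangeable",
                                                  "independence")) {
  family <- match.arg(family)
  working_correlation <- match.arg(working_correlation)
  df <- as.data.frame(panel)
  if (!outcome %in% names(df)) stop("outcome not in panel: ", outcome)
  keep <- !is.na(df[[outcome]])
  df <- df[keep, ]
  y <- df[[outcome]]
  if (length(unique(df$wave)) < 2L) {
    stop("trend undefined: outcome observed at fewer than 2 waves")
  }
  if (var(y) == 0) stop("degenerate outcome: '", outcome, "' is constant")
  sizes <- table(df$participant_id)
  if (sum(sizes >= 2) < 2L) stop("need at least 2 clusters with >= 2 visits")
  x <- cbind(`(Intercept)` = 1, time = df$wave)
  fit <- gee_solve(x, y, df$participant_id, family, working_correlation)
  w <- gee_wald(fit, "time")
  if (family == "binomial") {
    effect <- exp(w$estimate); ci <- exp(c(w$ci_low, w$ci_high))
  } else {
    effect <- w$estimate; ci <- c(w$ci_low, w$ci_high)
  }
  structure(list(outcome = outcome, family = family,
                 effect = unname(effect), ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), p_value = unname(w$p),
                 coefficient = unname(w$estimate), se = unname(w$se),
                 n_obs = fit$n_obs, n_clusters = fit$n_clusters,
                 working_correlation = working_correlation,
                 alpha = fit$alpha, fit = fit),
            class = "gee_trend")
}

#' @export
#' @method print gee_trend
print.gee_trend <- function(x, ...) {
  lab <- if (x$family == "binomial") "OR" else "beta"
  cat("GEE trend for '", x$outcome, "' (", x$family, ", ",
      x$working_correlation, "):\n  ", lab, " per wave = ",
      signif(x$effect, 3), " (95% CI ", signif(x$ci_low, 3), "-",
      signif(x$ci_high, 3), "), p = ", signif(x$p_value, 3), "\n  n = ",
      x$n_obs, " visits, ", x$n_clusters, " participants\n", sep = "")
  invisible(x)
}

#' @export
coef.gee_trend <- function(object, ...) object$fit$coefficients

#' Multivariable GEE sensitivity model for uptake outcomes
#'
#' Logistic GEE of the uptake outcome on time plus all other roster nodes
#' as covariates, reporting per-covariate odds ratios, robust Wald CIs and
#' p-values. Covariates with |coefficient| > 10 are flagged as showing
#' separation and the model result is kept.
#'
#' @param panel a panel with the roster attached (or pass \code{roster}).
#' @param outcome \code{"PrEP"} or \code{"VLS"}.
#' @param roster node roster; default taken from the panel.
#' @return data frame (term, or, ci_low, ci_high, p, separation).
#' @export
trend_sensitivity_all_predictors <- function(panel, outcome = c("PrEP", "VLS"),
                                             roster = attr(panel, "roster")) {
  outcome <- match.arg(outcome)
  df <- as.data.frame(panel)
  if (length(unique(df$wave)) < 2L) {
    stop("trend undefined: panel has a single wave")
  }
  covs <- setdiff(roster$code, outcome)
  x <- cbind(`(Intercept)` = 1, time = df$wave,
             as.matrix(df[, covs, drop = FALSE]))
  y <- df[[outcome]]
  if (var(y) == 0) stop("degenerate outcome: '", outcome, "' is constant")
  fit <- gee_solve(x, y, df$participant_id, "binomial", "exchangeable")
  terms <- setdiff(colnames(x), "(Intercept)")
  w <- gee_wald(fit, terms)
  out <- data.frame(term = terms, or = exp(unname(w$estimate)),
                    ci_low = exp(w$estimate - qnorm(0.975) * w$se),
                    ci_high = exp(w$estimate + qnorm(0.975) * w$se),
                    p = unname(w$p),
                    separation = abs(unname(w$estimate)) > 10,
                    row.names = NULL)
  if (any(out$separation)) {
    warning("possible separation for: ",
            paste(out$term[out$separation], collapse = ", "))
  }
  out
}
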