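# Internal helpers: deterministic seeding, input checks, small numerics.

#' Derive a stage seed from a master seed
#'
#' Stable polynomial hash of the stage name folded into the master seed, so
#' that adding a pipeline stage never shifts the random streams of earlier
#' stages. Result is a non-negative integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master %% m)
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

# Column-standardize a numeric matrix; constant columns error with the name.
standardize_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  if (any(s == 0)) {
    stop("constant column: ", paste(colnames(x)[s == 0], collapse = ", "))
  }
  scale(x, center = mu, scale = s)
}

check_symmetric <- function(w, tol = 1e-10) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("weights must be a square matrix")
  if (max(abs(w - t(w))) > tol) stop("weights must be symmetric")
  if (any(abs(diag(w)) > tol)) stop("weights must have a zero diagonal")
  invisible(TRUE)
}

# Partial correlations from a precision matrix.
precision_to_pcor <- function(theta) {
  d <- sqrt(diag(theta))
  p <- -theta / tcrossprod(d)
  diag(p) <- 0
  (p + t(p)) / 2
}

# Round half away from zero (display rounding used in the uptake tables).
round_half_away <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# Log-spaced lambda path from lambda_max down to ratio * lambda_max.
lambda_path <- function(lambda_max, n_lambda, ratio) {
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n_lambda))
}
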