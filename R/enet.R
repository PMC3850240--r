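#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)` — the proximal operator of the l1 penalty,
#' applied coordinate-wise inside the coordinate-descent update.
#'
#' @param z numeric vector.
#' @param gamma nonnegative threshold.
#' @return thresholded values, same length as `z`.
#' @export
soft_threshold <- function(z, gamma) {
  if (any(gamma < 0)) stop("gamma must be nonnegative")
  sign(z) * pmax(abs(z) - gamma, 0)
}

#' Solver configuration
#'
#' @param epsilon ratio lambda_min / lambda_max for the path (default 0.001).
#' @param K number of lambda values on the log-spaced path (default 100).
#' @param tol convergence tolerance: a sweep converges when the maximum
#'   squared coefficient change, on the standardized scale, falls below `tol`
#'   (default 1e-7, i.e. changes below about 3e-4).
#' @param max_iter cap on coordinate sweeps per lambda (default 1e5).
#' @param update_rule `"naive"` (residual updates, O(pn) per full cycle) or
#'   `"covariance"` (cached cross-products, O(pm) when the active set is
#'   stable); both give identical coefficients.
#' @param standardize standardize predictors to unit variance before fitting
#'   (coefficients are always returned on the original scale).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(epsilon = 0.001, K = 100L, tol = 1e-7,
                          max_iter = 1e5, update_rule = c("naive", "covariance"),
                          standardize = TRUE) {
  update_rule <- match.arg(update_rule)
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  if (K < 2) stop("K must be at least 2")
  if (tol <= 0) stop("tol must be positive")
  structure(list(epsilon = epsilon, K = as.integer(K), tol = tol,
                 max_iter = as.integer(max_iter), update_rule = update_rule,
                 standardize = standardize),
            class = "solver_config")
}

.as_matrix <- function(X) {
  if (inherits(X, "genotype_matrix")) {
    if (anyNA(X$values)) stop("genotype matrix contains missing values; run qc_filter() first")
    storage.mode(X$values) <- "double"
    X$values
  } else {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    X
  }
}

#' Lambda path for the elastic net
#'
#' Computes `lambda_max`, the smallest penalty at which every penalized
#' coefficient is zero, as
#' `max_j |<x_j, y - ybar>| / (n * alpha * pf_j)` over penalized predictors
#' (standardized x), then returns `K` values log-spaced down to
#' `epsilon * lambda_max`.  For `alpha = 0` the all-zero point does not exist;
#' alpha is clamped to 0.001 for path construction only.
#'
#' @param X predictor matrix or `genotype_matrix`.
#' @param y response vector.
#' @param alpha elastic-net mixing weight in \[0, 1\] (1 = lasso).
#' @param config a [solver_config()].
#' @param penalty_factors per-predictor penalty multipliers; 0 marks an
#'   unpenalized covariate.
#' @param rows optional subset of individuals (1-based) used to compute the
#'   path, e.g. a training fold.
#' @return decreasing numeric vector of length `config$K`.
#' @export
lambda_path <- function(X, y, alpha, config = solver_config(),
                        penalty_factors = NULL, rows = NULL) {
  X <- .as_matrix(X)
  n_all <- nrow(X); p <- ncol(X)
  if (is.null(rows)) rows <- seq_len(n_all)
  rows <- as.integer(rows)
  n <- length(rows)
  if (is.null(penalty_factors)) penalty_factors <- rep(1, p)
  if (all(penalty_factors == 0)) stop("all penalty factors are zero: path undefined")
  a <- max(alpha, 0.001)
  yc <- y[rows] - mean(y[rows])
  dots <- .col_crossprod_cpp(X, yc, rows)
  if (config$standardize) {
    means <- .col_crossprod_cpp(X, rep(1, n), rows) / n
    sds <- sqrt(pmax(.col_sumsq_cpp(X, rows) / n - means^2, 0))
    ok <- sds > 1e-6 & penalty_factors > 0
    vals <- abs(dots[ok]) / (n * a * penalty_factors[ok] * sds[ok])
  } else {
    ok <- penalty_factors > 0
    vals <- abs(dots[ok]) / (n * a * penalty_factors[ok])
  }
  # tiny inflation so the boundary coordinate rounds to exactly zero at the
  # top of the path
  lam_max <- max(vals) * (1 + 1e-9)
  exp(seq(log(lam_max), log(config$epsilon * lam_max), length.out = config$K))
}

#' Fit the elastic-net path by cyclic coordinate descent
#'
#' Minimizes, for each lambda on the path (warm-started from the previous),
#' \deqn{\frac{1}{2n}\|y - \beta_0 - X\beta\|^2 +
#'   \lambda \sum_j pf_j [\alpha |\beta_j| + \tfrac{1-\alpha}{2}\beta_j^2]}
#' by cyclic coordinate descent with soft thresholding and proportional
#' shrinkage.  Predictors are standardized internally; returned coefficients
#' are on the original scale.  Zero-variance columns get coefficient 0.
#'
#' @inheritParams lambda_path
#' @param lambda_seq decreasing penalty sequence; computed by [lambda_path()]
#'   when `NULL`.
#' @return an object of class `enet_path` with fields `alpha`, `lambda_seq`,
#'   `intercepts` (length K), `coefs` (p x K), `penalty_factors`, `n_iter`,
#'   `converged`.
#' @export
fit_path <- function(X, y, alpha, lambda_seq = NULL,
                     penalty_factors = NULL, config = solver_config(),
                     rows = NULL) {
  Xm <- .as_matrix(X)
  n_all <- nrow(Xm); p <- ncol(Xm)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.null(rows)) rows <- seq_len(n_all)
  rows <- as.integer(rows)
  if (!all(is.finite(y[rows])) || !all(is.finite(Xm)))
    stop("non-finite values in input")
  if (is.null(penalty_factors)) penalty_factors <- rep(1, p)
  if (length(penalty_factors) != p) stop("penalty_factors length mismatch")
  if (is.null(lambda_seq))
    lambda_seq <- lambda_path(Xm, y, alpha, config, penalty_factors, rows)
  if (is.unsorted(rev(lambda_seq))) stop("lambda_seq must be decreasing")

  fit <- .ccd_path_cpp(Xm, as.numeric(y), rows, alpha,
                       as.numeric(lambda_seq), as.numeric(penalty_factors),
                       config$tol, config$max_iter,
                       config$update_rule == "covariance")
  structure(list(alpha = alpha, lambda_seq = as.numeric(lambda_seq),
                 intercepts = as.numeric(fit$intercepts), coefs = fit$coefs,
                 penalty_factors = as.numeric(penalty_factors),
                 n_iter = as.integer(fit$n_iter),
                 converged = as.logical(fit$converged),
                 standardize = config$standardize),
            class = "enet_path")
}

#' @export
print.enet_path <- function(x, ...) {
  nz <- colSums(x$coefs != 0)
  cat(sprintf("enet_path: alpha = %g, %d lambdas (%.4g .. %.4g), df %d .. %d\n",
              x$alpha, length(x$lambda_seq), x$lambda_seq[1],
              x$lambda_seq[length(x$lambda_seq)], nz[1], nz[length(nz)]))
  invisible(x)
}

#' Predict from a fitted elastic-net path
#'
#' @param object an `enet_path`.
#' @param X_new matrix (or `genotype_matrix`) with the same columns as the
#'   training predictors.
#' @param lambda_index index into the lambda path.
#' @param ... unused.
#' @return numeric vector of predictions `beta0 + X_new %*% beta`.
#' @export
predict.enet_path <- function(object, X_new, lambda_index, ...) {
  X_new <- .as_matrix(X_new)
  if (ncol(X_new) != nrow(object$coefs)) stop("X_new column count mismatch")
  if (lambda_index < 1 || lambda_index > length(object$lambda_seq))
    stop("lambda_index out of range")
  drop(object$intercepts[lambda_index] +
         X_new %*% object$coefs[, lambda_index])
}

#' Elastic-net objective value
#'
#' `(1/2n)||y - b0 - Xb||^2 + lambda * sum_j pf_j (alpha |b_j| +
#' (1-alpha)/2 b_j^2)`, evaluated on standardized predictors so that the
#' objective matches the solver's internal parameterization.  Used in tests to
#' compare against independent optimizers.
#'
#' @param X predictor matrix.
#' @param y response.
#' @param b0,b intercept and coefficients on the standardized scale.
#' @param alpha,lambda penalty parameters.
#' @param penalty_factors per-predictor multipliers.
#' @return scalar objective value.
#' @export
enet_objective <- function(X, y, b0, b, alpha, lambda, penalty_factors = NULL) {
  X <- .as_matrix(X)
  n <- nrow(X)
  if (is.null(penalty_factors)) penalty_factors <- rep(1, ncol(X))
  r <- y - b0 - drop(X %*% b)
  sum(r^2) / (2 * n) +
    lambda * sum(penalty_factors * (alpha * abs(b) + (1 - alpha) / 2 * b^2))
}
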