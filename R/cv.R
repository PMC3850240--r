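#' Random k-fold partition
#'
#' @param n number of observations.
#' @param k number of folds (2 <= k <= n); fold sizes differ by at most one.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return integer vector of fold labels in 1..k, length n.
#' @export
make_folds <- function(n, k, seed) {
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n")
  set.seed(as.integer(seed))
  sample(rep(seq_len(k), length.out = n))
}

#' k-fold cross-validation over the lambda path
#'
#' The lambda grid is computed once on the full data and reused across folds.
#' For each fold the path is fitted on the remaining k-1 folds and held-out
#' squared errors are recorded at every lambda.  `mean_mse` averages over all
#' n held-out errors; `se_mse` is the standard error of the k per-fold MSEs
#' (SD / sqrt(k)).  `lambda_min` minimizes `mean_mse`; `lambda_1se` is the
#' largest lambda whose mean MSE is within one standard error of the minimum.
#'
#' @inheritParams fit_path
#' @param k number of folds (default 10).
#' @param seed seed for the fold partition (independent of any simulation
#'   stream).
#' @return object of class `cv_result` with the CV curve, the two selected
#'   lambdas and their path indices, and a full-data `enet_path` fit.
#' @export
cv_path <- function(X, y, alpha, k = 10, config = solver_config(),
                    penalty_factors = NULL, seed = 1L) {
  Xm <- .as_matrix(X)
  n <- nrow(Xm)
  if (is.null(penalty_factors)) penalty_factors <- rep(1, ncol(Xm))
  lambda_seq <- lambda_path(Xm, y, alpha, config, penalty_factors)
  K <- length(lambda_seq)
  fold_ids <- make_folds(n, k, seed)

  sq_err <- matrix(NA_real_, n, K)
  for (f in seq_len(k)) {
    test <- which(fold_ids == f)
    train <- which(fold_ids != f)
    if (stats::var(y[train]) == 0) {
      warning(sprintf("fold %d has constant training response; skipped", f))
      next
    }
    fit <- fit_path(Xm, y, alpha, lambda_seq, penalty_factors, config,
                    rows = train)
    pred <- matrix(fit$intercepts, length(test), K, byrow = TRUE) +
      Xm[test, , drop = FALSE] %*% fit$coefs
    sq_err[test, ] <- (y[test] - pred)^2
  }
  used <- !is.na(sq_err[, 1L])
  mean_mse <- colMeans(sq_err[used, , drop = FALSE])
  fold_mse <- rowsum(sq_err[used, , drop = FALSE], fold_ids[used]) /
    as.vector(table(fold_ids[used]))
  se_mse <- apply(fold_mse, 2, stats::sd) / sqrt(nrow(fold_mse))

  i_min <- which.min(mean_mse)
  thresh <- mean_mse[i_min] + se_mse[i_min]
  i_1se <- min(which(mean_mse <= thresh))  # largest lambda within 1 SE
  full_fit <- fit_path(Xm, y, alpha, lambda_seq, penalty_factors, config)

  structure(list(lambda_seq = lambda_seq, mean_mse = mean_mse,
                 se_mse = se_mse, lambda_min = lambda_seq[i_min],
                 lambda_1se = lambda_seq[i_1se], index_min = i_min,
                 index_1se = i_1se, fold_ids = fold_ids, seed = seed,
                 alpha = alpha, fit = full_fit),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("cv_result: alpha = %g, %d folds\n",
                     "  lambda_min = %.5g (CV MSE %.4g)\n",
                     "  lambda_1se = %.5g (CV MSE %.4g)\n"),
              x$alpha, max(x$fold_ids), x$lambda_min, x$mean_mse[x$index_min],
              x$lambda_1se, x$mean_mse[x$index_1se]))
  invisible(x)
}

#' Variable selection at a CV-chosen lambda
#'
#' Reads the coefficients at `lambda_min` or `lambda_1se` off the full-data
#' path fit and returns the indices of nonzero penalized coefficients;
#' unpenalized covariates (penalty factor 0) are excluded from the selection.
#'
#' @param fit an `enet_path` (typically `cv$fit`).
#' @param cv a `cv_result`.
#' @param criterion `"min"` or `"1se"`.
#' @return object of class `selection_result` with fields `criterion`,
#'   `lambda_star`, `lambda_index`, `selected` (integer indices),
#'   `coefficients` (nonzero values at lambda_star), `cv_mse`.
#' @export
select_variables <- function(fit, cv, criterion = c("1se", "min")) {
  criterion <- match.arg(criterion)
  idx <- if (criterion == "min") cv$index_min else cv$index_1se
  beta <- fit$coefs[, idx]
  sel <- which(beta != 0 & fit$penalty_factors > 0)
  structure(list(criterion = criterion,
                 lambda_star = fit$lambda_seq[idx], lambda_index = idx,
                 selected = sel, coefficients = beta[sel],
                 cv_mse = cv$mean_mse[idx]),
            class = "selection_result")
}

#' Averaged lambda over repeated cross-validation runs
#'
#' Runs k-fold CV `runs` times with different fold partitions and returns the
#' arithmetic mean of the per-run selected lambdas, smoothing out the
#' fold-partition noise in the chosen penalty.  The averaged lambda is used
#' as-is (not snapped to the grid) for a final full-data refit.
#'
#' @inheritParams cv_path
#' @param runs number of CV repetitions.
#' @param criterion `"min"` or `"1se"`.
#' @param seeds optional integer vector of per-run fold seeds (length `runs`);
#'   derived from `seed` when `NULL`.
#' @param seed base seed used to derive per-run seeds.
#' @return list with `lambda_star` (the average), `lambda_runs` (per-run
#'   values) and `selection` (a `selection_result`-like list from the
#'   full-data refit at the averaged lambda).
#' @export
repeated_cv_lambda <- function(X, y, alpha, runs = 10, k = 10,
                               criterion = c("1se", "min"),
                               config = solver_config(),
                               penalty_factors = NULL, seeds = NULL,
                               seed = 1L) {
  criterion <- match.arg(criterion)
  if (runs < 1) stop("runs must be >= 1")
  if (is.null(seeds)) seeds <- as.integer(seed) + 7919L * seq_len(runs)
  if (length(seeds) != runs) stop("seeds must have length runs")
  lams <- vapply(seeds, function(s) {
    cv <- cv_path(X, y, alpha, k, config, penalty_factors, seed = s)
    if (criterion == "min") cv$lambda_min else cv$lambda_1se
  }, numeric(1))
  lambda_star <- mean(lams)
  # full-data refit at exactly the averaged lambda: descend the path to it
  Xm <- .as_matrix(X)
  grid <- lambda_path(Xm, y, alpha, config, penalty_factors)
  path <- sort(unique(c(grid[grid > lambda_star], lambda_star)),
               decreasing = TRUE)
  fit <- fit_path(Xm, y, alpha, path, penalty_factors, config)
  idx <- length(path)
  beta <- fit$coefs[, idx]
  sel <- which(beta != 0 & fit$penalty_factors > 0)
  list(lambda_star = lambda_star, lambda_runs = lams,
       selection = structure(list(criterion = criterion,
                                  lambda_star = lambda_star,
                                  lambda_index = idx, selected = sel,
                                  coefficients = beta[sel], cv_mse = NA_real_),
                             class = "selection_result"))
}
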