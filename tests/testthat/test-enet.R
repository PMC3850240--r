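test_that("soft thresholding follows its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  z <- c(-2, -0.3, 0, 0.3, 2)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(z, 0.5), c(-1.5, 0, 0, 0, 1.5))
  expect_error(soft_threshold(1, -1), "nonnegative")
})

test_that("lambda path spans [lambda_max, eps*lambda_max] log-uniformly and zeroes the model at its top", {
  inst <- toy_instance(n = 60, p = 12, seed = 2)
  cfg <- solver_config(epsilon = 0.001, K = 100)
  for (alpha in c(1, 0.4)) {
    lam <- lambda_path(inst$X, inst$y, alpha, cfg)
    expect_length(lam, 100)
    expect_equal(lam[100] / lam[1], 0.001, tolerance = 1e-10)
    expect_equal(sd(diff(log(lam))), 0, tolerance = 1e-12)
    fit <- fit_path(inst$X, inst$y, alpha, lam, config = cfg)
    expect_true(all(fit$coefs[, 1] == 0))
    # KKT at lambda_max: all standardized gradients within alpha*lambda_max
    Xs <- std1n(inst$X)
    g <- abs(crossprod(Xs, inst$y - mean(inst$y)) / nrow(Xs))
    expect_true(all(g <= alpha * lam[1] * (1 + 1e-10)))
    expect_equal(max(g), alpha * lam[1], tolerance = 1e-8)
  }
  # lambda_max scales as 1/alpha
  l1 <- lambda_path(inst$X, inst$y, 1, cfg)
  l01 <- lambda_path(inst$X, inst$y, 0.1, cfg)
  expect_equal(l01[1] / l1[1], 10, tolerance = 1e-10)
  expect_error(lambda_path(inst$X, inst$y, 1, cfg,
                           penalty_factors = rep(0, 12)), "penalty factors")
})

test_that("lasso on an orthonormal design equals soft-thresholded OLS", {
  set.seed(9)
  n <- 64; p <- 8
  # columns orthonormal and exactly mean-zero: orthogonalize against 1 first
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n))))[, 2:(p + 1)]
  Xs <- sqrt(n) * Q                              # unit 1/n variance, gram = I
  y <- drop(Xs %*% c(2, -1, 0.5, 0.2, 0, 0, 0, 0)) + rnorm(n, sd = 0.1)
  b_ols <- drop(crossprod(Xs, y - mean(y)) / n)
  for (lam in c(0.05, 0.3, 1)) {
    fit <- fit_path(Xs, y, 1, lambda_seq = c(2 * max(abs(b_ols)), lam),
                    config = solver_config(tol = 1e-14))
    expect_equal(fit$coefs[, 2], soft_threshold(b_ols, lam),
                 tolerance = 1e-7)
  }
})

test_that("the path end at tiny lambda matches ordinary least squares", {
  inst <- toy_instance(n = 50, p = 8, seed = 3)
  lam <- lambda_path(inst$X, inst$y, 1, solver_config(epsilon = 1e-8, K = 50))
  fit <- fit_path(inst$X, inst$y, 1, lam, config = solver_config(tol = 1e-16))
  ols <- lm(inst$y ~ inst$X)
  expect_equal(fit$coefs[, 50], unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(fit$intercepts[50], unname(coef(ols)[1]), tolerance = 1e-6)
  pred <- predict(fit, inst$X, 50)
  expect_equal(pred, unname(fitted(ols)), tolerance = 1e-5)
})

test_that("coordinate descent matches a high-precision proximal-gradient oracle", {
  for (seed in 1:3) {
    inst <- toy_instance(n = 40, p = 10, seed = seed)
    Xs <- std1n(inst$X)
    yc <- inst$y - mean(inst$y)
    set.seed(seed)
    pf <- c(rep(1, 8), 0.5, 2)
    for (alpha in c(1, 0.6, 0.2)) {
      lam_seq <- lambda_path(inst$X, inst$y, alpha,
                             solver_config(K = 5, epsilon = 0.01),
                             penalty_factors = pf)
      fit <- fit_path(inst$X, inst$y, alpha, lam_seq, penalty_factors = pf,
                      config = solver_config(tol = 1e-14))
      for (k in c(3, 5)) {
        b_cd <- to_std_scale(inst$X, fit$coefs[, k])
        b_or <- fista_enet(Xs, yc, alpha, lam_seq[k], pf)
        o_cd <- enet_obj_std(Xs, yc, b_cd, alpha, lam_seq[k], pf)
        o_or <- enet_obj_std(Xs, yc, b_or, alpha, lam_seq[k], pf)
        expect_equal(o_cd, o_or, tolerance = 1e-6)
        expect_equal(b_cd, b_or, tolerance = 1e-4)
      }
    }
  }
})

test_that("KKT conditions hold at convergence along the path", {
  inst <- toy_instance(n = 50, p = 12, seed = 4)
  alpha <- 0.7
  lam_seq <- lambda_path(inst$X, inst$y, alpha, solver_config(K = 20))
  fit <- fit_path(inst$X, inst$y, alpha, lam_seq,
                  config = solver_config(tol = 1e-16))
  Xs <- std1n(inst$X)
  yc <- inst$y - mean(inst$y)
  for (k in c(1, 10, 20)) {
    b <- to_std_scale(inst$X, fit$coefs[, k])
    g <- drop(crossprod(Xs, yc - Xs %*% b)) / nrow(Xs) -
      lam_seq[k] * (1 - alpha) * b
    zero <- b == 0
    expect_true(all(abs(g[zero]) <= lam_seq[k] * alpha + 1e-7))
    if (any(!zero))
      expect_equal(g[!zero], lam_seq[k] * alpha * sign(b[!zero]),
                   tolerance = 1e-6)
  }
})

test_that("alpha=0 reproduces the analytic ridge solution and alpha=1 a reference lasso", {
  inst <- toy_instance(n = 60, p = 10, seed = 5)
  Xs <- std1n(inst$X)
  yc <- inst$y - mean(inst$y)
  n <- nrow(Xs)
  lam <- 0.4
  fit <- fit_path(inst$X, inst$y, 0, lambda_seq = c(10, lam),
                  config = solver_config(tol = 1e-16))
  b_ridge <- solve(crossprod(Xs) / n + lam * diag(10),
                   crossprod(Xs, yc) / n)
  expect_equal(to_std_scale(inst$X, fit$coefs[, 2]), drop(b_ridge),
               tolerance = 1e-6)

  skip_if_not_installed("glmnet")
  # unit-variance response: our objective and glmnet's parameterization agree
  ys <- yc / sqrt(mean(yc^2))
  lam_seq <- lambda_path(inst$X, ys, 1)
  fit1 <- fit_path(inst$X, ys, 1, lam_seq, config = solver_config(tol = 1e-12))
  g <- glmnet::glmnet(inst$X, ys, alpha = 1, lambda = lam_seq, thresh = 1e-14)
  expect_equal(as.matrix(g$beta), fit1$coefs, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("elastic-net agreement with the reference implementation across alphas", {
  skip_if_not_installed("glmnet")
  inst <- toy_instance(n = 80, p = 25, seed = 6)
  yc <- inst$y - mean(inst$y)
  ys <- yc / sqrt(mean(yc^2))
  for (alpha in c(0.75, 0.3, 0.1)) {
    lam_seq <- lambda_path(inst$X, ys, alpha, solver_config(K = 30))
    fit <- fit_path(inst$X, ys, alpha, lam_seq,
                    config = solver_config(tol = 1e-12))
    g <- glmnet::glmnet(inst$X, ys, alpha = alpha, lambda = lam_seq,
                        thresh = 1e-14)
    expect_equal(as.matrix(g$beta), fit$coefs, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("naive and covariance update rules produce identical paths", {
  inst <- toy_instance(n = 50, p = 15, seed = 7)
  for (alpha in c(1, 0.3)) {
    lam_seq <- lambda_path(inst$X, inst$y, alpha, solver_config(K = 25))
    f1 <- fit_path(inst$X, inst$y, alpha, lam_seq,
                   config = solver_config(update_rule = "naive"))
    f2 <- fit_path(inst$X, inst$y, alpha, lam_seq,
                   config = solver_config(update_rule = "covariance"))
    expect_equal(f1$coefs, f2$coefs, tolerance = 1e-9)
    expect_equal(f1$intercepts, f2$intercepts, tolerance = 1e-9)
  }
})

test_that("sparsity is non-decreasing in alpha at fixed lambda", {
  inst <- toy_instance(n = 50, p = 20, seed = 8)
  alphas <- c(0.05, 0.1, 0.3, 0.6, 1)
  for (lam in c(0.05, 0.15, 0.4)) {
    nz <- sapply(alphas, function(a) {
      fit <- fit_path(inst$X, inst$y, a, lambda_seq = c(5, lam))
      sum(fit$coefs[, 2] == 0)
    })
    expect_true(all(diff(nz) >= 0))
  }
})

test_that("zero-variance columns are skipped with zero coefficients", {
  inst <- toy_instance(n = 30, p = 6, seed = 9)
  X <- cbind(inst$X, 3)  # constant column
  lam <- lambda_path(X, inst$y, 1)
  fit <- fit_path(X, inst$y, 1, lam)
  expect_true(all(fit$coefs[7, ] == 0))
})

test_that("predict validates its inputs and reproduces simple arithmetic", {
  fit <- structure(list(alpha = 1, lambda_seq = 0.5, intercepts = 1,
                        coefs = matrix(2), penalty_factors = 1,
                        n_iter = 1L, converged = TRUE, standardize = TRUE),
                   class = "enet_path")
  expect_equal(predict(fit, matrix(3), 1), 7)
  expect_error(predict(fit, matrix(3), 2), "out of range")
  expect_error(predict(fit, matrix(1, 1, 2), 1), "mismatch")
})
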