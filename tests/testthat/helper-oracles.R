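# Independent oracles and small fixtures shared across test files.

# Standardize columns to mean 0 / variance 1 with the 1/n denominator used by
# the solver; zero-variance columns become all-zero.
std1n <- function(X) {
  m <- colMeans(X)
  s <- sqrt(colMeans(X^2) - m^2)
  s[s < 1e-12] <- Inf
  sweep(sweep(X, 2, m), 2, s, "/")
}

# High-precision FISTA solver for the elastic-net objective
#   (1/2n)||yc - Xs b||^2 + lambda * sum pf_j (alpha |b_j| + (1-alpha)/2 b_j^2)
# on standardized predictors and centered response.  Independent of the
# coordinate-descent implementation under test.
fista_enet <- function(Xs, yc, alpha, lambda, pf = rep(1, ncol(Xs)),
                       iters = 50000, tol = 1e-13) {
  n <- nrow(Xs); p <- ncol(Xs)
  L <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                 only.values = TRUE)$values) +
    lambda * (1 - alpha) * max(pf)
  b <- rep(0, p); v <- b; tk <- 1
  for (it in seq_len(iters)) {
    grad <- -crossprod(Xs, yc - Xs %*% v) / n + lambda * (1 - alpha) * pf * v
    bn <- drop(v - grad / L)
    thr <- lambda * alpha * pf / L
    bn <- sign(bn) * pmax(abs(bn) - thr, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- bn + (tk - 1) / tn * (bn - b)
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn; tk <- tn
  }
  b
}

# Objective value matching the solver's parameterization, on standardized
# scale coefficients.
enet_obj_std <- function(Xs, yc, b, alpha, lambda, pf = rep(1, length(b))) {
  n <- nrow(Xs)
  r <- yc - drop(Xs %*% b)
  sum(r^2) / (2 * n) +
    lambda * sum(pf * (alpha * abs(b) + (1 - alpha) / 2 * b^2))
}

# Small dense regression instance with a few informative predictors.
toy_instance <- function(n = 40, p = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, 1:3] %*% c(1.5, -1, 0.5)) + rnorm(n)
  list(X = X, y = y)
}

# Convert solver coefficients (original scale) to the standardized scale the
# oracle works on.
to_std_scale <- function(X, beta) {
  s <- sqrt(colMeans(X^2) - colMeans(X)^2)
  beta * s
}
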