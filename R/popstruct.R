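#' Genetic similarity matrix between individuals
#'
#' Inner products of column-standardized genotypes, divided by the number of
#' SNPs (a genomic-relationship-style matrix), then shifted and scaled to the
#' nonnegative range \[0, 1\] so it can serve as the weight matrix of a
#' similarity graph over individuals.
#'
#' @param G `genotype_matrix` or plain matrix (no missing values).
#' @return symmetric n x n matrix of weights in \[0, 1\].
#' @export
similarity_matrix <- function(G) {
  Xm <- .as_matrix(G)
  if (nrow(Xm) < 2) stop("need at least 2 individuals")
  sds <- apply(Xm, 2, stats::sd)
  keep <- sds > 1e-12
  S <- tcrossprod(scale(Xm[, keep, drop = FALSE])) / sum(keep)
  W <- (S - min(S)) / (max(S) - min(S))
  (W + t(W)) / 2
}

#' Spectral embedding of the similarity graph
#'
#' Eigenvectors of the symmetric-normalized weight matrix
#' `D^{-1/2} W D^{-1/2}` (D = diagonal row-sum degree matrix).  The leading
#' eigenvector is the trivial near-constant direction `D^{1/2} 1` and is
#' dropped; the next `q` eigenvectors are returned as orthonormal covariates
#' encoding population structure.  Signs are fixed so the first entry of
#' largest magnitude is positive.
#'
#' @param W symmetric nonnegative weight matrix, e.g. from
#'   [similarity_matrix()].
#' @param q number of eigenvector covariates to return.
#' @return object of class `covariate_matrix` with fields `vectors` (n x q,
#'   orthonormal), `eigenvalues` (length q), `n_significant` (NA unless set
#'   by [n_significant()]).
#' @export
spectral_eigenvectors <- function(W, q) {
  n <- nrow(W)
  if (q >= n) stop("q must be smaller than the number of individuals")
  if (max(abs(W - t(W))) > 1e-8) stop("W must be symmetric")
  d <- rowSums(W)
  if (any(d <= 0)) stop("zero-degree vertex in similarity graph")
  Dh <- 1 / sqrt(d)
  M <- W * tcrossprod(Dh)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  # drop the trivial leading eigenvector (proportional to sqrt(d))
  V <- eig$vectors[, 2:(q + 1), drop = FALSE]
  vals <- eig$values[2:(q + 1)]
  for (j in seq_len(ncol(V))) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(vectors = V, eigenvalues = vals, n_significant = NA_integer_),
            class = "covariate_matrix")
}

#' Number of significant structure eigenvectors by permutation null
#'
#' Compares the leading nontrivial eigenvalues of the spectral embedding of
#' `G` with those of null populations obtained by independently permuting
#' each SNP column across individuals (which preserves allele frequencies but
#' destroys structure).  An eigenvalue is significant while it exceeds the
#' maximum of the corresponding eigenvalue over all null simulations; the
#' count stops at the first non-exceeding position.
#'
#' @param G `genotype_matrix` or plain matrix.
#' @param n_null_sims number of null populations (default 10).
#' @param seed integer seed.
#' @param q_max how many leading eigenvalues to test (default 10).
#' @return integer count of significant eigenvectors.
#' @export
n_significant <- function(G, n_null_sims = 10, seed = 1L, q_max = 10) {
  Xm <- .as_matrix(G)
  n <- nrow(Xm)
  q_max <- min(q_max, n - 2L)
  obs <- spectral_eigenvectors(similarity_matrix(Xm), q_max)$eigenvalues
  set.seed(as.integer(seed))
  null_max <- rep(-Inf, q_max)
  for (s in seq_len(n_null_sims)) {
    Xp <- apply(Xm, 2, sample)
    ev <- spectral_eigenvectors(similarity_matrix(Xp), q_max)$eigenvalues
    null_max <- pmax(null_max, ev)
  }
  exceeds <- obs > null_max
  if (!exceeds[1]) 0L else sum(cumprod(exceeds) > 0)
}

#' Principal-component covariates from standardized genotypes
#'
#' Plain PCA alternative to the spectral embedding: the top `q` left singular
#' vectors of the column-standardized genotype matrix.
#'
#' @inheritParams spectral_eigenvectors
#' @param G `genotype_matrix` or plain matrix.
#' @return a `covariate_matrix` (vectors orthonormal; eigenvalues are the
#'   squared singular values / (n - 1)).
#' @export
pca_eigenvectors <- function(G, q) {
  Xm <- .as_matrix(G)
  n <- nrow(Xm)
  if (q >= n) stop("q must be smaller than the number of individuals")
  sds <- apply(Xm, 2, stats::sd)
  Z <- scale(Xm[, sds > 1e-12, drop = FALSE])
  sv <- svd(Z, nu = q, nv = 0)
  V <- sv$u
  for (j in seq_len(ncol(V))) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(vectors = V, eigenvalues = sv$d[seq_len(q)]^2 / (n - 1),
                 n_significant = NA_integer_),
            class = "covariate_matrix")
}
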