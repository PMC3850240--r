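#' Per-SNP single-marker regression scan
#'
#' Ordinary least squares of the phenotype on (intercept, covariates, one SNP)
#' for every SNP, with the two-sided t-test p-value for the SNP slope.  The
#' scan is vectorized: phenotype and genotypes are residualized on the
#' intercept-plus-covariate design once, after which each SNP slope is a
#' ratio of inner products with the usual residual-variance t statistic on
#' n - q - 1 degrees of freedom (q = number of non-SNP columns).
#'
#' Zero-variance SNPs (after residualization) get slope 0, p = 1 and are
#' flagged in the `degenerate` column.
#'
#' @param G `genotype_matrix` or plain matrix (no missing values; impute
#'   first).
#' @param y phenotype vector.
#' @param covariates optional numeric matrix of additional fixed covariates.
#' @return data.frame with columns snp_id, index, slope, se, t, p, degenerate.
#' @export
marker_scan <- function(G, y, covariates = NULL) {
  Xm <- .as_matrix(G)
  snp_ids <- if (inherits(G, "genotype_matrix")) G$snp_ids
             else sprintf("snp%06d", seq_len(ncol(Xm)))
  n <- nrow(Xm)
  if (length(y) != n) stop("phenotype length mismatch")
  Z <- cbind(Intercept = rep(1, n), covariates)
  q <- ncol(Z)
  df <- n - q - 1L
  if (df < 1) stop("not enough residual degrees of freedom")
  qrZ <- qr(Z)
  ry <- qr.resid(qrZ, y)
  RG <- qr.resid(qrZ, Xm)
  gg <- colSums(RG^2)
  gy <- drop(crossprod(RG, ry))
  yy <- sum(ry^2)
  degen <- gg <= 1e-10
  slope <- ifelse(degen, 0, gy / gg)
  rss <- pmax(yy - slope * gy, 0)
  se <- ifelse(degen, NA_real_, sqrt(rss / df / gg))
  tval <- ifelse(degen, 0, slope / se)
  pval <- ifelse(degen, 1, 2 * stats::pt(-abs(tval), df))
  data.frame(snp_id = snp_ids, index = seq_len(ncol(Xm)), slope = slope,
             se = se, t = tval, p = pval, degenerate = degen,
             stringsAsFactors = FALSE)
}

#' Bonferroni selection from a marker scan
#'
#' @param scan data.frame from [marker_scan()].
#' @param family_alpha family-wise error rate (default 0.05); the per-test
#'   threshold is `family_alpha / nrow(scan)`.
#' @return integer vector of selected SNP indices.
#' @export
bonferroni_select <- function(scan, family_alpha = 0.05) {
  if (nrow(scan) == 0) return(integer(0))
  scan$index[scan$p < family_alpha / nrow(scan)]
}

#' Transform p-values to z-values
#'
#' The default signed form is `z = sign(slope) * |qnorm(p/2)|`, which keeps
#' the direction of effect for two-sided p-values.  The literal one-sided
#' form `z = qnorm(p)` (which maps all small p-values to the left tail) is
#' available with `signed = FALSE`.  P-values are clipped to
#' \[1e-15, 1 - 1e-15\] before the quantile transform.
#'
#' @param p p-values in (0, 1\].
#' @param slope optional effect signs for the signed transform.
#' @param signed use the signed two-tailed convention (default TRUE).
#' @return numeric z vector.
#' @export
z_transform <- function(p, slope = NULL, signed = TRUE) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  if (signed) {
    if (is.null(slope)) stop("signed transform needs slopes for direction")
    sign(slope) * abs(stats::qnorm(p / 2))
  } else {
    stats::qnorm(p)
  }
}

#' Local false discovery rate with an empirical null
#'
#' Estimates `fdr(z) = pi0 * f0(z) / f(z)`: the marginal density f is fitted
#' by Poisson regression of histogram counts on a natural-spline basis of the
#' bin midpoints; the empirical null N(delta0, sigma0^2) and the null
#' proportion pi0 are fitted by maximum likelihood on the central portion of
#' the z-values (truncated-normal likelihood on the central window, with
#' pi0 = central count / (N * null mass in window)).  SNPs with fdr below the
#' threshold are flagged as non-null.
#'
#' @param z numeric vector of z-values.
#' @param threshold flagging threshold on the local fdr (default 0.2).
#' @param bins number of histogram bins (default 120).
#' @param df natural-spline degrees of freedom for the density fit
#'   (default 7).
#' @param null_fit_range central proportion of z used for the empirical-null
#'   fit (default 0.5).
#' @return object of class `local_fdr_result` with fields `z`, `delta0`,
#'   `sigma0`, `pi0`, `fdr` (clipped to \[0, 1\]), `flagged`, `threshold`.
#' @export
local_fdr <- function(z, threshold = 0.2, bins = 120, df = 7,
                      null_fit_range = 0.5) {
  N <- length(z)
  if (N < bins) stop("too few z-values for density estimation")

  # marginal density by Poisson spline regression on histogram counts
  br <- seq(min(z) - 1e-8, max(z) + 1e-8, length.out = bins + 1)
  h <- hist(z, breaks = br, plot = FALSE)
  mid <- h$mids
  w <- diff(br)[1]
  basis <- splines::ns(mid, df = df)
  pois <- stats::glm(h$counts ~ basis, family = stats::poisson())
  f_bin <- pmax(stats::fitted(pois), 1e-12) / (N * w)

  # empirical null: truncated-normal ML on the central window
  lo <- stats::quantile(z, (1 - null_fit_range) / 2)
  hi <- stats::quantile(z, 1 - (1 - null_fit_range) / 2)
  if (hi - lo < 1e-8) stop("degenerate central window for the null fit")
  zc <- z[z >= lo & z <= hi]
  nll <- function(par) {
    d <- par[1]; s <- exp(par[2])
    mass <- stats::pnorm(hi, d, s) - stats::pnorm(lo, d, s)
    if (mass <= 0) return(1e10)
    -sum(stats::dnorm(zc, d, s, log = TRUE)) + length(zc) * log(mass)
  }
  # the truncated-normal likelihood is unbounded toward the uniform limit
  # (sigma -> Inf); constrain the null mode to the central window and sigma
  # to the window scale, which is where a genuine empirical null must live
  s_up <- log(2 * (hi - lo))
  s0 <- min(max(log(stats::sd(zc)), log(0.05) + 1e-6), s_up - 1e-6)
  opt <- stats::optim(c(stats::median(zc), s0), nll, method = "L-BFGS-B",
                      lower = c(lo, log(0.05)), upper = c(hi, s_up))
  delta0 <- opt$par[1]
  sigma0 <- exp(opt$par[2])
  mass <- stats::pnorm(hi, delta0, sigma0) - stats::pnorm(lo, delta0, sigma0)
  pi0 <- length(zc) / (N * mass)
  if (pi0 > 1) {
    warning("pi0 estimate exceeded 1; clipped")
    pi0 <- 1
  }

  bin_of <- findInterval(z, br, rightmost.closed = TRUE, all.inside = TRUE)
  f_z <- f_bin[bin_of]
  fdr <- pmin(pmax(pi0 * stats::dnorm(z, delta0, sigma0) / f_z, 0), 1)
  structure(list(z = z, delta0 = delta0, sigma0 = sigma0, pi0 = pi0,
                 fdr = fdr, flagged = which(fdr < threshold),
                 threshold = threshold),
            class = "local_fdr_result")
}

#' @export
print.local_fdr_result <- function(x, ...) {
  cat(sprintf(paste0("local_fdr_result: %d z-values\n",
                     "  empirical null N(%.3f, %.3f^2), pi0 = %.3f\n",
                     "  %d flagged at fdr < %g\n"),
              length(x$z), x$delta0, x$sigma0, x$pi0, length(x$flagged),
              x$threshold))
  invisible(x)
}
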