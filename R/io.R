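#' Read a genotype matrix from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{raw}{PLINK `.raw`-style whitespace-delimited text: a header line
#'     `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP
#'     (header typically suffixed with the counted allele, e.g. `snp1_A`),
#'     genotypes 0/1/2, missing coded `NA`.}
#'   \item{csv}{a plain delimited matrix, one header row of SNP ids, one row
#'     per individual, genotypes 0/1/2, missing empty or `NA`.}
#' }
#'
#' @param path file path.
#' @param format `"raw"` or `"csv"`.
#' @return a `genotype_matrix`; for `"raw"` the phenotype column is attached
#'   as attribute `"phenotype"`.
#' @export
read_genotypes <- function(path, format = c("raw", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "raw") {
    tab <- utils::read.table(path, header = TRUE, sep = "",
                             na.strings = "NA", check.names = FALSE,
                             colClasses = NA, stringsAsFactors = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!identical(colnames(tab)[1:6], need))
      stop("not a .raw file: first six columns must be ", paste(need, collapse = " "))
    snp_cols <- colnames(tab)[-(1:6)]
    vals <- as.matrix(tab[, -(1:6), drop = FALSE])
    .check_geno_tokens(vals, path)
    snp_ids <- sub("_[ACGT0-9]+$", "", snp_cols)
    G <- genotype_matrix(vals, snp_ids = snp_ids, sample_ids = tab$IID)
    attr(G, "phenotype") <- as.numeric(tab$PHENOTYPE)
    G
  } else {
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
    vals <- as.matrix(tab)
    .check_geno_tokens(vals, path)
    genotype_matrix(vals, snp_ids = colnames(tab))
  }
}

.check_geno_tokens <- function(vals, path) {
  bad <- !(is.na(vals) | vals == 0 | vals == 1 | vals == 2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: invalid genotype %s at data row %d, SNP column %d",
                 path, vals[bad][1L], idx[1L], idx[2L]))
  }
}

#' Write a genotype matrix (and phenotype) in PLINK .raw dialect
#'
#' @param G a `genotype_matrix`.
#' @param phenotype numeric vector written to the PHENOTYPE column; -9 when
#'   omitted.
#' @param path output path.
#' @param counted_allele suffix appended to SNP header names.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, phenotype = NULL, counted_allele = "A") {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$values)
  if (is.null(phenotype)) phenotype <- rep(-9, n)
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
              paste0(G$snp_ids, "_", counted_allele))
  lead <- cbind(G$sample_ids, G$sample_ids, "0", "0", "0",
                formatC(phenotype, format = "g", digits = 8))
  body <- cbind(lead, ifelse(is.na(G$values), "NA",
                             format(G$values, trim = TRUE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Quality-control filter for genotype matrices
#'
#' Applies, in order: call-rate filter (fraction of non-missing genotypes per
#' SNP), minor-allele-frequency filter (computed on non-missing genotypes,
#' after call-rate filtering), and a one-degree-of-freedom Pearson chi-square
#' test of Hardy-Weinberg equilibrium on the observed genotype counts.
#' Missing entries of the surviving SNPs are then mean-imputed (replaced by
#' the SNP's mean genotype, i.e. twice the allele frequency).
#'
#' @param G a `genotype_matrix` (missing entries `NA`).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param callrate_min minimum call rate (default 0.90).
#' @param hwe_p_min minimum HWE p-value (default 1e-5).
#' @return list with `genotypes` (filtered, imputed; values become numeric
#'   where imputation occurred) and `report` (a `qc_report`).
#' @export
qc_filter <- function(G, maf_min = 0.01, callrate_min = 0.90,
                      hwe_p_min = 1e-5) {
  stopifnot(inherits(G, "genotype_matrix"))
  vals <- G$values
  n <- nrow(vals); p0 <- ncol(vals)

  callrate <- colMeans(!is.na(vals))
  drop_cr <- callrate < callrate_min
  keep <- !drop_cr

  af <- colMeans(vals, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  drop_maf <- keep & (maf < maf_min)
  keep <- keep & !drop_maf

  hwe_p <- rep(NA_real_, p0)
  for (j in which(keep)) {
    x <- vals[, j]
    obs <- c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 2, na.rm = TRUE))
    m <- sum(obs)
    q <- (obs[2] + 2 * obs[3]) / (2 * m)  # frequency of the counted allele
    expd <- m * c((1 - q)^2, 2 * q * (1 - q), q^2)
    ok <- expd > 0
    hwe_p[j] <- stats::pchisq(sum((obs[ok] - expd[ok])^2 / expd[ok]),
                              df = 1, lower.tail = FALSE)
  }
  drop_hwe <- keep & !is.na(hwe_p) & (hwe_p < hwe_p_min)
  keep <- keep & !drop_hwe
  if (!any(keep)) stop("all SNPs removed by QC")

  out <- vals[, keep, drop = FALSE]
  n_imputed <- sum(is.na(out))
  if (n_imputed > 0) {
    storage.mode(out) <- "double"
    for (j in seq_len(ncol(out))) {
      miss <- is.na(out[, j])
      if (any(miss)) out[miss, j] <- mean(out[, j], na.rm = TRUE)
    }
  }
  Gout <- structure(list(values = out, snp_ids = G$snp_ids[keep],
                         positions = G$positions[keep],
                         sample_ids = G$sample_ids),
                    class = "genotype_matrix")
  report <- structure(list(n_snps_in = p0, n_removed_callrate = sum(drop_cr),
                           n_removed_maf = sum(drop_maf),
                           n_removed_hwe = sum(drop_hwe),
                           n_imputed_entries = n_imputed,
                           n_snps_out = sum(keep)),
                      class = "qc_report")
  list(genotypes = Gout, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d SNPs in, %d out\n",
                     "  removed: call rate %d, MAF %d, HWE %d\n",
                     "  imputed entries: %d\n"),
              x$n_snps_in, x$n_snps_out, x$n_removed_callrate,
              x$n_removed_maf, x$n_removed_hwe, x$n_imputed_entries))
  invisible(x)
}

#' Write a result table as TSV
#'
#' Deterministic column order, tab-delimited, header row, floats formatted
#' with `%.6g`.  Accepts a `selection_result`, a marker-scan data.frame, an
#' `evaluation_summary`, or any data.frame.
#'
#' @param result the object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  tab <- if (inherits(result, "selection_result")) {
    data.frame(index = result$selected, coefficient = result$coefficients,
               lambda_star = rep(result$lambda_star,
                                 length(result$selected)),
               criterion = rep(result$criterion, length(result$selected)),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(result)
  }
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(v) formatC(v, format = "g", digits = 6))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key:value run configuration
#'
#' One `key: value` pair per line; `#` starts a comment.  Recognized keys
#' (with defaults): seed (1), setting (high), p (5000), n (1000),
#' n_causal (25), alpha (1; comma-separated list allowed), k (10), K (100),
#' epsilon (0.001), criterion (1se), reps (1), fdr_threshold (0.2),
#' bonferroni_alpha (0.05).
#'
#' @param path config file path.
#' @return named list of validated values, class `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(lapply(kv, function(x)
    trimws(paste(x[-1], collapse = ":"))), trimws(vapply(kv, `[`, "", 1)))
  cfg <- list(seed = 1L, setting = "high", p = 5000L, n = 1000L,
              n_causal = 25L, alpha = 1, k = 10L, K = 100L, epsilon = 0.001,
              criterion = "1se", reps = 1L, fdr_threshold = 0.2,
              bonferroni_alpha = 0.05)
  for (key in names(vals)) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    v <- vals[[key]]
    cfg[[key]] <- switch(key,
      setting = , criterion = v,
      alpha = as.numeric(strsplit(v, ",")[[1]]),
      seed = , p = , n = , n_causal = , k = , K = , reps = as.integer(v),
      as.numeric(v))
  }
  if (any(cfg$alpha < 0 | cfg$alpha > 1)) stop("alpha must be in [0, 1]")
  if (!cfg$setting %in% c("high", "mixed", "low")) stop("unknown setting")
  if (!cfg$criterion %in% c("min", "1se")) stop("unknown criterion")
  if (cfg$epsilon <= 0 || cfg$epsilon >= 1) stop("epsilon must be in (0,1)")
  structure(cfg, class = "run_config")
}

#' Run the simulate / fit / select / score pipeline from a configuration
#'
#' For each replicate: simulate the configured LD setting, run 10-fold CV at
#' each configured alpha, select variables at the configured criterion and
#' score against the causal set.  Results are written as a TSV when `out` is
#' given.
#'
#' @param config a `run_config` (from [read_config()]) or a named list of
#'   overrides of the default configuration.
#' @param out optional output TSV path.
#' @return data.frame of per-replicate results, invisibly when `out` is
#'   given.
#' @export
run_pipeline <- function(config = list(), out = NULL) {
  if (!inherits(config, "run_config")) {
    base <- list(seed = 1L, setting = "high", p = 5000L, n = 1000L,
                 n_causal = 25L, alpha = 1, k = 10L, K = 100L,
                 epsilon = 0.001, criterion = "1se", reps = 1L,
                 fdr_threshold = 0.2, bonferroni_alpha = 0.05)
    unknown <- setdiff(names(config), names(base))
    if (length(unknown)) stop("unknown config key: ", unknown[1])
    base[names(config)] <- config
    config <- base
    if (any(config$alpha < 0 | config$alpha > 1))
      stop("alpha must be in [0, 1]")
  }
  message("run_pipeline config: ",
          paste(names(config), vapply(config, paste, "", collapse = ","),
                sep = "=", collapse = " "))
  sc <- solver_config(epsilon = config$epsilon, K = config$K)
  t_start <- proc.time()[3]
  summary <- replicate_table1(settings = config$setting,
                              alphas = config$alpha,
                              criteria = config$criterion,
                              n_reps = config$reps, p = config$p,
                              n_causal = config$n_causal, n = config$n,
                              k = config$k, seed = config$seed, config = sc)
  message(sprintf("run_pipeline: %d replicate fits in %.1f s (%d failed)",
                  nrow(attr(summary, "replicates")),
                  proc.time()[3] - t_start, attr(summary, "n_failed")))
  res <- attr(summary, "replicates")
  if (!is.null(out)) {
    write_selection(res, out)
    return(invisible(res))
  }
  res
}
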