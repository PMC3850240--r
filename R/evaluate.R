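#' Score a selection against the known causal set
#'
#' @param selected integer vector of selected column indices (or a
#'   `selection_result`).
#' @param causal causal set: integer vector or the `causal` data.frame from
#'   [make_setting()].
#' @return list with `n_correct` and `n_false_pos`;
#'   `n_correct + n_false_pos == length(selected)`.
#' @export
score_selection <- function(selected, causal) {
  if (inherits(selected, "selection_result")) selected <- selected$selected
  if (is.data.frame(causal)) causal <- causal$index
  selected <- unique(as.integer(selected))
  causal <- as.integer(causal)
  list(n_correct = sum(selected %in% causal),
       n_false_pos = sum(!selected %in% causal))
}

#' Replicate the selection-accuracy experiment grid
#'
#' Runs, for every combination of LD setting and penalty weight alpha, the
#' full pipeline over `n_reps` simulated replicates: simulate the data, fit
#' the elastic-net path, tune lambda by 10-fold CV, select variables at the
#' `min` and/or `1se` criterion, and score against the known causal set.
#' Summaries are the median and SD of the correct and false-positive counts
#' and the mean and SD of the CV MSE at the chosen lambda.
#'
#' @param settings character vector of LD settings to run.
#' @param alphas numeric vector of elastic-net penalty weights.
#' @param criteria subset of `c("min", "1se")`.
#' @param n_reps replicates per cell.
#' @param p number of SNPs per replicate.
#' @param n_causal number of causal SNPs.
#' @param n number of individuals.
#' @param k CV folds.
#' @param seed master seed; replicate r uses simulation seed `seed + r` and
#'   an independently derived fold seed.
#' @param config a [solver_config()].
#' @return object of class `evaluation_summary`: a data.frame with one row
#'   per (setting, alpha, criterion) and attribute `"replicates"` holding the
#'   per-replicate counts.
#' @export
replicate_table1 <- function(settings = c("high", "mixed", "low"),
                             alphas = c(1, 0.75, 0.5, 0.4, 0.3, 0.2, 0.15,
                                        0.1, 0.05, 0.01),
                             criteria = c("min", "1se"), n_reps = 100,
                             p = 5000, n_causal = 25, n = 1000, k = 10,
                             seed = 1L, config = solver_config()) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  reps <- list()
  failed <- 0L
  for (setting in settings) {
    for (r in seq_len(n_reps)) {
      sim_seed <- as.integer(seed) + r
      dat <- make_setting(setting, p = p, n_causal = n_causal,
                          seed = sim_seed, n = n)
      for (alpha in alphas) {
        res <- tryCatch({
          cv <- cv_path(dat$genotypes, dat$phenotype, alpha, k = k,
                        config = config,
                        seed = (sim_seed %% 10000000L) * 131L +
                          round(alpha * 100))  # stays below .Machine$integer.max
          lapply(criteria, function(cr) {
            sel <- select_variables(cv$fit, cv, cr)
            sc <- score_selection(sel, dat$causal)
            data.frame(setting = setting, alpha = alpha, criterion = cr,
                       rep = r, n_correct = sc$n_correct,
                       n_false_pos = sc$n_false_pos, cv_mse = sel$cv_mse,
                       stringsAsFactors = FALSE)
          })
        }, error = function(e) {
          warning(sprintf("replicate %d (%s, alpha=%g) failed: %s", r,
                          setting, alpha, conditionMessage(e)))
          NULL
        })
        if (is.null(res)) failed <- failed + 1L else reps <- c(reps, res)
      }
    }
  }
  per_rep <- do.call(rbind, reps)
  groups <- split(per_rep,
                  list(per_rep$setting, per_rep$alpha, per_rep$criterion),
                  drop = TRUE)
  summary <- do.call(rbind, lapply(groups, function(g) {
    data.frame(setting = g$setting[1], alpha = g$alpha[1],
               criterion = g$criterion[1],
               median_correct = stats::median(g$n_correct),
               sd_correct = stats::sd(g$n_correct),
               median_false_pos = stats::median(g$n_false_pos),
               sd_false_pos = stats::sd(g$n_false_pos),
               mean_mse = mean(g$cv_mse), sd_mse = stats::sd(g$cv_mse),
               n_reps = nrow(g), stringsAsFactors = FALSE)
  }))
  summary <- summary[order(match(summary$setting, settings),
                           match(summary$criterion, c("min", "1se")),
                           -summary$alpha), ]
  rownames(summary) <- NULL
  attr(summary, "replicates") <- per_rep
  attr(summary, "n_failed") <- failed
  class(summary) <- c("evaluation_summary", "data.frame")
  summary
}

#' Format an evaluation summary in the classic wide benchmark layout
#'
#' Rearranges an [replicate_table1()] summary into the familiar wide table:
#' one block per tuning criterion, rows (setting x statistic) with statistics
#' `Correct`, `False positive` and `MSE`, one column per penalty labelled
#' `Lasso`, `EN075`, ..., `EN001`, and cells formatted as `median (sd)`.
#'
#' @param summary an `evaluation_summary`.
#' @return data.frame of character cells with columns criterion, setting,
#'   statistic and one column per alpha.
#' @export
format_table1 <- function(summary) {
  stopifnot(inherits(summary, "evaluation_summary"))
  alphas <- sort(unique(summary$alpha), decreasing = TRUE)
  alpha_label <- function(a) {
    if (a == 1) "Lasso"
    else paste0("EN", sub("^0\\.", "0", formatC(a, format = "g")))
  }
  cell <- function(m, s) sprintf("%g (%.2f)", m, s)
  rows <- list()
  for (cr in intersect(c("min", "1se"), summary$criterion)) {
    for (st in unique(summary$setting)) {
      sub <- summary[summary$criterion == cr & summary$setting == st, ]
      sub <- sub[match(alphas, sub$alpha), ]
      block <- data.frame(
        criterion = if (cr == "min") "minMSE" else "minMSE + 1SE",
        setting = paste(c(high = "High", mixed = "Mixed",
                          low = "Low")[st], "LD"),
        statistic = c("Correct", "False positive", "MSE"),
        stringsAsFactors = FALSE)
      vals <- rbind(cell(sub$median_correct, sub$sd_correct),
                    cell(sub$median_false_pos, sub$sd_false_pos),
                    sprintf("%.2f (%.2f)", sub$mean_mse, sub$sd_mse))
      colnames(vals) <- vapply(alphas, alpha_label, "")
      rows[[length(rows) + 1L]] <- cbind(block, vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap counts for up to three selection sets
#'
#' Exact cardinalities for every intersection region of the named sets, the
#' numbers behind a Venn diagram of markers selected by different methods.
#'
#' @param sets named list of 2 or 3 integer vectors.
#' @return named integer vector of region cardinalities; for two sets the
#'   regions are `"A.only"`, `"B.only"`, `"A.B"` (with A, B replaced by the
#'   set names), analogously for three.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3)
    stop("overlap_counts supports 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, function(s) unique(as.integer(s)))
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0)
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))[-2^length(sets), , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1, function(pt) {
    sum(apply(member, 1, function(m) all(m == pt)))
  })
  labels <- apply(patterns, 1, function(pt) {
    paste(names(sets)[as.logical(pt)], collapse = ".")
  })
  labels[rowSums(patterns) == 1] <-
    paste0(labels[rowSums(patterns) == 1], ".only")
  stats::setNames(as.integer(counts), labels)
}
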