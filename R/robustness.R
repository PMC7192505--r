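#' Random-response null distribution of the AUC
#'
#' Each draw scores the true responder labels against an i.i.d.
#' Bernoulli(1/2) binary vector (ties counted 1/2), emulating pure random
#' guessing at the cohort's size; with `generator = "permutation"` the true
#' label vector is permuted instead.
#'
#' @param labels 0/1 responder vector of the cohort.
#' @param n_draws number of random vectors (10,000 in a full-scale run).
#' @param seed RNG seed.
#' @param generator `"random_binary"` (default) or `"permutation"`.
#' @return a `null_distribution` with the AUC draws.
#' @export
random_response_null <- function(labels, n_draws = 10000L, seed = 1L,
                                 generator = c("random_binary",
                                               "permutation")) {
  generator <- match.arg(generator)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  n <- length(labels)
  draws <- vapply(seq_len(n_draws), function(i) {
    scores <- if (generator == "random_binary")
      stats::rbinom(n, 1, 0.5) else sample(labels)
    roc_auc(scores, labels)
  }, numeric(1))
  structure(list(draws = draws, generator = generator,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "null_distribution")
}

#' @exportS3Method base::print
print.null_distribution <- function(x, ...) {
  cat("null_distribution (", x$generator, "): ", x$n_draws,
      " draws, mean AUC ", round(mean(x$draws), 3), "\n", sep = "")
  invisible(x)
}

#' Gene-label permutation null
#'
#' For each permutation the cohort's gene ids are shuffled (values
#' untouched) and every pipeline re-runs its full test-side processing on
#' the relabeled patient object; the resulting AUCs form a per-pipeline
#' null distribution.
#'
#' @param configs data.frame of pipeline configurations.
#' @param screen a [cell_screen]; `cohort` a [patient_cohort].
#' @param cohort the evaluation cohort.
#' @param n_perm permutations (1,000 in a full-scale run).
#' @param seed RNG seed.
#' @param control a [black_box_control()].
#' @return matrix of AUCs, `n_perm` rows x one column per pipeline.
#' @export
permuted_gene_null <- function(configs, screen, cohort, n_perm = 1000L,
                               seed = 1L, control = black_box_control()) {
  set.seed(seed)
  genes <- rownames(cohort$expression)
  out <- matrix(NA_real_, n_perm, nrow(configs),
                dimnames = list(NULL, pipeline_id(configs)))
  for (p in seq_len(n_perm)) {
    shuffled <- cohort$expression
    rownames(shuffled) <- sample(genes)
    perm_cohort <- patient_cohort(shuffled, cohort$response,
                                  cohort$raw_labels,
                                  cohort$survival_months)
    for (i in seq_len(nrow(configs)))
      out[p, i] <- run_pipeline(configs[i, ], screen, perm_cohort,
                                control)$auc_roc
  }
  out
}

#' Draw a seeded random sample of pipeline configurations
#'
#' @param grid data.frame from [enumerate_grid()].
#' @param n sample size (100 in a full-scale specificity run).
#' @param seed RNG seed.
#' @return data.frame subset, without replacement.
#' @export
sample_configs <- function(grid, n = 100L, seed = 1L) {
  set.seed(seed)
  grid[sort(sample(nrow(grid), min(n, nrow(grid)))), , drop = FALSE]
}

#' Drug-specificity ranking
#'
#' Trains the sampled pipelines on each drug of a multi-drug screen in
#' turn, evaluates them on the cohort, and ranks the drugs by their mean
#' AUC (rank 1 = best, ties averaged). A drug-specific signal should put
#' the administered drug near rank 1; with a purely shared sensitivity
#' factor all drugs are informationally equivalent and the administered
#' drug's rank scatters.
#'
#' @param sampled_configs data.frame of pipeline configurations (the
#'   `drug` column is overridden per drug).
#' @param screen multi-drug [cell_screen].
#' @param cohort a [patient_cohort].
#' @param administered_drug drug actually given to the cohort.
#' @param min_responses drugs with fewer non-missing responses are skipped
#'   with a warning.
#' @param control a [black_box_control()].
#' @return list with `drug_mean_auc`, `ranks` and `administered_rank`.
#' @export
drug_specificity_scan <- function(sampled_configs, screen, cohort,
                                  administered_drug,
                                  min_responses = 10L,
                                  control = black_box_control()) {
  drugs <- rownames(screen$response)
  if (length(drugs) < 2) stop("need a multi-drug screen")
  n_resp <- rowSums(!is.na(screen$response))
  usable <- drugs[n_resp >= min_responses]
  if (length(usable) < length(drugs))
    warning("skipped drug(s) with < ", min_responses, " responses: ",
            paste(setdiff(drugs, usable), collapse = ", "))
  mean_auc <- vapply(usable, function(d) {
    cfgs <- sampled_configs
    cfgs$drug <- d
    sc <- run_scan(cfgs, screen, cohort, dataset_id = d)
    mean(sc$results$auc_roc, na.rm = TRUE)
  }, numeric(1))
  ranks <- assign_ranks(mean_auc)
  list(drug_mean_auc = mean_auc, ranks = ranks,
       administered_rank = unname(ranks[administered_drug]))
}

#' Hypergeometric enrichment of stage options among the top pipelines
#'
#' The top set is the best `ceiling(top_frac * N)` pipelines by AUC (ties
#' by average rank, then stable order). For every option of every stage
#' with `K` occurrences in the universe of `N` scanned pipelines and `x`
#' occurrences among the top `n`, the one-sided hypergeometric p-value
#' `P(X >= x)` is reported, flagged significant at `alpha`, together with
#' the option's mean AUC.
#'
#' @param scan a `scan_result` (or its `results` data.frame).
#' @param top_frac top fraction (default 5%).
#' @param alpha significance level (default 0.01).
#' @return data.frame, one row per (stage, option).
#' @export
setting_enrichment <- function(scan, top_frac = 0.05, alpha = 0.01) {
  results <- if (inherits(scan, "scan_result")) scan$results else scan
  results <- results[!is.na(results$auc_roc), , drop = FALSE]
  N <- nrow(results)
  if (N < 1 / top_frac) stop("scan too small for the requested fraction")
  n_top <- ceiling(top_frac * N)
  top_idx <- order(-results$auc_roc)[seq_len(n_top)]  # stable on ties
  stages <- c("response_transform", "homogenization", "feature_filter",
              "feature_preprocess", "black_box")
  rows <- list()
  for (st in stages) {
    for (opt in unique(results[[st]])) {
      in_opt <- results[[st]] == opt
      K <- sum(in_opt)
      x <- sum(in_opt[top_idx])
      p <- stats::phyper(x - 1, K, N - K, n_top, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        stage = st, option = opt, count_top = x, count_universe = K,
        mean_auc = mean(results$auc_roc[in_opt]), p_value = p,
        significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
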