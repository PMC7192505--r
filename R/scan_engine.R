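#' Stage option lists of the default pipeline grid
#'
#' Five cell-response transforms x seven homogenization methods x four
#' feature filters x four feature preprocessors x seven black boxes =
#' 3,920 pipelines.
#'
#' @name stage_options
#' @export
RESPONSE_TRANSFORMS <- c("none", "logarithm", "powertransform",
                         "binarization_cutoff", "binarization_kmeans")
#' @rdname stage_options
#' @export
HOMOGENIZATIONS <- c("none", "quantile", "combat", "limma", "ruv4", "ruv",
                     "yugene")
#' @rdname stage_options
#' @export
FEATURE_FILTERS <- c("all", "landmarkgenes", "variance", "pvalue")
#' @rdname stage_options
#' @export
FEATURE_PREPROCESSES <- c("none", "zscore_samplewise", "zscore_genewise",
                          "pca")

#' Enumerate the pipeline grid
#'
#' Full Cartesian product of the stage option lists, in deterministic
#' lexicographic order (last stage varies fastest). The defaults reproduce
#' the 3,920-pipeline grid; fixing the filter to landmark genes, the
#' preprocessing to PCA and the black box to linear regression leaves the
#' 35 guideline pipelines.
#'
#' @param drug drug name attached to every configuration.
#' @param response_transforms,homogenizations,feature_filters,feature_preprocesses,black_boxes
#'   per-stage option lists.
#' @param seed base seed stored with the grid.
#' @return data.frame with one row per pipeline configuration and a
#'   `pipeline_id` column.
#' @export
enumerate_grid <- function(drug = "drug01",
                           response_transforms = RESPONSE_TRANSFORMS,
                           homogenizations = HOMOGENIZATIONS,
                           feature_filters = FEATURE_FILTERS,
                           feature_preprocesses = FEATURE_PREPROCESSES,
                           black_boxes = BLACK_BOXES,
                           seed = 1L) {
  stages <- list(response_transform = response_transforms,
                 homogenization = homogenizations,
                 feature_filter = feature_filters,
                 feature_preprocess = feature_preprocesses,
                 black_box = black_boxes)
  for (s in names(stages))
    if (length(stages[[s]]) == 0) stop("empty option list for ", s)
  grid <- expand.grid(rev(stages), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(names(grid))]
  grid <- data.frame(drug = drug, grid, seed = as.integer(seed),
                     stringsAsFactors = FALSE)
  grid$pipeline_id <- pipeline_id(grid)
  rownames(grid) <- NULL
  grid
}

#' Stable identifier of a pipeline's stage choices (drug excluded)
#' @param config one-or-more-row data.frame of pipeline configurations.
#' @return character vector of ids.
#' @export
pipeline_id <- function(config) {
  paste(config$response_transform, config$homogenization,
        config$feature_filter, config$feature_preprocess,
        config$black_box, sep = "|")
}

# deterministic per-pipeline seed derived from the base seed and the stage
# choices (order- and worker-invariant); kept below 2^31
derive_seed <- function(config, base_seed) {
  s <- paste(config$drug, pipeline_id(config))
  h <- sum(utf8ToInt(s) * seq_along(utf8ToInt(s)) * 131) %% 2147483647
  as.integer((h + as.numeric(base_seed) * 7919) %% 2147483647)
}

# stages 1-7: everything deterministic that precedes model fitting.
# Cacheable across black boxes because no RNG is consumed here.
prepare_pipeline_data <- function(config, screen, cohort) {
  drug <- config$drug
  if (!drug %in% rownames(screen$response))
    stop("drug '", drug, "' not in the screen response table")
  y <- screen$response[drug, ]
  y <- y[!is.na(y)]
  if (length(y) < 2) stop("fewer than 2 screened cell lines for ", drug)
  train <- screen$expression[, names(y), drop = FALSE]
  test <- cohort$expression

  dedup <- remove_duplicate_genes(train, test)
  shared <- intersect_features(dedup$train, dedup$test)
  train <- dedup$train[shared, , drop = FALSE]
  test <- dedup$test[shared, , drop = FALSE]

  target <- transform_response(y, config$response_transform)

  hspec <- homogenization_spec(
    config$homogenization,
    control_genes = intersect(screen$housekeeping_genes, shared),
    yugene_shift = TRUE)   # simulated log-expression is unbounded below
  hom <- homogenize(train, test, hspec)

  fspec <- feature_spec(filter = config$feature_filter,
                        preprocess = config$feature_preprocess,
                        landmark_list = screen$landmark_genes)
  keep <- filter_features(hom$train, hom$test, response = target,
                          spec = fspec)
  feats <- preprocess_features(hom$train[keep, , drop = FALSE],
                               hom$test[keep, , drop = FALSE], fspec)
  list(x_train = feats$train, x_test = feats$test, target = target)
}

#' Execute one translational modeling pipeline
#'
#' Runs the stages in their fixed order — select screened cell lines,
#' remove duplicated gene names, intersect features, transform the cell
#' response, homogenize train and test expression, filter and preprocess
#' features, fit the black box, predict the cohort, orient the scores —
#' and evaluates responder discrimination. Stage errors are captured into
#' the result, never raised out of a scan.
#'
#' @param config one-row data.frame (or list) with fields `drug`,
#'   `response_transform`, `homogenization`, `feature_filter`,
#'   `feature_preprocess`, `black_box`, `seed`.
#' @param screen a [cell_screen].
#' @param cohort a [patient_cohort].
#' @param control a [black_box_control()].
#' @param prepared optional precomputed output of the deterministic
#'   preparation stages (internal, used by [run_scan()] memoization).
#' @return a `pipeline_result` list with `auc_roc`, `auc_pr`,
#'   `separation_p`, oriented `predictions` and a `failure` reason (or
#'   `NA`).
#' @export
run_pipeline <- function(config, screen, cohort,
                         control = black_box_control(),
                         prepared = NULL) {
  res <- list(config = as.list(config), auc_roc = NA_real_,
              auc_pr = NA_real_, separation_p = NA_real_,
              predictions = NULL, failure = NA_character_)
  class(res) <- "pipeline_result"
  out <- try({
    if (is.null(prepared))
      prepared <- prepare_pipeline_data(config, screen, cohort)
    seed_i <- derive_seed(config, config$seed)
    model <- suppressWarnings(
      fit_black_box(prepared$x_train, prepared$target, config$black_box,
                    seed = seed_i, control = control))
    raw <- predict_black_box(model, prepared$x_test)
    oriented <- orient_scores(raw, model$target_orientation)
    labels <- cohort$response[names(oriented)]
    res$predictions <- oriented
    res$auc_roc <- roc_auc(oriented, labels)
    res$auc_pr <- pr_auc(oriented, labels)
    res$separation_p <- separation_ttest(oriented, labels)
    NULL
  }, silent = TRUE)
  if (inherits(out, "try-error"))
    res$failure <- conditionMessage(attr(out, "condition"))
  res
}

result_row <- function(r) {
  data.frame(drug = r$config$drug,
             response_transform = r$config$response_transform,
             homogenization = r$config$homogenization,
             feature_filter = r$config$feature_filter,
             feature_preprocess = r$config$feature_preprocess,
             black_box = r$config$black_box,
             pipeline_id = pipeline_id(r$config),
             auc_roc = r$auc_roc, auc_pr = r$auc_pr,
             separation_p = r$separation_p, failure = r$failure,
             stringsAsFactors = FALSE)
}

#' Scan a set of pipeline configurations
#'
#' Results are independent of configuration order and worker count: every
#' pipeline derives its own seed from its stage choices. With one worker,
#' the deterministic preparation stages (everything before model fitting)
#' are memoized across pipelines that share them.
#'
#' @param configs data.frame from [enumerate_grid()] (possibly subset).
#' @param screen a [cell_screen]; `cohort` a [patient_cohort].
#' @param cohort the evaluation cohort.
#' @param n_workers parallel workers (forked; 1 = serial with memoization).
#' @param control a [black_box_control()].
#' @param scenario label stored with the result.
#' @param dataset_id label stored with the result.
#' @return a `scan_result`: list with the per-pipeline `results`
#'   data.frame (one row per configured pipeline, failures carried with a
#'   reason), `scenario`, `dataset_id` and a `summary` (median and best).
#' @export
run_scan <- function(configs, screen, cohort, n_workers = 1L,
                     control = black_box_control(),
                     scenario = "cell2patient", dataset_id = "dataset") {
  if (nrow(configs) == 0) {
    empty <- result_row(run_pipeline(
      enumerate_grid()[1, ], screen, cohort, control))[0, ]
    return(structure(list(results = empty, scenario = scenario,
                          dataset_id = dataset_id,
                          summary = list(median_auc = NA_real_,
                                         best = NULL)),
                     class = "scan_result"))
  }
  run_one <- local({
    cache <- new.env(parent = emptyenv())
    function(i) {
      cfg <- configs[i, ]
      key <- paste(cfg$drug, cfg$response_transform, cfg$homogenization,
                   cfg$feature_filter, cfg$feature_preprocess)
      prepared <- cache[[key]]
      if (is.null(prepared)) {
        prepared <- try(prepare_pipeline_data(cfg, screen, cohort),
                        silent = TRUE)
        cache[[key]] <- prepared
      }
      if (inherits(prepared, "try-error")) {
        r <- list(config = as.list(cfg), auc_roc = NA_real_,
                  auc_pr = NA_real_, separation_p = NA_real_,
                  predictions = NULL,
                  failure = conditionMessage(attr(prepared, "condition")))
        class(r) <- "pipeline_result"
        return(result_row(r))
      }
      result_row(run_pipeline(cfg, screen, cohort, control,
                              prepared = prepared))
    }
  })
  rows <- if (n_workers > 1) {
    parallel::mclapply(seq_len(nrow(configs)), run_one,
                       mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(configs)), run_one)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- !is.na(results$auc_roc)
  best <- if (any(ok)) results[ok, ][which.max(results$auc_roc[ok]), ]
          else NULL
  structure(list(results = results, scenario = scenario,
                 dataset_id = dataset_id,
                 summary = list(median_auc = stats::median(results$auc_roc,
                                                           na.rm = TRUE),
                                best = best)),
            class = "scan_result")
}

#' @exportS3Method base::print
print.scan_result <- function(x, ...) {
  cat("scan_result (", x$scenario, ", ", x$dataset_id, "): ",
      nrow(x$results), " pipelines, median AUC ",
      round(x$summary$median_auc, 3), "\n", sep = "")
  invisible(x)
}

# binarize a held-out continuous truth per the pipeline's own rule:
# the configured binarization, or a median split for continuous targets
binarize_heldout <- function(y, response_transform) {
  tr <- switch(response_transform,
               binarization_cutoff = transform_binarize_cutoff(y),
               binarization_kmeans = transform_binarize_kmeans(y),
               transform_binarize_cutoff(y))
  tr$values
}

#' In-vitro (cell-to-cell) cross-validated baseline
#'
#' Cell lines with a measured response are split into `k` seeded folds;
#' each fold in turn is treated as the test cohort, its continuous truth
#' binarized (1 = sensitive) by the configuration's binarization method, or
#' at the median for continuous targets, and the fold AUC computed from
#' the oriented predictions. Folds collapsing to a single class are
#' skipped with a warning.
#'
#' @param config one-row pipeline configuration.
#' @param screen a [cell_screen].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param control a [black_box_control()].
#' @return mean AUC over valid folds (attribute `fold_aucs`).
#' @export
crossvalidate_cell2cell <- function(config, screen, k = 5L, seed = 1L,
                                    control = black_box_control()) {
  y <- screen$response[config$drug, ]
  y <- y[!is.na(y)]
  if (length(y) < k) stop("fewer cell lines than folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(y)))
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test_cells <- names(y)[fold == f]
    train_cells <- names(y)[fold != f]
    truth <- binarize_heldout(y[test_cells], config$response_transform)
    if (length(unique(truth)) < 2) {
      warning("fold ", f, " has a single class; skipped")
      next
    }
    sub_screen <- cell_screen(
      screen$expression[, train_cells, drop = FALSE],
      screen$response[config$drug, train_cells, drop = FALSE],
      screen$tissues[train_cells],
      landmark_genes = screen$landmark_genes,
      housekeeping_genes = screen$housekeeping_genes)
    pseudo <- patient_cohort(
      screen$expression[, test_cells, drop = FALSE], truth)
    r <- run_pipeline(config, sub_screen, pseudo, control)
    aucs[f] <- r$auc_roc
  }
  if (all(is.na(aucs))) stop("no valid folds")
  structure(mean(aucs, na.rm = TRUE), fold_aucs = aucs)
}

#' Train/validation/test transfer experiment
#'
#' Splits the screened cell lines into three parts. Every pipeline is
#' trained on the training split and scored on the validation split; the
#' `n_top` pipelines by validation AUC are compared (two-sided t-tests)
#' with the full set on the held-out in-vitro test split and on the
#' patient cohort.
#'
#' @param configs data.frame of pipeline configurations (`>= n_top` rows).
#' @param screen a [cell_screen]; `cohort` a [patient_cohort].
#' @param cohort the translational evaluation cohort.
#' @param n_top size of the selected subset (300 in a full-scale run).
#' @param proportions train/validation/test fractions (default 60/20/20).
#' @param seed split seed.
#' @param control a [black_box_control()].
#' @param n_workers parallel workers for the three surface scans.
#' @return list with the per-pipeline surface AUCs (`results`), the ids of
#'   the selected subset, and `p_validation`, `p_test`, `p_cohort`.
#' @export
transfer_experiment <- function(configs, screen, cohort, n_top = 300L,
                                proportions = c(0.6, 0.2, 0.2),
                                seed = 1L,
                                control = black_box_control(),
                                n_workers = 1L) {
  if (nrow(configs) < n_top) stop("need at least n_top configurations")
  drug <- configs$drug[1]
  y <- screen$response[drug, ]
  cells <- names(y)[!is.na(y)]
  set.seed(seed)
  part <- sample(cut(seq_along(cells), ceiling(length(cells) *
                                                 cumsum(c(0, proportions))),
                     labels = c("train", "validation", "test")))
  if (min(table(part)) < 5) stop("split too small")
  split_cells <- split(cells, part)

  sub_screen <- cell_screen(
    screen$expression[, split_cells$train, drop = FALSE],
    screen$response[drug, split_cells$train, drop = FALSE],
    screen$tissues[split_cells$train],
    landmark_genes = screen$landmark_genes,
    housekeeping_genes = screen$housekeeping_genes)
  pseudo_cohort <- function(cells_in) {
    truth_all <- lapply(unique(configs$response_transform), function(tr)
      binarize_heldout(y[cells_in], tr))
    names(truth_all) <- unique(configs$response_transform)
    list(expr = screen$expression[, cells_in, drop = FALSE],
         truth = truth_all)
  }
  surface_auc <- function(cells_in) {
    ps <- pseudo_cohort(cells_in)
    vapply(seq_len(nrow(configs)), function(i) {
      cfg <- configs[i, ]
      truth <- ps$truth[[cfg$response_transform]]
      if (length(unique(truth)) < 2) return(NA_real_)
      run_pipeline(cfg, sub_screen,
                   patient_cohort(ps$expr, truth), control)$auc_roc
    }, numeric(1))
  }
  auc_val <- surface_auc(split_cells$validation)
  auc_test <- surface_auc(split_cells$test)
  cohort_scan <- run_scan(configs, sub_screen, cohort,
                          n_workers = n_workers, control = control)
  auc_cohort <- cohort_scan$results$auc_roc

  top_idx <- order(-auc_val)[seq_len(n_top)]
  pcomp <- function(a) {
    if (n_top == length(a)) return(1)
    tryCatch(stats::t.test(a[top_idx], a)$p.value, error = function(e) NA)
  }
  list(results = data.frame(pipeline_id = pipeline_id(configs),
                            auc_validation = auc_val, auc_test = auc_test,
                            auc_cohort = auc_cohort,
                            stringsAsFactors = FALSE),
       top_ids = pipeline_id(configs)[top_idx],
       p_validation = pcomp(auc_val),
       p_test = pcomp(auc_test),
       p_cohort = pcomp(auc_cohort))
}
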