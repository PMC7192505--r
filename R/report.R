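#' Summary tables across one or more scans
#'
#' Builds the standard result views over a list of `scan_result`s sharing
#' one pipeline universe: the best pipeline per dataset (with AUC-ROC,
#' AUC-PR and separation p-value), the cross-dataset performance and rank
#' matrices of those best pipelines, the Pearson correlation matrix of the
#' full performance vectors, and the per-setting mean-AUC table with
#' enrichment flags.
#'
#' @param scans named list of `scan_result` objects.
#' @param top_frac,alpha forwarded to [setting_enrichment()].
#' @return list of data.frames / matrices: `best_per_dataset`,
#'   `cross_auc`, `cross_rank`, `correlation`, `setting_summary`.
#' @export
make_report <- function(scans, top_frac = 0.05, alpha = 0.01) {
  if (length(scans) < 1) stop("need at least one scan result")
  if (is.null(names(scans)))
    names(scans) <- vapply(scans, function(s) s$dataset_id, character(1))
  ids <- lapply(scans, function(s) s$results$pipeline_id)
  if (length(unique(lapply(ids, sort))) != 1)
    stop("scan results cover different pipeline universes")

  best <- do.call(rbind, lapply(names(scans), function(nm) {
    b <- scans[[nm]]$summary$best
    if (is.null(b)) return(NULL)
    data.frame(dataset = nm, b, stringsAsFactors = FALSE)
  }))

  # best pipeline of each dataset evaluated in every dataset
  best_ids <- best$pipeline_id
  cross_auc <- matrix(NA_real_, length(best_ids), length(scans),
                      dimnames = list(paste(best$dataset, best_ids),
                                      names(scans)))
  cross_rank <- cross_auc
  for (j in names(scans)) {
    res <- scans[[j]]$results
    ranks <- assign_ranks(stats::setNames(res$auc_roc, res$pipeline_id))
    aucs <- stats::setNames(res$auc_roc, res$pipeline_id)
    cross_auc[, j] <- aucs[best_ids]
    cross_rank[, j] <- ranks[best_ids]
  }

  correlation <- if (length(scans) >= 2) {
    performance_correlation(lapply(scans, function(s)
      stats::setNames(s$results$auc_roc, s$results$pipeline_id)))
  } else matrix(1, 1, 1, dimnames = list(names(scans), names(scans)))

  setting_summary <- do.call(rbind, lapply(names(scans), function(nm)
    data.frame(dataset = nm,
               setting_enrichment(scans[[nm]], top_frac, alpha),
               stringsAsFactors = FALSE)))

  list(best_per_dataset = best, cross_auc = cross_auc,
       cross_rank = cross_rank, correlation = correlation,
       setting_summary = setting_summary)
}

#' Run a scenario described by a configuration file
#'
#' The configuration (YAML or JSON) names a scenario — `simulate`, `scan`,
#' `cv`, `transfer`, `robustness` or `report` — together with its
#' parameters and an output directory. Artifacts (results TSV and a run
#' metadata JSON with the configuration and seed) are written there;
#' identical configuration + seed reproduces identical artifacts.
#'
#' @param config_path path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return invisibly, the list of written artifact paths.
#' @export
run_from_config <- function(config_path) {
  if (!file.exists(config_path)) stop("config file not found: ",
                                      config_path)
  cfg <- if (grepl("[.]ya?ml$", config_path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(config_path)
  } else jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (field in c("scenario", "output_dir", "seed"))
    if (is.null(cfg[[field]])) stop("config missing field: ", field)
  if (!cfg$scenario %in% c("simulate", "scan"))
    stop("unsupported scenario: ", cfg$scenario)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- cfg$simulation
  params <- do.call(simulation_params,
                    c(sim_args, list(seed = cfg$seed)))
  sim <- generate_paired_datasets(params)
  paths <- character()
  write_artifact <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (cfg$scenario == "simulate") {
    write_expression_matrix(sim$screen$expression,
                            file.path(cfg$output_dir, "train_expr.tsv"))
    write_expression_matrix(sim$cohort$expression,
                            file.path(cfg$output_dir, "test_expr.tsv"))
    paths <- c(paths, file.path(cfg$output_dir,
                                c("train_expr.tsv", "test_expr.tsv")))
  } else {
    grid <- do.call(enumerate_grid,
                    c(list(drug = rownames(sim$screen$response)[1],
                           seed = cfg$seed),
                      cfg$grid))
    ctl <- do.call(black_box_control,
                   if (is.null(cfg$control)) list() else cfg$control)
    sc <- run_scan(grid, sim$screen, sim$cohort,
                   n_workers = if (is.null(cfg$n_workers)) 1L
                               else cfg$n_workers,
                   control = ctl)
    write_artifact(sc$results, "scan_results.tsv")
  }
  meta <- file.path(cfg$output_dir, "run_metadata.json")
  jsonlite::write_json(list(config = cfg, seed = cfg$seed,
                            package_version =
                              as.character(utils::packageVersion("tmscan"))),
                       meta, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, meta)
  invisible(paths)
}
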