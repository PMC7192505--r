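#' Parameters for the paired cell-screen / patient-cohort simulator
#'
#' The generator emulates the statistical structure of a translational
#' drug-response setting: a cell-line training screen and a patient test
#' cohort share a gene universe, a subset of signal genes links expression
#' to a latent drug sensitivity, housekeeping genes carry only batch
#' variation, and the patient side is displaced by per-gene additive and
#' multiplicative batch offsets (the train-vs-test distribution shift that
#' homogenization methods must remove).
#'
#' @param n_genes total number of distinct gene ids.
#' @param n_signal_genes genes with non-zero response weight.
#' @param n_housekeeping negative-control genes (zero weight, batch only).
#' @param n_landmark size of the landmark subset.
#' @param landmark_signal_fraction share of the landmark set drawn from the
#'   signal genes (controls how informative the landmark filter is).
#' @param n_cell_lines,n_patients sample sizes; cohorts of 24-169 patients
#'   are the realistic clinical range.
#' @param effect_size total latent-signal scale: per-signal-gene slopes are
#'   `effect_size/sqrt(n_signal_genes)` in magnitude so the latent
#'   sensitivity has variance `effect_size^2` regardless of the gene budget.
#' @param batch_shift_sd sd of the per-gene additive train-vs-patient offset.
#' @param batch_scale_sd sd (log scale) of the per-gene multiplicative
#'   offset applied to patient expression variation.
#' @param noise_sd sd of the measurement noise on ln(IC50).
#' @param n_drugs number of drugs in the screen.
#' @param shared_fraction weight of the drug-unspecific general-sensitivity
#'   factor versus drug-specific factors, in \[0, 1\].
#' @param responder_fraction target fraction of responders in the cohort.
#' @param duplicate_gene_fraction fraction of gene ids repeated (as extra
#'   rows) to exercise duplication handling.
#' @param seed integer RNG seed; everything downstream is reproducible
#'   from it.
#' @return a validated `simulation_params` list.
#' @export
simulation_params <- function(n_genes = 1000, n_signal_genes = 50,
                              n_housekeeping = 100, n_landmark = 100,
                              landmark_signal_fraction = 0.5,
                              n_cell_lines = 150, n_patients = 30,
                              effect_size = 1, batch_shift_sd = 1,
                              batch_scale_sd = 0.1, noise_sd = 0.5,
                              n_drugs = 1, shared_fraction = 0.5,
                              responder_fraction = 0.45,
                              duplicate_gene_fraction = 0.05,
                              seed = 1L) {
  p <- list(n_genes = n_genes, n_signal_genes = n_signal_genes,
            n_housekeeping = n_housekeeping, n_landmark = n_landmark,
            landmark_signal_fraction = landmark_signal_fraction,
            n_cell_lines = n_cell_lines, n_patients = n_patients,
            effect_size = effect_size, batch_shift_sd = batch_shift_sd,
            batch_scale_sd = batch_scale_sd, noise_sd = noise_sd,
            n_drugs = n_drugs, shared_fraction = shared_fraction,
            responder_fraction = responder_fraction,
            duplicate_gene_fraction = duplicate_gene_fraction,
            seed = as.integer(seed))
  if (p$n_signal_genes + p$n_housekeeping > p$n_genes)
    stop("infeasible gene budget: n_signal_genes + n_housekeeping > n_genes")
  if (p$n_landmark > p$n_genes) stop("n_landmark exceeds n_genes")
  if (p$shared_fraction < 0 || p$shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  if (any(c(p$batch_shift_sd, p$batch_scale_sd, p$noise_sd) < 0))
    stop("sd parameters must be >= 0")
  if (p$responder_fraction <= 0 || p$responder_fraction >= 1)
    stop("responder_fraction must be in (0, 1)")
  class(p) <- "simulation_params"
  p
}

#' Generate a paired cell screen and patient cohort with known ground truth
#'
#' Cell-line expression is Gaussian per gene around a gene-level baseline.
#' A latent sensitivity \eqn{s = \sum_g \beta_g (x_g - \mu_g)} over the
#' signal genes drives the response: per drug,
#' \eqn{ln(IC50) = a_d - (f s + (1-f) s_d) + \epsilon} with a shared
#' general-sensitivity factor (weight `shared_fraction` = f) and a
#' drug-specific factor. Lower ln(IC50) means more sensitive. Patient
#' expression is the same baseline plus per-gene additive and multiplicative
#' batch offsets; patients whose (pre-batch) latent sensitivity lies above
#' the `1 - responder_fraction` quantile are responders.
#'
#' The cohort is treated with the screen's first drug, so its latent
#' sensitivity mixes the shared and that drug's specific factor with the
#' same weights as the in-vitro response.
#'
#' @param params a [simulation_params()] object.
#' @return list with elements `screen` ([cell_screen]), `cohort`
#'   ([patient_cohort]) and `truth` (signal gene ids, per-drug weights,
#'   the cohort's effective weights, latent patient scores, batch
#'   offsets, gene baselines).
#' @export
generate_paired_datasets <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)
  genes <- sprintf("g%04d", seq_len(p$n_genes))
  cells <- sprintf("cl%03d", seq_len(p$n_cell_lines))
  patients <- sprintf("pt%03d", seq_len(p$n_patients))

  roles <- sample(genes)
  signal <- roles[seq_len(p$n_signal_genes)]
  housekeeping <- roles[p$n_signal_genes + seq_len(p$n_housekeeping)]
  free <- roles[-seq_len(p$n_signal_genes + p$n_housekeeping)]

  n_lm_sig <- min(round(p$landmark_signal_fraction * p$n_landmark),
                  p$n_signal_genes)
  landmark <- c(sample(signal, n_lm_sig),
                sample(free, min(p$n_landmark - n_lm_sig, length(free))))

  mu <- stats::setNames(stats::rnorm(p$n_genes, 7, 1.5), genes)

  # per-signal-gene slopes: +/- effect_size / sqrt(n_signal)
  beta <- stats::setNames(numeric(p$n_genes), genes)
  if (p$n_signal_genes > 0)
    beta[signal] <- sample(c(-1, 1), p$n_signal_genes, replace = TRUE) *
      p$effect_size / sqrt(p$n_signal_genes)

  expr_train <- matrix(stats::rnorm(p$n_genes * p$n_cell_lines), p$n_genes,
                       dimnames = list(genes, cells)) + mu
  s_cell <- drop(crossprod(expr_train - mu, beta))   # latent sensitivity

  drugs <- sprintf("drug%02d", seq_len(p$n_drugs))
  drug_beta <- matrix(0, p$n_genes, p$n_drugs,
                      dimnames = list(genes, drugs))
  if (p$n_signal_genes > 0)
    drug_beta[signal, ] <- matrix(
      stats::rnorm(p$n_signal_genes * p$n_drugs,
                   sd = p$effect_size / sqrt(p$n_signal_genes)),
      p$n_signal_genes)
  a_d <- stats::setNames(stats::rnorm(p$n_drugs, 2, 1), drugs)
  s_drug <- crossprod(expr_train - mu, drug_beta)    # cells x drugs
  f <- p$shared_fraction
  # cells x drugs: a_d - (f*s + (1-f)*s_d)
  noiseless <- vapply(seq_len(p$n_drugs), function(d)
    a_d[d] - (f * s_cell + (1 - f) * s_drug[, d]),
    numeric(p$n_cell_lines))
  response <- noiseless +
    matrix(stats::rnorm(p$n_cell_lines * p$n_drugs, sd = p$noise_sd),
           p$n_cell_lines)
  response <- t(response)                            # drugs x cells
  dimnames(response) <- list(drugs, cells)

  delta <- stats::setNames(stats::rnorm(p$n_genes, 0, p$batch_shift_sd),
                           genes)
  lambda <- stats::setNames(exp(stats::rnorm(p$n_genes, 0,
                                             p$batch_scale_sd)), genes)
  z_pat <- matrix(stats::rnorm(p$n_genes * p$n_patients), p$n_genes,
                  dimnames = list(genes, patients))
  expr_pat <- mu + delta + lambda * z_pat
  dimnames(expr_pat) <- list(genes, patients)
  # the cohort is treated with the first drug: its latent sensitivity mixes
  # the shared factor and that drug's specific factor with the same weights
  # as the in-vitro response
  cohort_weights <- f * beta + (1 - f) * drug_beta[, 1L]
  s_pat <- drop(crossprod(z_pat, cohort_weights))
  cut <- stats::quantile(s_pat, 1 - p$responder_fraction)
  resp_pat <- stats::setNames(as.integer(s_pat > cut), patients)
  if (p$effect_size == 0) {
    # no signal: responders are an arbitrary labelled subset of the cohort
    k <- max(1L, round(p$responder_fraction * p$n_patients))
    resp_pat[] <- 0L
    resp_pat[sample(p$n_patients, k)] <- 1L
  }

  # duplicated gene ids (extra rows, fresh noise) drawn from genes that
  # carry no planted structure, so removing them is harmless by design
  n_dup <- round(p$duplicate_gene_fraction * p$n_genes)
  dup_pool <- setdiff(free, landmark)
  dup_ids <- if (n_dup > 0) sample(dup_pool, min(n_dup, length(dup_pool)))
             else character()
  if (length(dup_ids) > 0) {
    extra_train <- matrix(stats::rnorm(length(dup_ids) * p$n_cell_lines),
                          length(dup_ids),
                          dimnames = list(dup_ids, cells)) + mu[dup_ids]
    extra_pat <- mu[dup_ids] + delta[dup_ids] + lambda[dup_ids] *
      matrix(stats::rnorm(length(dup_ids) * p$n_patients), length(dup_ids),
             dimnames = list(dup_ids, patients))
    expr_train <- rbind(expr_train, extra_train)
    expr_pat <- rbind(expr_pat, extra_pat)
  }

  tissues <- stats::setNames(
    sample(c("breast", "lung", "ovary", "blood", "skin"),
           p$n_cell_lines, replace = TRUE), cells)

  screen <- cell_screen(expr_train, response, tissues,
                        landmark_genes = landmark,
                        housekeeping_genes = housekeeping)
  cohort <- patient_cohort(expr_pat, resp_pat)
  truth <- list(signal_genes = signal, beta = beta, drug_beta = drug_beta,
                cohort_weights = cohort_weights, administered_drug = drugs[1L],
                patient_latent = s_pat, batch_shift = delta,
                batch_scale = lambda, gene_baseline = mu,
                drug_intercepts = a_d, duplicated_ids = dup_ids,
                noiseless_response = t(noiseless))
  list(screen = screen, cohort = cohort, truth = truth)
}

#' Generate a multi-drug cell screen
#'
#' Convenience wrapper for drug-specificity experiments: all drugs share the
#' general-sensitivity factor with weight `shared_fraction`; the pairwise
#' correlation of noiseless drug responses grows monotonically with it
#' (population value \eqn{f^2 / (f^2 + (1-f)^2)}).
#'
#' @param params a [simulation_params()] with `n_drugs >= 2`.
#' @return a [cell_screen].
#' @export
generate_multi_drug_screen <- function(params) {
  if (params$n_drugs < 2) stop("need n_drugs >= 2")
  generate_paired_datasets(params)$screen
}

#' Score samples with the generator's true weights
#'
#' The oracle predictor: applies the planted per-gene weights to an observed
#' expression matrix (higher score = more sensitive / responder).
#'
#' @param truth the `truth` element of [generate_paired_datasets()].
#' @param expression gene x sample matrix covering the signal genes.
#' @return named numeric score per sample.
#' @export
oracle_predict <- function(truth, expression) {
  sig <- intersect(truth$signal_genes, rownames(expression))
  if (length(sig) == 0) stop("expression matrix carries no signal genes")
  drop(crossprod(expression[sig, , drop = FALSE] -
                   truth$gene_baseline[sig], truth$cohort_weights[sig]))
}
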