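# shared fixtures and independent oracles

fast_control <- black_box_control(rf_trees = 20, ranger_trees = 40)

small_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 200, n_signal_genes = 20, n_housekeeping = 40,
               n_landmark = 40, n_cell_lines = 80, n_patients = 30,
               seed = seed)
  args[names(list(...))] <- list(...)
  generate_paired_datasets(do.call(simulation_params, args))
}

rand_expr <- function(genes, samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(length(genes) * length(samples)), length(genes),
         dimnames = list(genes, samples))
}

# brute-force ROC AUC: average over all responder/non-responder pairs,
# ties counted 1/2
brute_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force PR AUC: explicit loop over distinct thresholds
brute_pr_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_rec <- 0; area <- 0
  for (t in th) {
    keep <- scores >= t
    prec <- sum(labels[keep] == 1) / sum(keep)
    rec <- sum(labels[keep] == 1) / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# exhaustive 1-D two-cluster partition minimizing within-cluster SS
exhaustive_kmeans2 <- function(y) {
  n <- length(y)
  best <- NULL; best_wss <- Inf
  for (k in seq_len(n - 1)) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      wss <- sum((y[idx] - mean(y[idx]))^2) +
        sum((y[-idx] - mean(y[-idx]))^2)
      if (wss < best_wss - 1e-12) {
        best_wss <- wss; best <- idx
      }
    }
  }
  labels <- integer(n)
  sensitive <- if (mean(y[best]) < mean(y[-best])) best else setdiff(seq_len(n), best)
  labels[sensitive] <- 1L
  labels
}

# exact hypergeometric upper tail by enumeration of all n-subsets
exhaustive_hyper_p <- function(N, K, n, x) {
  marked <- seq_len(K)
  hits <- vapply(utils::combn(N, n, simplify = FALSE),
                 function(s) sum(s %in% marked), numeric(1))
  mean(hits >= x)
}
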