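#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by `n1 * n0`, with
#' tied score pairs counted 1/2 (equivalently, average ranks).
#'
#' @param scores named or plain numeric vector (higher = more likely
#'   responder).
#' @param labels 0/1 vector aligned with `scores`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation over the distinct score thresholds (tied scores are
#' processed as one block). For constant scores the curve collapses to a
#' single step and the area equals the positive prevalence.
#'
#' @inheritParams roc_auc
#' @return AUC-PR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  # block boundaries at distinct thresholds
  last_of_block <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- cumsum(lab)[last_of_block]
  nseen <- seq_along(lab)[last_of_block]
  prec <- tp / nseen
  rec <- tp / sum(labels == 1)
  sum(diff(c(0, rec)) * prec)
}

#' Two-sided t-test between responder and non-responder scores
#'
#' Pooled-variance Student t-test by default; Welch behind `welch = TRUE`.
#' If the pooled variance is zero the test degenerates: p = 1 when the
#' group means coincide, p = 0 otherwise.
#'
#' @inheritParams roc_auc
#' @param welch use the Welch (unequal-variance) test.
#' @return two-sided p-value.
#' @export
separation_ttest <- function(scores, labels, welch = FALSE) {
  labels <- as.integer(labels)
  g1 <- scores[labels == 1]; g0 <- scores[labels == 0]
  if (length(g1) < 2 || length(g0) < 2)
    stop("need >= 2 samples per class")
  if (stats::sd(c(g1, g0)) == 0 ||
      (stats::sd(g1) == 0 && stats::sd(g0) == 0))
    return(if (mean(g1) == mean(g0)) 1 else 0)
  stats::t.test(g1, g0, var.equal = !welch)$p.value
}

#' Assign competition-free ranks (1 = best, ties averaged)
#'
#' @param performances named numeric vector (higher = better).
#' @return named numeric ranks; tied values share the average of the ranks
#'   they cover (two tied best pipelines each get 1.5).
#' @export
assign_ranks <- function(performances) {
  if (length(performances) == 0) stop("no performances to rank")
  rank(-performances, ties.method = "average")
}

#' Pearson correlation matrix of performance vectors
#'
#' @param vectors named list of equally-indexed performance vectors
#'   (pipeline id -> metric).
#' @return symmetric correlation matrix with unit diagonal; entries
#'   involving a zero-variance vector are `NA` with a warning.
#' @export
performance_correlation <- function(vectors) {
  if (length(vectors) < 2) stop("need >= 2 performance vectors")
  ids <- names(vectors[[1]])
  m <- vapply(vectors, function(v) {
    if (!is.null(ids) && !is.null(names(v))) v <- v[ids]
    if (anyNA(v)) stop("performance vectors must share a pipeline universe")
    v
  }, numeric(length(vectors[[1]])))
  zero_var <- apply(m, 2, stats::sd) == 0
  if (any(zero_var))
    warning("zero-variance performance vector(s): correlations undefined")
  out <- suppressWarnings(stats::cor(m))
  diag(out) <- 1
  out
}
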