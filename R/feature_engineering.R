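#' Feature filtering and preprocessing settings
#'
#' @param filter one of `"all"`, `"landmarkgenes"`, `"variance"`,
#'   `"pvalue"`.
#' @param preprocess one of `"none"`, `"zscore_samplewise"`,
#'   `"zscore_genewise"`, `"pca"`.
#' @param drop_fraction fraction of genes removed by the variance and
#'   p-value filters (default 0.20).
#' @param n_components number of principal components kept by the PCA
#'   preprocessor (default 10).
#' @param extreme_fraction fraction of most-sensitive / most-resistant
#'   training samples contrasted by the p-value filter (default 0.25).
#' @param landmark_list gene ids for the landmark filter.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(filter = c("all", "landmarkgenes", "variance",
                                    "pvalue"),
                         preprocess = c("none", "zscore_samplewise",
                                        "zscore_genewise", "pca"),
                         drop_fraction = 0.20, n_components = 10L,
                         extreme_fraction = 0.25,
                         landmark_list = character()) {
  filter <- match.arg(filter)
  preprocess <- match.arg(preprocess)
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must be in (0, 1)")
  if (n_components < 1) stop("n_components must be >= 1")
  structure(list(filter = filter, preprocess = preprocess,
                 drop_fraction = drop_fraction,
                 n_components = as.integer(n_components),
                 extreme_fraction = extreme_fraction,
                 landmark_list = landmark_list),
            class = "feature_spec")
}

# row-wise Welch t-test p-values between two sample groups
rowwise_t_pvalues <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- apply(x[, idx1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, idx2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(p)] <- 1   # zero-variance genes are uninformative
  p
}

#' Select the training feature set
#'
#' Filters depend only on the training data (plus fixed gene lists), never
#' on the test samples. `variance` drops the `drop_fraction` least variant
#' genes; `pvalue` contrasts the most-sensitive versus most-resistant
#' `extreme_fraction` of training samples (the two classes for binary
#' responses) with a two-sided t-test per gene and drops the
#' `drop_fraction` genes with the highest p-values. Ties are resolved by
#' stable gene order.
#'
#' @param train,test gene x sample matrices on the shared gene set.
#' @param response a `transformed_response` (required for `filter =
#'   "pvalue"`).
#' @param spec a [feature_spec()].
#' @return character vector of retained gene ids, in training order.
#' @export
filter_features <- function(train, test, response = NULL,
                            spec = feature_spec()) {
  genes <- rownames(train)
  keep <- switch(spec$filter,
    all = genes,
    landmarkgenes = {
      out <- genes[genes %in% spec$landmark_list]
      if (length(out) == 0) stop("landmark intersection is empty")
      out
    },
    variance = {
      v <- apply(train, 1, stats::var)
      n_drop <- floor(spec$drop_fraction * length(genes))
      drop_idx <- order(v)[seq_len(n_drop)]
      if (n_drop > 0) genes[-drop_idx] else genes
    },
    pvalue = {
      if (is.null(response))
        stop("the p-value filter needs the transformed response")
      y <- response$values[colnames(train)]
      if (response$kind == "binary") {
        idx1 <- which(y == 1); idx2 <- which(y == 0)
      } else {
        # lower ln(IC50)-scale values = more sensitive
        k <- max(2L, floor(spec$extreme_fraction * length(y)))
        o <- order(y)
        idx1 <- o[seq_len(k)]
        idx2 <- o[length(y) - seq_len(k) + 1]
      }
      if (length(idx1) < 2 || length(idx2) < 2)
        stop("extreme groups too small for the p-value filter")
      p <- rowwise_t_pvalues(train, idx1, idx2)
      n_drop <- floor(spec$drop_fraction * length(genes))
      drop_idx <- order(-p)[seq_len(n_drop)]
      if (n_drop > 0) genes[-drop_idx] else genes
    })
  if (length(keep) == 0) stop("feature filter removed all genes")
  keep
}

#' Fit a feature preprocessor on training data and apply it to both sides
#'
#' `zscore_samplewise` standardizes each sample by its own gene mean/sd
#' (self-referential, so train and test are handled independently by
#' definition); `zscore_genewise` estimates per-gene mean/sd on the
#' training samples only and applies them to both matrices;
#' `pca` fits centering + rotation on the training samples and projects
#' both sides onto the first `n_components` components.
#'
#' @param train,test gene x sample matrices (already filtered).
#' @param spec a [feature_spec()].
#' @return list with `train` and `test` as sample x feature matrices and
#'   `transform`, the fitted parameters (reusable / serializable).
#' @export
preprocess_features <- function(train, test, spec = feature_spec()) {
  out <- switch(spec$preprocess,
    none = list(train = t(train), test = t(test),
                transform = list(kind = "none")),
    zscore_samplewise = {
      zs <- function(m) apply(m, 2, function(x) (x - mean(x)) / stats::sd(x))
      a <- zs(train); b <- zs(test)
      dimnames(a) <- dimnames(train); dimnames(b) <- dimnames(test)
      list(train = t(a), test = t(b),
           transform = list(kind = "zscore_samplewise"))
    },
    zscore_genewise = {
      mu <- rowMeans(train)
      sd <- apply(train, 1, stats::sd)
      keep <- sd > 0
      if (any(!keep))
        warning(sum(!keep), " zero-sd gene(s) dropped by genewise z-score")
      a <- (train[keep, , drop = FALSE] - mu[keep]) / sd[keep]
      b <- (test[keep, , drop = FALSE] - mu[keep]) / sd[keep]
      list(train = t(a), test = t(b),
           transform = list(kind = "zscore_genewise", center = mu[keep],
                            scale = sd[keep]))
    },
    pca = {
      k_max <- min(ncol(train) - 1L, nrow(train))
      k <- min(spec$n_components, k_max)
      if (k < spec$n_components)
        warning("n_components reduced to ", k)
      pc <- stats::prcomp(t(train), center = TRUE, scale. = FALSE)
      tr <- pc$x[, seq_len(k), drop = FALSE]
      te <- scale(t(test), center = pc$center, scale = FALSE) %*%
        pc$rotation[, seq_len(k), drop = FALSE]
      rownames(te) <- colnames(test)
      list(train = tr, test = te,
           transform = list(kind = "pca", center = pc$center,
                            rotation = pc$rotation[, seq_len(k),
                                                   drop = FALSE]))
    })
  out
}
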