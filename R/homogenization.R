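#' @title Train/test homogenization and batch-effect correction
#' @description Seven methods mapping a (train, test) expression pair on a
#'   shared gene set to adjusted matrices. The batch variable is always the
#'   binary train-vs-test indicator. Every method preserves matrix shape
#'   and gene/sample order.
#' @name homogenization
NULL

#' Homogenization settings
#'
#' @param method one of `"none"`, `"quantile"`, `"combat"`, `"limma"`,
#'   `"ruv4"`, `"ruv"`, `"yugene"`.
#' @param n_unwanted_factors number of unwanted-variation factors for the
#'   RUV methods (default 10 principal components).
#' @param control_genes housekeeping gene ids used as negative controls.
#' @param yugene_shift allow the cumulative-proportion transform to
#'   min-shift data containing negative values.
#' @return a `homogenization_spec` list.
#' @export
homogenization_spec <- function(method = c("none", "quantile", "combat",
                                           "limma", "ruv4", "ruv",
                                           "yugene"),
                                n_unwanted_factors = 10L,
                                control_genes = character(),
                                yugene_shift = FALSE) {
  method <- match.arg(method)
  if (n_unwanted_factors < 1) stop("n_unwanted_factors must be >= 1")
  if (method %in% c("ruv", "ruv4") && length(control_genes) < 2)
    stop(method, " needs >= 2 control (housekeeping) genes")
  structure(list(method = method,
                 n_unwanted_factors = as.integer(n_unwanted_factors),
                 control_genes = control_genes,
                 yugene_shift = isTRUE(yugene_shift)),
            class = "homogenization_spec")
}

check_same_genes <- function(train, test) {
  if (!identical(rownames(train), rownames(test)))
    stop("train and test must share the same gene set in the same order")
}

split_pooled <- function(pooled, train, test) {
  out_train <- pooled[, seq_len(ncol(train)), drop = FALSE]
  out_test <- pooled[, ncol(train) + seq_len(ncol(test)), drop = FALSE]
  dimnames(out_train) <- dimnames(train)
  dimnames(out_test) <- dimnames(test)
  list(train = out_train, test = out_test)
}

#' Apply a homogenization method to a train/test pair
#'
#' @param train,test gene x sample matrices on the same gene set.
#' @param spec a [homogenization_spec()]; a bare method name is accepted.
#' @return list with adjusted `train` and `test` matrices.
#' @export
homogenize <- function(train, test, spec = homogenization_spec("none")) {
  if (is.character(spec)) spec <- homogenization_spec(spec)
  switch(spec$method,
         none = homogenize_none(train, test),
         quantile = homogenize_quantile(train, test),
         combat = homogenize_combat(train, test),
         limma = homogenize_limma(train, test),
         ruv = homogenize_ruv_custom(train, test, spec),
         ruv4 = homogenize_ruv4(train, test, spec),
         yugene = homogenize_yugene(train, test,
                                    shift_nonnegative = spec$yugene_shift))
}

#' @rdname homogenize
#' @export
homogenize_none <- function(train, test) {
  check_same_genes(train, test)
  list(train = train, test = test)
}

#' Quantile-normalize the pooled sample collection
#'
#' All samples of train and test together are mapped onto the pooled mean
#' quantile distribution (ties by average), so afterwards every sample's
#' sorted value vector is identical.
#'
#' @rdname homogenize
#' @export
homogenize_quantile <- function(train, test) {
  check_same_genes(train, test)
  pooled <- limma::normalizeQuantiles(cbind(train, test), ties = TRUE)
  split_pooled(pooled, train, test)
}

#' Two-batch parametric empirical-Bayes adjustment (ComBat)
#'
#' Genes with zero variance in either batch cannot be standardized and are
#' passed through uncorrected with a warning.
#'
#' @rdname homogenize
#' @export
homogenize_combat <- function(train, test) {
  check_same_genes(train, test)
  if (ncol(train) < 2 || ncol(test) < 2)
    stop("ComBat needs >= 2 samples per batch")
  pooled <- cbind(train, test)
  batch <- rep(c(1L, 2L), c(ncol(train), ncol(test)))
  v1 <- apply(train, 1, stats::var)
  v2 <- apply(test, 1, stats::var)
  fixable <- v1 > 0 & v2 > 0
  out <- pooled
  if (any(!fixable))
    warning(sum(!fixable),
            " zero-variance gene(s) passed through uncorrected")
  if (sum(fixable) > 0) {
    adj <- suppressMessages(
      sva::ComBat(pooled[fixable, , drop = FALSE], batch = batch))
    out[fixable, ] <- adj
  }
  split_pooled(out, train, test)
}

#' Gene-wise linear batch-term removal
#'
#' Fits per gene `value = mu_g + beta_g * batch` and subtracts the fitted
#' batch term; per-gene batch means are exactly equal afterwards.
#'
#' @rdname homogenize
#' @export
homogenize_limma <- function(train, test) {
  check_same_genes(train, test)
  pooled <- cbind(train, test)
  batch <- rep(c("train", "test"), c(ncol(train), ncol(test)))
  adj <- limma::removeBatchEffect(pooled, batch = batch)
  split_pooled(adj, train, test)
}

ruv_check <- function(train, test, spec) {
  check_same_genes(train, test)
  controls <- intersect(spec$control_genes, rownames(train))
  if (length(controls) < 2)
    stop("need >= 2 control genes present in the shared gene set")
  n <- ncol(train) + ncol(test)
  if (spec$n_unwanted_factors >= n)
    stop("n_unwanted_factors must be < number of pooled samples")
  controls
}

# regress every gene on the factor scores W (with intercept), keep
# residuals + intercept; residuals are orthogonal to each column of W
regress_out_factors <- function(pooled, W) {
  D <- cbind(1, W)
  fit <- stats::lm.fit(D, t(pooled))
  resid <- t(fit$residuals) + matrix(fit$coefficients[1L, ],
                                     nrow(pooled), ncol(pooled))
  dimnames(resid) <- dimnames(pooled)
  resid
}

#' Principal-component RUV with housekeeping negative controls
#'
#' PCA on the pooled control-gene submatrix (samples as observations); the
#' first `n_unwanted_factors` component scores are regressed out of every
#' gene, and the residual expression (intercept restored) is the
#' homogenized data.
#'
#' @rdname homogenize
#' @export
homogenize_ruv_custom <- function(train, test, spec) {
  controls <- ruv_check(train, test, spec)
  pooled <- cbind(train, test)
  pc <- stats::prcomp(t(pooled[controls, , drop = FALSE]), center = TRUE)
  k <- min(spec$n_unwanted_factors, ncol(pc$x))
  if (k < spec$n_unwanted_factors)
    warning("only ", k, " principal components available; reduced")
  W <- pc$x[, seq_len(k), drop = FALSE]
  split_pooled(regress_out_factors(pooled, W), train, test)
}

#' SVD-based removal of unwanted variation (RUV4-style)
#'
#' Factor scores are the leading left singular vectors of the sample x
#' control matrix (genes centered); loadings for all genes are estimated by
#' regression on those factors and the fitted unwanted component is
#' subtracted.
#'
#' @rdname homogenize
#' @export
homogenize_ruv4 <- function(train, test, spec) {
  controls <- ruv_check(train, test, spec)
  pooled <- cbind(train, test)
  C <- t(scale(t(pooled[controls, , drop = FALSE]), center = TRUE,
               scale = FALSE))
  sv <- svd(t(C))
  k <- min(spec$n_unwanted_factors, sum(sv$d > 1e-12))
  if (k < 1) return(split_pooled(pooled, train, test))  # no-op limit
  if (k < spec$n_unwanted_factors)
    warning("only ", k, " non-null singular factors available; reduced")
  W <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  split_pooled(regress_out_factors(pooled, W), train, test)
}

#' Cumulative-proportion transform (per sample)
#'
#' Each sample is independently mapped to `1 - cumsum/total` over its
#' values sorted in descending order (ties broken by gene index), yielding
#' values in `[0, 1)` that preserve the within-sample order and are
#' invariant to sample scaling.
#'
#' @param shift_nonnegative if `TRUE`, a global min-shift is applied first
#'   when any value is negative (the transform itself requires
#'   non-negative input).
#' @rdname homogenize
#' @export
homogenize_yugene <- function(train, test, shift_nonnegative = FALSE) {
  check_same_genes(train, test)
  lo <- min(train, test)
  if (lo < 0) {
    if (!shift_nonnegative)
      stop("cumulative-proportion transform needs non-negative values; ",
           "shift the data first")
    train <- train - lo
    test <- test - lo
  }
  cp <- function(x) {
    if (any(x < 0))
      stop("cumulative-proportion transform needs non-negative values; ",
           "shift the data first")
    total <- sum(x)
    if (total == 0) stop("zero-sum sample")
    o <- order(-x)   # stable: descending value, ties by gene index
    out <- numeric(length(x))
    out[o] <- 1 - cumsum(x[o]) / total
    out
  }
  out_train <- apply(train, 2, cp)
  out_test <- apply(test, 2, cp)
  dimnames(out_train) <- dimnames(train)
  dimnames(out_test) <- dimnames(test)
  list(train = out_train, test = out_test)
}
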