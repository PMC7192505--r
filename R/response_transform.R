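#' @title Cell-response preprocessing
#' @description The five training-target transforms. Continuous transforms
#'   keep the ln(IC50) orientation (lower = more sensitive); binarizations
#'   flip to 1 = sensitive. The orientation travels with the transformed
#'   response so downstream ROC scoring can orient predictions.
#' @name response_transform
NULL

new_transformed_response <- function(values, kind, orientation,
                                     offset = 0, boxcox_lambda = NULL) {
  structure(list(values = values, kind = kind, orientation = orientation,
                 offset = offset, boxcox_lambda = boxcox_lambda),
            class = "transformed_response")
}

#' @exportS3Method base::print
print.transformed_response <- function(x, ...) {
  cat("transformed_response:", x$kind, "(", x$orientation, "),",
      length(x$values), "cell lines\n")
  invisible(x)
}

#' Apply one of the five cell-response transforms
#'
#' @param y named numeric vector of per-cell-line drug response (ln(IC50)).
#' @param method one of `"none"`, `"logarithm"`, `"powertransform"`,
#'   `"binarization_cutoff"`, `"binarization_kmeans"`.
#' @param seed integer seed (kept for interface symmetry; the k-means
#'   binarization is solved exactly and needs no randomness).
#' @return a `transformed_response`.
#' @export
transform_response <- function(y, method = c("none", "logarithm",
                                             "powertransform",
                                             "binarization_cutoff",
                                             "binarization_kmeans"),
                               seed = 1L) {
  method <- match.arg(method)
  switch(method,
         none = transform_none(y),
         logarithm = transform_logarithm(y),
         powertransform = transform_powertransform(y),
         binarization_cutoff = transform_binarize_cutoff(y),
         binarization_kmeans = transform_binarize_kmeans(y, seed))
}

#' @rdname transform_response
#' @export
transform_none <- function(y) {
  if (length(y) < 2) stop("need >= 2 response values")
  new_transformed_response(y, "continuous", "lower_is_sensitive")
}

# offset rule shared by logarithm and powertransform: shift so the minimum
# becomes 1 whenever min(y) <= 0 (applied at exactly 0 too, else log(0))
response_offset <- function(y) if (min(y) <= 0) -min(y) + 1 else 0

#' @rdname transform_response
#' @export
transform_logarithm <- function(y) {
  if (length(y) < 2) stop("need >= 2 response values")
  off <- response_offset(y)
  shifted <- y + off
  if (any(shifted <= 0)) stop("non-positive values after offset")
  new_transformed_response(log(shifted), "continuous",
                           "lower_is_sensitive", offset = off)
}

#' @rdname transform_response
#' @export
transform_powertransform <- function(y) {
  if (length(unique(y)) < 3) stop("need >= 3 distinct response values")
  off <- response_offset(y)
  shifted <- y + off
  if (any(shifted <= 0)) stop("non-positive values after offset")
  lambda <- unname(coef(car::powerTransform(shifted)))
  out <- if (abs(lambda) < 1e-8) log(shifted)
         else (shifted^lambda - 1) / lambda
  new_transformed_response(stats::setNames(out, names(y)), "continuous",
                           "lower_is_sensitive", offset = off,
                           boxcox_lambda = lambda)
}

#' @rdname transform_response
#' @export
transform_binarize_cutoff <- function(y) {
  if (length(unique(y)) < 2) stop("degenerate response: single value")
  med <- stats::median(y)
  cls <- as.integer(y <= med)   # ties at the median go sensitive
  if (length(unique(cls)) < 2) stop("median split produced a single class")
  new_transformed_response(stats::setNames(cls, names(y)), "binary",
                           "higher_is_sensitive")
}

# exact 1-D 2-means: scan all split points of the sorted values for the
# partition minimizing within-cluster sum of squares (global optimum, no
# Lloyd initialization nondeterminism)
exact_kmeans2_1d <- function(y) {
  o <- order(y)
  ys <- y[o]
  n <- length(ys)
  csum <- cumsum(ys); csq <- cumsum(ys^2)
  wss <- vapply(seq_len(n - 1), function(k) {
    left <- csq[k] - csum[k]^2 / k
    right <- (csq[n] - csq[k]) - (csum[n] - csum[k])^2 / (n - k)
    left + right
  }, numeric(1))
  k <- which.min(wss)
  labels <- integer(n)
  labels[o[seq_len(k)]] <- 1L   # lower-valued cluster
  labels
}

#' @rdname transform_response
#' @param seed unused (exact solver); kept for a uniform signature.
#' @export
transform_binarize_kmeans <- function(y, seed = 1L) {
  if (length(unique(y)) < 2) stop("degenerate response: single value")
  cls <- exact_kmeans2_1d(y)    # cluster with lower center -> sensitive
  new_transformed_response(stats::setNames(cls, names(y)), "binary",
                           "higher_is_sensitive")
}
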