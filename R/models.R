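#' Black-box training controls
#'
#' Tree counts follow the screened defaults (500 trees for the classic
#' random forest, 10,000 shallow-unconstrained trees for the fast ranger
#' forest) but are configurable so test suites can run reduced forests.
#'
#' @param rf_trees trees for `rf`.
#' @param ranger_trees trees for `rf_ranger`.
#' @param cv_folds folds for the glmnet lambda cross-validation.
#' @return a `black_box_control` list.
#' @export
black_box_control <- function(rf_trees = 500L, ranger_trees = 10000L,
                              cv_folds = 10L) {
  structure(list(rf_trees = as.integer(rf_trees),
                 ranger_trees = as.integer(ranger_trees),
                 cv_folds = as.integer(cv_folds)),
            class = "black_box_control")
}

#' Algorithms available to the scan
#' @export
BLACK_BOXES <- c("linear", "lasso", "elasticnet", "ridge", "rf",
                 "rf_ranger", "svm")

# minimum-norm least squares with intercept (works for p >= n)
fit_minnorm <- function(x, y) {
  X <- cbind(`(Intercept)` = 1, x)
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  drop(coef)
}

#' Fit one of the seven regression black boxes
#'
#' Binary targets are encoded 0/1 and fitted as numeric regression, so all
#' algorithms share one interface and yield continuous scores for ROC
#' evaluation. The glmnet family selects lambda on its internal grid by
#' `cv_folds`-fold cross-validation minimizing mean squared error, with
#' folds drawn once from `seed`; `linear` falls back to minimum-norm least
#' squares whenever features >= samples.
#'
#' @param features sample x feature numeric matrix (rownames = sample ids).
#' @param target a `transformed_response` covering the training samples.
#' @param algorithm one of [BLACK_BOXES].
#' @param seed integer seed controlling CV folds and forest randomness.
#' @param control a [black_box_control()].
#' @return a `fitted_model` with the algorithm, the fitted state, the
#'   target orientation and the ordered training feature ids.
#' @export
fit_black_box <- function(features, target, algorithm = BLACK_BOXES,
                          seed = 1L, control = black_box_control()) {
  algorithm <- match.arg(algorithm)
  if (nrow(features) < 2) stop("need >= 2 training samples")
  y <- as.numeric(target$values[rownames(features)])
  if (anyNA(y)) stop("target missing for some training samples")
  set.seed(seed)

  constant_y <- stats::sd(y) == 0
  needs_cv <- algorithm %in% c("lasso", "elasticnet", "ridge")
  fit <- NULL
  kind <- algorithm
  if (constant_y && algorithm != "rf" && algorithm != "rf_ranger") {
    warning("constant target; fitting intercept-only model")
    kind <- "intercept_only"
    fit <- mean(y)
  } else if (needs_cv && ncol(features) < 2) {
    warning("fewer than 2 features; penalized fit replaced by least squares")
    kind <- "linear"
    fit <- fit_minnorm(features, y)
  } else {
    fit <- switch(algorithm,
      linear = fit_minnorm(features, y),
      lasso = ,
      elasticnet = ,
      ridge = {
        if (nrow(features) < 10)
          stop("lambda cross-validation needs >= 10 samples")
        alpha <- c(lasso = 1, elasticnet = 0.5, ridge = 0)[[algorithm]]
        foldid <- sample(rep(seq_len(control$cv_folds),
                             length.out = nrow(features)))
        glmnet::cv.glmnet(features, y, alpha = alpha, foldid = foldid,
                          family = "gaussian")
      },
      rf = randomForest::randomForest(x = features, y = y,
                                      ntree = control$rf_trees),
      rf_ranger = ranger::ranger(
        x = features, y = y, num.trees = control$ranger_trees,
        seed = seed, num.threads = 1),
      svm = e1071::svm(x = features, y = y, kernel = "radial"))
  }
  structure(list(algorithm = algorithm, kind = kind, fit = fit,
                 target_orientation = target$orientation,
                 training_feature_ids = colnames(features)),
            class = "fitted_model")
}

#' Predict scores for new samples
#'
#' The feature columns must match the training features exactly, in order.
#'
#' @param model a `fitted_model`.
#' @param features sample x feature matrix.
#' @return named numeric score per sample (on the training-target scale).
#' @export
predict_black_box <- function(model, features) {
  ids <- model$training_feature_ids
  if (!identical(colnames(features), ids)) {
    missing <- setdiff(ids, colnames(features))
    extra <- setdiff(colnames(features), ids)
    stop("feature mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "),
         "] (order must match training)")
  }
  preds <- switch(model$kind,
    intercept_only = rep(model$fit, nrow(features)),
    linear = drop(cbind(1, features) %*% model$fit),
    lasso = ,
    elasticnet = ,
    ridge = drop(stats::predict(model$fit, newx = features,
                                s = "lambda.min")),
    rf = unname(stats::predict(model$fit, newdata = features)),
    rf_ranger = stats::predict(model$fit, data = features,
                               num.threads = 1)$predictions,
    svm = unname(stats::predict(model$fit, newdata = features)))
  stats::setNames(as.numeric(preds), rownames(features))
}

#' Orient prediction scores so that higher = more likely responder
#'
#' Continuous targets live on the ln(IC50) scale where lower means more
#' sensitive, so their predictions are negated; binary (1 = sensitive)
#' targets pass through unchanged.
#'
#' @param predictions named numeric scores.
#' @param orientation `"lower_is_sensitive"` or `"higher_is_sensitive"`.
#' @return oriented scores.
#' @export
orient_scores <- function(predictions,
                          orientation = c("lower_is_sensitive",
                                          "higher_is_sensitive")) {
  orientation <- match.arg(orientation)
  if (orientation == "lower_is_sensitive") -predictions else predictions
}
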