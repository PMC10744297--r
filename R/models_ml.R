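#' Classical machine-learning classifiers
#'
#' Thin, seeded wrappers with fixed default hyperparameters around
#' established implementations: ridge-penalized logistic regression
#' (glmnet), RBF support vector machine (e1071), random forest
#' (randomForest) and gradient-boosted trees (xgboost). All expose the same
#' fit / predict-probability surface used by the cross-validation driver.
#'
#' @name classifiers-ml
NULL

.ML_FAMILIES <- c("logreg", "svm", "random_forest", "xgboost")
.DL_FAMILIES <- c("cnn1d", "resnet1d")

#' Model specification
#'
#' @param family one of \code{logreg}, \code{svm}, \code{random_forest},
#'   \code{xgboost}, \code{cnn1d}, \code{resnet1d}.
#' @param seed integer RNG seed used at fit time.
#' @param ... family-specific hyperparameters. Defaults: logreg — L2
#'   (ridge) penalty \code{lambda = 1e-4}; svm — RBF kernel, \code{cost =
#'   1}; random_forest — \code{n_trees = 100}; xgboost — \code{n_rounds =
#'   200}, \code{learning_rate = 0.1}, \code{max_depth = 3},
#'   \code{l2_strength = 1e-4}; cnn1d/resnet1d — \code{l2_strength = 1e-4},
#'   \code{dropout = 0.25}, \code{epochs = 40}, \code{learning_rate =
#'   0.001}, \code{batch_size = 32}.
#' @return a \code{model_spec} object.
#' @export
model_spec <- function(family, seed = 1L, ...) {
  if (!family %in% c(.ML_FAMILIES, .DL_FAMILIES))
    stop(sprintf("unknown model family '%s'", family), call. = FALSE)
  defaults <- switch(family,
    logreg        = list(lambda = 1e-4),
    svm           = list(cost = 1, kernel = "radial"),
    random_forest = list(n_trees = 100L),
    xgboost       = list(n_rounds = 200L, learning_rate = 0.1,
                         max_depth = 3L, l2_strength = 1e-4),
    cnn1d         = list(l2_strength = 1e-4, dropout = 0.25, epochs = 40L,
                         learning_rate = 0.001, batch_size = 32L),
    resnet1d      = list(l2_strength = 1e-4, dropout = 0.25, epochs = 40L,
                         learning_rate = 0.001, batch_size = 32L))
  hp <- utils::modifyList(defaults, list(...))
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown hyperparameter(s) for %s: %s", family,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  structure(list(family = family, seed = as.integer(seed), hyperparams = hp),
            class = "model_spec")
}

#' Build an untrained classical ML model
#'
#' @param spec a \code{model_spec} with an ML family.
#' @return an object of class \code{ml_model} carrying the spec; fit with
#'   \code{\link{fit_model}}.
#' @export
build_ml_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$family %in% .ML_FAMILIES)
    stop(sprintf("'%s' is not a classical ML family", spec$family),
         call. = FALSE)
  structure(list(spec = spec, fit = NULL), class = "ml_model")
}

#' Fit a classifier on a feature matrix
#'
#' @param model an \code{ml_model} (or \code{dl_model}).
#' @param x numeric feature matrix (rows = spectra).
#' @param y integer labels (0 = healthy, 1 = cancerous).
#' @param ... passed to family-specific fitting.
#' @return the fitted model.
#' @export
fit_model <- function(model, x, y, ...) UseMethod("fit_model")

#' Predict class-1 (cancerous) probabilities
#'
#' @param model a fitted model.
#' @param x feature matrix.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(model, x) UseMethod("predict_prob")

#' @export
fit_model.ml_model <- function(model, x, y, ...) {
  x <- as.matrix(x); y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  hp <- model$spec$hyperparams
  set.seed(model$spec$seed)
  model$fit <- switch(model$spec$family,
    logreg = glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = hp$lambda, standardize = TRUE),
    svm = {
      sv <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = hp$kernel,
                       cost = hp$cost, scale = TRUE)
      # deterministic Platt scaling on training decision values (the glm
      # slope absorbs the decision-value sign convention)
      dv <- as.numeric(attr(stats::predict(sv, x, decision.values = TRUE),
                            "decision.values"))
      platt <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial()))
      list(svm = sv, platt = platt)
    },
    random_forest = randomForest::randomForest(
      x, factor(y, levels = c(0, 1)), ntree = hp$n_trees),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$learning_rate,
                    max_depth = hp$max_depth, lambda = hp$l2_strength,
                    nthread = 1L, seed = model$spec$seed),
      data = xgboost::xgb.DMatrix(x, label = y),
      nrounds = hp$n_rounds, verbose = 0))
  model
}

#' @export
predict_prob.ml_model <- function(model, x) {
  if (is.null(model$fit)) stop("model has not been fitted", call. = FALSE)
  x <- as.matrix(x)
  p <- switch(model$spec$family,
    logreg = as.numeric(stats::predict(model$fit, newx = x,
                                       type = "response")),
    svm = {
      dv <- as.numeric(attr(stats::predict(model$fit$svm, x,
                                           decision.values = TRUE),
                            "decision.values"))
      as.numeric(stats::predict(model$fit$platt,
                                newdata = data.frame(dv = dv),
                                type = "response"))
    },
    random_forest = as.numeric(
      stats::predict(model$fit, x, type = "prob")[, "1"]),
    xgboost = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x))))
  pmin(pmax(p, 0), 1)
}

#' Predicted labels at the 0.5 threshold
#'
#' @param model a fitted model.
#' @param x feature matrix.
#' @return integer labels (1 when probability >= 0.5).
#' @export
predict_label <- function(model, x) {
  as.integer(predict_prob(model, x) >= 0.5)
}
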