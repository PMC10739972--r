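#' Base learner specification
#'
#' The four conventional classifier families used throughout: decision
#' tree (`DT`), gradient boosting (`GB`), support vector machine
#' (`SVM`) and extremely randomised trees (`ET`). Training is delegated
#' to established implementations (rpart, xgboost, e1071, ranger); every
#' fitted learner satisfies the same contract — `predict()` returns
#' either hard labels or a two-class probability simplex per sample —
#' so families are interchangeable inside the ensembles.
#'
#' @param family One of `"DT"`, `"GB"`, `"SVM"`, `"ET"`.
#' @param params Named list of family-specific hyperparameter overrides.
#' @param seed Integer RNG seed (default 10, the random state used for
#'   the reference configuration).
#' @return A `base_learner_spec`.
#' @export
base_learner <- function(family = c("DT", "GB", "SVM", "ET"),
                         params = list(), seed = 10L) {
  family <- match.arg(family)
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "base_learner_spec")
}

#' The fixed family ordering used for tie-breaks
#' @keywords internal
learner_families <- function() c("DT", "GB", "SVM", "ET")

#' Train a base learner
#'
#' @param spec A [base_learner()].
#' @param data Training `clinical_tbl` with both classes present.
#' @param features Feature subset to train on (default: all schema
#'   predictors present in the table).
#' @return An `hf_base_fit` exposing `predict(fit, newdata,
#'   type = "prob"|"label")`.
#' @examples
#' tbl <- simulate_hf(hf_generator_config(n_samples = 80, seed = 5))
#' fit <- train_base(base_learner("DT"), tbl)
#' head(predict(fit, tbl, type = "prob"))
#' @export
train_base <- function(spec, data, features = NULL) {
  stopifnot(inherits(spec, "base_learner_spec"))
  y <- clinical_labels(data)
  if (length(unique(y)) < 2) {
    stop("single-class training table", call. = FALSE)
  }
  features <- features %||%
    intersect(setdiff((attr(data, "schema") %||% hf_schema())$name,
                      "death_event"),
              names(data))
  X <- clinical_features(data, features)
  fit <- withr::with_seed(spec$seed, switch(
    spec$family,
    DT = fit_dt(X, y, spec$params),
    GB = fit_gb(X, y, spec$params, spec$seed),
    SVM = fit_svm(X, y, spec$params),
    ET = fit_et(X, y, spec$params, spec$seed)
  ))
  structure(list(spec = spec, fit = fit, features = features),
            class = "hf_base_fit")
}

fit_dt <- function(X, y, params) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  ctrl <- utils::modifyList(
    list(maxdepth = 30, cp = 0.01, minsplit = 20, xval = 0),
    params
  )
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = do.call(rpart::rpart.control, ctrl))
}

fit_gb <- function(X, y, params, seed) {
  pars <- utils::modifyList(
    list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
         nthread = 1, seed = seed),
    params[setdiff(names(params), "nrounds")]
  )
  nrounds <- params$nrounds %||% 100L
  xgboost::xgb.train(
    params = do.call(xgboost::xgb.params, pars),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}

# SVM decision values are mapped to probabilities by a deterministic
# logistic (Platt-style) calibration fitted on the training scores
fit_svm <- function(X, y, params) {
  args <- utils::modifyList(
    list(kernel = "radial", cost = 1, scale = TRUE),
    params
  )
  yf <- factor(y, levels = c(0, 1))
  svm_fit <- do.call(e1071::svm,
                     c(list(x = X, y = yf, probability = FALSE), args))
  dec <- attr(predict(svm_fit, X, decision.values = TRUE),
              "decision.values")[, 1]
  calib <- suppressWarnings(
    stats::glm(y ~ dec, family = stats::binomial(),
               data = data.frame(y = y, dec = dec))
  )
  list(svm = svm_fit, calib = calib)
}

fit_et <- function(X, y, params, seed) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  args <- utils::modifyList(
    list(num.trees = 100, splitrule = "extratrees", num.random.splits = 1,
         replace = FALSE, sample.fraction = 1, min.node.size = 1),
    params
  )
  do.call(ranger::ranger,
          c(list(formula = .y ~ ., data = df, probability = TRUE,
                 seed = seed, num.threads = 1),
            args))
}

#' @export
predict.hf_base_fit <- function(object, newdata, type = c("prob", "label"),
                                ...) {
  type <- match.arg(type)
  X <- clinical_features(newdata, object$features)
  p1 <- switch(
    object$spec$family,
    DT = predict(object$fit, as.data.frame(X), type = "prob")[, "1"],
    GB = predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    SVM = {
      dec <- attr(predict(object$fit$svm, X, decision.values = TRUE),
                  "decision.values")[, 1]
      unname(stats::predict(object$fit$calib,
                            newdata = data.frame(dec = dec),
                            type = "response"))
    },
    ET = predict(object$fit, as.data.frame(X), num.threads = 1)$
      predictions[, "1"]
  )
  p1 <- pmin(pmax(as.numeric(p1), 0), 1)
  prob <- cbind(`0` = 1 - p1, `1` = p1)
  if (type == "prob") prob else as.integer(p1 >= 0.5)
}

#' @export
print.hf_base_fit <- function(x, ...) {
  cat("<hf_base_fit>", x$spec$family, "on", length(x$features),
      "features\n")
  invisible(x)
}
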