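#' Available machine-learning selector families
#'
#' Registry of generic multi-class classifier families usable for method
#' selection on the three lesion features (SUVpeak, TBRpeak, SUVbg). Each
#' entry names the backing package; a family is only usable when its
#' package is installed.
#'
#' @return named character vector mapping family id to backing package.
#' @export
selector_families <- function() {
  c(logistic = "nnet",         # multinomial logistic regression
    tree = "rpart",            # decision tree
    random_forest = "randomForest",
    svm = "e1071",
    xgboost = "xgboost")
}

selector_priority <- function() c("MV2", "MV3", "SUV4.0", "A50peak", "41max", "SUV2.5")

# one training label per lesion: the rate-3 method of highest priority
training_labels <- function(table) {
  rm3 <- rating_matrix(table) == 3L
  pr <- selector_priority()
  lab <- apply(rm3[, pr, drop = FALSE], 1L, function(z) {
    w <- which(z)
    if (length(w)) pr[w[1]] else NA_character_
  })
  lab
}

#' Train a method-selection classifier
#'
#' Fits a multi-class model predicting the preferred segmentation method
#' from (SUVpeak, TBRpeak, SUVbg). Because several methods can be acceptable
#' for one lesion, the training label is the single rate-3 method of highest
#' priority (MV2 > MV3 > SUV4.0 > A50peak > 41%max > SUV2.5); lesions with
#' no method rated 3 are excluded from training. Evaluation, by contrast,
#' should accept any rate-3 method — use [rule_accuracy()] semantics via
#' [selector_accuracy()].
#'
#' @param table rated lesion table (see [rule_accuracy()]).
#' @param model_kind a family id from [selector_families()].
#' @param rng_seed integer seed (used by the stochastic families).
#' @return an object of class `method_selector` with a `predict` method
#'   returning a lesion-by-method probability matrix over all six methods
#'   (rows sum to 1), and [select_method()] for highest-probability
#'   selection.
#' @export
train_selector <- function(table, model_kind = "tree", rng_seed = 1L) {
  fams <- selector_families()
  if (!model_kind %in% names(fams))
    stop("unknown model_kind '", model_kind, "'; available: ",
         paste(names(fams), collapse = ", "), call. = FALSE)
  pkg <- fams[[model_kind]]
  if (!requireNamespace(pkg, quietly = TRUE))
    stop(sprintf("family '%s' needs package '%s'", model_kind, pkg), call. = FALSE)
  lab <- training_labels(table)
  keep <- !is.na(lab)
  if (!any(keep))
    stop("no lesion has a method rated 3; nothing to train on", call. = FALSE)
  x <- table[keep, c("suvpeak", "tbrpeak", "suvbg")]
  y <- factor(lab[keep], levels = pet_methods())
  y <- droplevels(y)
  df <- cbind(x, .label = y)
  set.seed(rng_seed)
  fit <- switch(model_kind,
    logistic = nnet::multinom(.label ~ suvpeak + tbrpeak + suvbg, data = df,
                              trace = FALSE, maxit = 300),
    tree = rpart::rpart(.label ~ suvpeak + tbrpeak + suvbg, data = df,
                        method = "class"),
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = 300),
    svm = e1071::svm(.label ~ suvpeak + tbrpeak + suvbg, data = df,
                     probability = TRUE),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                     label = as.integer(y) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = nlevels(y),
                                       max_depth = 4, eta = 0.3,
                                       nthread = 1, seed = rng_seed),
                         data = dtrain, nrounds = 60, verbose = 0)
    })
  structure(list(model = fit, kind = model_kind, levels = levels(y),
                 feature_names = c("suvpeak", "tbrpeak", "suvbg"),
                 n_train = sum(keep), rng_seed = rng_seed),
            class = "method_selector")
}

#' @export
print.method_selector <- function(x, ...) {
  cat(sprintf("Method selector: %s family, trained on %d lesions, classes: %s\n",
              x$kind, x$n_train, paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict method probabilities for new lesions
#'
#' @param object a [method_selector][train_selector].
#' @param newdata data frame with columns `suvpeak`, `tbrpeak`, `suvbg`.
#' @param ... unused.
#' @return numeric matrix, one row per lesion and one column per method in
#'   [pet_methods()] order; rows sum to 1 (methods absent from the training
#'   classes get probability 0).
#' @export
predict.method_selector <- function(object, newdata, ...) {
  if (is.null(object$model)) stop("unfitted selector", call. = FALSE)
  x <- newdata[, object$feature_names, drop = FALSE]
  p <- switch(object$kind,
    logistic = {
      pr <- predict(object$model, newdata = x, type = "probs")
      if (is.null(dim(pr))) {
        if (length(object$levels) == 2L)
          pr <- cbind(1 - pr, pr, deparse.level = 0)  # binomial collapse
        else pr <- matrix(pr, nrow = 1L)
      }
      pr
    },
    tree = predict(object$model, newdata = x, type = "prob"),
    random_forest = predict(object$model, newdata = x, type = "prob"),
    svm = {
      pr <- predict(object$model, newdata = x, probability = TRUE)
      attr(pr, "probabilities")[, , drop = FALSE]
    },
    xgboost = {
      pr <- predict(object$model, xgboost::xgb.DMatrix(as.matrix(x)))
      if (!is.matrix(pr))
        pr <- matrix(pr, ncol = length(object$levels), byrow = TRUE)
      colnames(pr) <- object$levels
      pr
    })
  p <- as.matrix(p)
  if (is.null(colnames(p))) colnames(p) <- object$levels
  out <- matrix(0, nrow(x), 6, dimnames = list(NULL, pet_methods()))
  out[, colnames(p)] <- p[, , drop = FALSE]
  out / rowSums(out)
}

#' Highest-probability method selection
#'
#' Picks the method with the largest predicted probability per lesion;
#' exact ties are broken by the fixed priority order
#' MV2 > MV3 > SUV4.0 > A50peak > 41%max > SUV2.5.
#'
#' @param model a [method_selector][train_selector], or a probability matrix
#'   over the six methods.
#' @param features data frame of lesion features (ignored when `model` is
#'   already a probability matrix).
#' @return character vector of selected methods.
#' @export
select_method <- function(model, features = NULL) {
  probs <- if (is.matrix(model)) {
    if (!all(pet_methods() %in% colnames(model)))
      stop("probability matrix must have one column per method", call. = FALSE)
    model[, pet_methods(), drop = FALSE]
  } else {
    predict(model, features)
  }
  pr <- selector_priority()
  probs_pr <- probs[, pr, drop = FALSE]
  pr[max.col(probs_pr, ties.method = "first")]
}

#' Accuracy of a selector under preferred-rating semantics
#'
#' The fraction of lesions whose selected method is rated 3, matching
#' [rule_accuracy()] exactly.
#'
#' @param model a [method_selector][train_selector].
#' @param table rated lesion table.
#' @return accuracy in \[0, 1\].
#' @export
selector_accuracy <- function(model, table) {
  sel <- select_method(model, table)
  rm <- rating_matrix(table)
  mean(rm[cbind(seq_len(nrow(rm)), match(sel, colnames(rm)))] == 3L)
}
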