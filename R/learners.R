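# Candidate learners: logistic baseline, single-hidden-layer ANN, linear
# and RBF SVM, tree ensemble; plus stratified k-fold cross-validation.
# Fits go through glm / nnet / e1071 / randomForest; each trained learner
# additionally exposes the fitted parameters that weight extraction needs
# (ANN weight matrices, SVM hyperplane vector, impurity importances).

LEARNER_KINDS <- c("logistic", "ann", "svm_linear", "svm_rbf", "tree_ensemble")

#' Configure a candidate learner
#'
#' Fields irrelevant to `kind` are ignored. Defaults mirror the finalized
#' reference models: one hidden layer of 7 nodes for the ANN, cost 0.5 for
#' the linear SVM.
#'
#' @param kind One of `"logistic"`, `"ann"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"tree_ensemble"`.
#' @param hidden_nodes Hidden-layer size of the ANN (default 7).
#' @param hidden_layers Number of hidden layers; only 1 is supported.
#' @param svm_cost SVM cost parameter C (default 0.5).
#' @param rbf_gamma RBF kernel width; default `1/p` at fit time.
#' @param n_trees Trees in the ensemble (default 500; 1 gives a single
#'   bagged tree).
#' @param max_epochs Optimizer iteration cap for the ANN (default 500).
#' @param l2_penalty Weight-decay penalty for the ANN (default 1). The
#'   connection-weight importance methods read the fitted weights
#'   directly, so the network is regularized enough that hidden-node
#'   weight cancellation does not swamp the signal; discrimination is
#'   essentially unaffected.
#' @param seed Integer seed controlling stochastic fits.
#' @return An object of class `learner_config`.
#' @export
learner_config <- function(kind, hidden_nodes = 7L, hidden_layers = 1L,
                           svm_cost = 0.5, rbf_gamma = NULL, n_trees = 500L,
                           max_epochs = 500L, l2_penalty = 1, seed = 1L) {
  kind <- match.arg(kind, LEARNER_KINDS)
  if (hidden_nodes < 1L) stop("hidden_nodes must be >= 1", call. = FALSE)
  if (hidden_layers != 1L)
    stop("only single-hidden-layer networks are supported", call. = FALSE)
  if (svm_cost <= 0) stop("svm_cost must be positive", call. = FALSE)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(kind = kind, hidden_nodes = as.integer(hidden_nodes),
                 hidden_layers = 1L, svm_cost = svm_cost,
                 rbf_gamma = rbf_gamma, n_trees = as.integer(n_trees),
                 max_epochs = as.integer(max_epochs),
                 l2_penalty = l2_penalty, seed = as.integer(seed)),
            class = "learner_config")
}

#' Train a candidate learner on a binary cohort
#'
#' Returns a `trained_learner` whose `parameters` element exposes what
#' weight extraction needs: for `ann` the input-to-hidden weight matrix `W`
#' (p x h), hidden biases, hidden-to-output vector `v`, and output bias;
#' for `svm_linear` the hyperplane vector `w` (recovered as
#' `sum(alpha_i y_i x_i)` over support vectors, oriented so positive
#' decision values favour cases) and intercept `b`; for `tree_ensemble`
#' the per-feature mean decrease in Gini impurity.
#'
#' @param cohort A [binary_cohort()] with both outcome classes present.
#' @param config A [learner_config()].
#' @return An object of class `trained_learner` with elements `config`,
#'   `kind`, `fit` (the underlying fitted object), `parameters`, and
#'   `feature_names`.
#' @export
train_learner <- function(cohort, config) {
  if (!inherits(cohort, "binary_cohort"))
    stop("cohort must be a binary_cohort", call. = FALSE)
  if (!inherits(config, "learner_config"))
    stop("config must be a learner_config", call. = FALSE)
  assert_both_classes(cohort$outcome)
  X <- cohort$features
  y <- cohort$outcome
  p <- ncol(X)
  fit_pars <- with_seed(config$seed, switch(
    config$kind,
    logistic = {
      df <- data.frame(X, y = y, check.names = FALSE)
      fit <- stats::glm(y ~ ., data = df, family = binomial())
      list(fit = fit, parameters = list(coefficients = coef(fit)))
    },
    ann = {
      fit <- nnet::nnet(x = X, y = y, size = config$hidden_nodes,
                        entropy = TRUE, decay = config$l2_penalty,
                        maxit = config$max_epochs, trace = FALSE)
      h <- config$hidden_nodes
      wts <- fit$wts
      W <- matrix(0, p, h, dimnames = list(colnames(X), NULL))
      b_hidden <- numeric(h)
      for (k in seq_len(h)) {
        block <- wts[((k - 1L) * (p + 1L) + 1L):(k * (p + 1L))]
        b_hidden[k] <- block[1L]
        W[, k] <- block[-1L]
      }
      out_block <- wts[(h * (p + 1L) + 1L):(h * (p + 1L) + h + 1L)]
      list(fit = fit,
           parameters = list(W = W, hidden_bias = b_hidden,
                             v = out_block[-1L], output_bias = out_block[1L]))
    },
    svm_linear = ,
    svm_rbf = {
      kernel <- if (config$kind == "svm_linear") "linear" else "radial"
      gamma <- if (is.null(config$rbf_gamma)) 1 / p else config$rbf_gamma
      yf <- factor(y, levels = c(0, 1))
      fit <- e1071::svm(x = X, y = yf, kernel = kernel, cost = config$svm_cost,
                        gamma = gamma, scale = FALSE, probability = TRUE)
      # orient the decision function so positive values favour outcome 1
      flip <- if (fit$labels[1L] == 2L) 1 else -1
      pars <- list(alpha = flip * as.numeric(fit$coefs),
                   support_vectors = fit$SV,
                   b = flip * -fit$rho, gamma = gamma)
      if (config$kind == "svm_linear") {
        w <- as.numeric(crossprod(fit$coefs, fit$SV)) * flip
        names(w) <- colnames(X)
        pars$w <- w
      }
      list(fit = fit, parameters = pars)
    },
    tree_ensemble = {
      fit <- randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                        ntree = config$n_trees)
      imp <- fit$importance[, "MeanDecreaseGini"]
      list(fit = fit, parameters = list(importance = imp))
    }))
  structure(list(config = config, kind = config$kind, fit = fit_pars$fit,
                 parameters = fit_pars$parameters,
                 feature_names = colnames(X)),
            class = "trained_learner")
}

#' @export
print.trained_learner <- function(x, ...) {
  cat(sprintf("<trained_learner> kind = %s, %d features\n",
              x$kind, length(x$feature_names)))
  invisible(x)
}

#' Predict case probabilities from a trained learner
#'
#' @param object A `trained_learner`.
#' @param newdata 0/1 matrix or data frame whose columns match the
#'   training features.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels at the
#'   0.5 threshold.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\] or 0/1 labels.
#' @export
predict.trained_learner <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X)))
      stop("newdata is missing training feature columns", call. = FALSE)
    X <- X[, object$feature_names, drop = FALSE]
  }
  prob <- switch(
    object$kind,
    logistic = {
      df <- as.data.frame(X)
      as.numeric(predict(object$fit, newdata = df, type = "response"))
    },
    ann = as.numeric(predict(object$fit, X)),
    svm_linear = ,
    svm_rbf = {
      pr <- predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    tree_ensemble = predict(object$fit, X, type = "prob")[, "1"])
  prob <- pmin(pmax(as.numeric(prob), 0), 1)
  if (type == "prob") prob else as.numeric(prob >= 0.5)
}

#' SVM decision values for a trained linear or RBF learner
#'
#' Oriented so positive values favour cases. For the linear kernel this
#' equals `X %*% w + b` with the stored hyperplane parameters.
#'
#' @param learner A `trained_learner` of kind `svm_linear` or `svm_rbf`.
#' @param newdata 0/1 feature matrix.
#' @return Numeric vector of signed distances (unnormalized).
#' @export
decision_values <- function(learner, newdata) {
  if (!learner$kind %in% c("svm_linear", "svm_rbf"))
    stop("decision_values requires an SVM learner", call. = FALSE)
  pr <- predict(learner$fit, as.matrix(newdata), decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  flip <- if (learner$fit$labels[1L] == 2L) 1 else -1
  flip * dv
}

#' Plan a stratified k-fold cross-validation
#'
#' @param n_folds Number of folds (default 10).
#' @param stratified Balance outcome classes across folds (default TRUE).
#' @param seed Seed for the fold shuffle.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10L, stratified = TRUE, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  structure(list(n_folds = as.integer(n_folds), stratified = isTRUE(stratified),
                 seed = as.integer(seed)), class = "cv_plan")
}

#' Assign cross-validation folds
#'
#' With stratification, each outcome class is shuffled and dealt
#' round-robin into folds, so a balanced cohort splits into folds with
#' equal case and control counts.
#'
#' @param outcome 0/1 vector.
#' @param plan A [cv_plan()].
#' @return Integer vector of fold labels in `1:n_folds`.
#' @export
assign_folds <- function(outcome, plan) {
  n <- length(outcome)
  if (plan$n_folds > n) stop("more folds than subjects", call. = FALSE)
  with_seed(plan$seed, {
    fold <- integer(n)
    if (plan$stratified) {
      for (cls in unique(outcome)) {
        idx <- which(outcome == cls)
        if (plan$n_folds > length(idx))
          stop("more folds than members of the smallest outcome class",
               call. = FALSE)
        fold[sample(idx)] <- rep_len(seq_len(plan$n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(plan$n_folds), n)
    }
    fold
  })
}

#' Pooled out-of-fold predictions under k-fold cross-validation
#'
#' Each subject is predicted exactly once, by the model trained on the
#' folds it does not belong to. Hard labels use the 0.5 threshold.
#'
#' @param cohort A [binary_cohort()].
#' @param config A [learner_config()].
#' @param plan A [cv_plan()].
#' @return A data frame with columns `subject`, `fold`, `probability`,
#'   `label`, `outcome`.
#' @export
cross_validate <- function(cohort, config, plan) {
  fold <- assign_folds(cohort$outcome, plan)
  prob <- rep(NA_real_, length(cohort$outcome))
  for (k in seq_len(plan$n_folds)) {
    train_idx <- which(fold != k)
    test_idx <- which(fold == k)
    if (!length(test_idx)) next
    sub <- binary_cohort(cohort$features[train_idx, , drop = FALSE],
                         cohort$outcome[train_idx])
    fit <- train_learner(sub, config)
    prob[test_idx] <- predict(fit, cohort$features[test_idx, , drop = FALSE])
  }
  stopifnot(!anyNA(prob))
  data.frame(subject = seq_along(prob), fold = fold, probability = prob,
             label = as.numeric(prob >= 0.5), outcome = cohort$outcome)
}
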