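# Model-driven feature-weight extraction: connection-weight methods for
# the ANN, hyperplane coordinates for the linear SVM, impurity importances
# for tree ensembles, and recursive feature elimination for kernel SVMs.
# Extraction is always performed on a full-data refit, never per fold,
# because split-dependent weights are unstable.

#' Construct a feature-weight table
#'
#' Holds the per-feature raw contributions of an extraction method and
#' their normalization to relative weights (%) summing to 100:
#' `relative_weight[j] = 100 * raw_contribution[j] / sum(raw_contribution)`.
#'
#' @param feature_names Length-p labels.
#' @param raw_contribution Length-p nonnegative reals.
#' @param method One of `"cwm_garson"`, `"cwm_olden"`, `"svm_hyperplane"`,
#'   `"tree_impurity"`, `"rfe_rank"`.
#' @param source_model Free-text descriptor of the fitted model.
#' @return A data frame of class `feature_weight_table` with columns
#'   `feature`, `raw_contribution`, `relative_weight` and attributes
#'   `method`, `source_model`.
#' @export
feature_weight_table <- function(feature_names, raw_contribution, method,
                                 source_model = "") {
  method <- match.arg(method, c("cwm_garson", "cwm_olden", "svm_hyperplane",
                                "tree_impurity", "rfe_rank"))
  if (length(feature_names) != length(raw_contribution))
    stop("feature_names and raw_contribution lengths differ", call. = FALSE)
  if (any(raw_contribution < 0))
    stop("raw contributions must be nonnegative", call. = FALSE)
  total <- sum(raw_contribution)
  if (total <= 0) stop("raw contributions sum to zero", call. = FALSE)
  out <- data.frame(feature = as.character(feature_names),
                    raw_contribution = as.numeric(raw_contribution),
                    relative_weight = 100 * raw_contribution / total)
  class(out) <- c("feature_weight_table", "data.frame")
  attr(out, "method") <- method
  attr(out, "source_model") <- source_model
  out
}

#' @export
print.feature_weight_table <- function(x, ...) {
  cat(sprintf("<feature_weight_table> method = %s, source = %s\n",
              attr(x, "method"), attr(x, "source_model")))
  print.data.frame(x, digits = 5)
  invisible(x)
}

#' Connection-weight feature importance for a fitted network
#'
#' Computes per-feature importance from the input-to-hidden weight matrix
#' `W` (p x h) and hidden-to-output vector `v` of a single-hidden-layer
#' network. The `garson` variant normalizes the absolute products within
#' each hidden node, `Q[j,k] = |W[j,k] v[k]| / sum_j' |W[j',k] v[k]|`, and
#' sums over nodes, so raw contributions total exactly h. The `olden`
#' variant keeps the signed sums `c_j = sum_k W[j,k] v[k]` and takes their
#' absolute value. Both are normalized to relative weights (%).
#'
#' @param learner A `trained_learner` of kind `ann`.
#' @param variant `"garson"` (default) or `"olden"`.
#' @return A [feature_weight_table()].
#' @export
ann_connection_weights <- function(learner, variant = c("garson", "olden")) {
  variant <- match.arg(variant)
  if (!inherits(learner, "trained_learner") || learner$kind != "ann")
    stop("learner must be a trained_learner of kind 'ann'", call. = FALSE)
  if (learner$config$hidden_layers != 1L)
    stop("connection-weight extraction supports a single hidden layer only",
         call. = FALSE)
  W <- learner$parameters$W
  v <- learner$parameters$v
  raw <- if (variant == "garson") {
    prod_abs <- abs(sweep(W, 2, v, `*`))   # |W[j,k] * v[k]|
    node_tot <- colSums(prod_abs)
    if (any(node_tot == 0))
      stop("a hidden node has all-zero incoming contribution products",
           call. = FALSE)
    rowSums(sweep(prod_abs, 2, node_tot, `/`))
  } else {
    abs(as.numeric(W %*% v))
  }
  feature_weight_table(learner$feature_names, raw,
                       method = paste0("cwm_", variant),
                       source_model = sprintf("ann(h=%d)",
                                              learner$config$hidden_nodes))
}

#' Hyperplane feature importance for a linear SVM
#'
#' The coordinates of the vector orthogonal to the separating hyperplane,
#' `w = sum(alpha_i y_i x_i)`, taken in absolute value and normalized to
#' relative weights (%).
#'
#' @param learner A `trained_learner` of kind `svm_linear`.
#' @return A [feature_weight_table()].
#' @export
svm_hyperplane_weights <- function(learner) {
  if (!inherits(learner, "trained_learner") || learner$kind != "svm_linear")
    stop("hyperplane weights require a linear-kernel SVM learner", call. = FALSE)
  w <- learner$parameters$w
  feature_weight_table(learner$feature_names, abs(w),
                       method = "svm_hyperplane",
                       source_model = sprintf("svm_linear(C=%g)",
                                              learner$config$svm_cost))
}

#' Impurity-decrease feature importance for a tree ensemble
#'
#' Mean decrease in Gini impurity per feature across the ensemble,
#' normalized to relative weights (%).
#'
#' @param learner A `trained_learner` of kind `tree_ensemble`.
#' @return A [feature_weight_table()].
#' @export
tree_impurity_weights <- function(learner) {
  if (!inherits(learner, "trained_learner") || learner$kind != "tree_ensemble")
    stop("impurity weights require a tree_ensemble learner", call. = FALSE)
  imp <- learner$parameters$importance
  feature_weight_table(learner$feature_names, as.numeric(imp),
                       method = "tree_impurity",
                       source_model = sprintf("tree_ensemble(n=%d)",
                                              learner$config$n_trees))
}

# Dual objective contribution (1/2) a' K a of a fitted SVM, with the RBF
# kernel recomputed over the support vectors using only `cols`.
rbf_dual_term <- function(alpha, SV, gamma, cols) {
  S <- SV[, cols, drop = FALSE]
  d2 <- as.matrix(stats::dist(S))^2
  K <- exp(-gamma * d2)
  0.5 * as.numeric(t(alpha) %*% K %*% alpha)
}

#' Recursive feature elimination for a kernel SVM
#'
#' Repeatedly fits the RBF-kernel machine and removes the feature whose
#' removal least perturbs the dual objective, holding the multipliers
#' fixed: the criterion for feature f is
#' `|1/2 a'Ka - 1/2 a'K^(-f)a|` with `K^(-f)` the kernel recomputed
#' without feature f. Elimination order is recorded; rank 1 is the last
#' survivor. Ties break toward the lower feature index.
#'
#' @param cohort A [binary_cohort()] with p >= 2 features.
#' @param config A [learner_config()] of kind `svm_rbf` (default
#'   `learner_config("svm_rbf")`).
#' @return A data frame with columns `feature`, `rank` (1 = most
#'   important, i.e. the last survivor), and `eliminated_at` (the step at
#'   which the feature was removed, 1 = first removed).
#' @export
rfe_ranking <- function(cohort, config = learner_config("svm_rbf")) {
  if (config$kind != "svm_rbf")
    stop("rfe_ranking expects an svm_rbf learner_config", call. = FALSE)
  p <- ncol(cohort$features)
  if (p < 2L) stop("RFE needs at least two features", call. = FALSE)
  remaining <- seq_len(p)
  order_removed <- integer(0)
  while (length(remaining) > 1L) {
    sub <- binary_cohort(cohort$features[, remaining, drop = FALSE],
                         cohort$outcome)
    fit <- tryCatch(train_learner(sub, config), error = function(e) {
      err <- simpleError(sprintf("SVM fit failed during RFE: %s",
                                 conditionMessage(e)))
      err$partial_ranking <- order_removed
      stop(err)
    })
    alpha <- fit$parameters$alpha
    SV <- fit$parameters$support_vectors
    gamma <- fit$parameters$gamma
    full <- rbf_dual_term(alpha, SV, gamma, seq_along(remaining))
    crit <- vapply(seq_along(remaining), function(f)
      abs(full - rbf_dual_term(alpha, SV, gamma, setdiff(seq_along(remaining), f))),
      numeric(1))
    drop_local <- which.min(crit)  # first minimum = lowest index on ties
    order_removed <- c(order_removed, remaining[drop_local])
    remaining <- remaining[-drop_local]
  }
  order_removed <- c(order_removed, remaining)
  rank <- integer(p)
  rank[order_removed] <- rev(seq_len(p))
  data.frame(feature = cohort$feature_names, rank = rank,
             eliminated_at = match(seq_len(p), order_removed))
}

#' Write / read feature-weight tables
#'
#' CSV layout: columns `feature`, `raw_contribution`, `relative_weight`,
#' `method`. JSON carries the same fields plus `source_model`.
#'
#' @param table A [feature_weight_table()].
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path` invisibly for the writer; a [feature_weight_table()] for
#'   the reader.
#' @export
write_weight_table <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(method = attr(table, "method"),
           source_model = attr(table, "source_model"),
           feature = table$feature,
           raw_contribution = table$raw_contribution,
           relative_weight = table$relative_weight),
      path, auto_unbox = TRUE, digits = I(17))
  } else {
    df <- data.frame(feature = table$feature,
                     raw_contribution = table$raw_contribution,
                     relative_weight = table$relative_weight,
                     method = attr(table, "method"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    feature_weight_table(x$feature, x$raw_contribution, x$method,
                         x$source_model %||% "")
  } else {
    df <- read.csv(path)
    feature_weight_table(df$feature, df$raw_contribution,
                         df$method[1L], "")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
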