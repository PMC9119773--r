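# Additive prognostic index construction and the one-covariate logistic
# risk equation fitted on it.

#' Compute the additive prognostic index
#'
#' Replaces each "present" (1) entry of a subject's binary risk-factor row
#' with that feature's relative weight and sums: `PI = sum_j w_j x_j`.
#' Because relative weights sum to 100, the score lives on a 0-100 scale
#' (0 = no risk factor present, 100 = all present).
#'
#' @param features 0/1 row, matrix, or data frame; column names must match
#'   the weight table's features (any order).
#' @param weights A [feature_weight_table()].
#' @return An object of class `prognostic_index`: a numeric vector of
#'   scores with the weight table and its method attached as attributes.
#' @export
#' @examples
#' compute_pi(example_subject(), reference_weights("ann"))
compute_pi <- function(features, weights) {
  if (!inherits(weights, "feature_weight_table"))
    stop("weights must be a feature_weight_table", call. = FALSE)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  X <- as.matrix(features)
  if (is.null(colnames(X)))
    stop("features must carry column names matching the weight table",
         call. = FALSE)
  if (!setequal(colnames(X), weights$feature))
    stop("feature names do not match the weight table", call. = FALSE)
  X <- X[, weights$feature, drop = FALSE]
  assert_binary(X, "features")
  values <- as.numeric(X %*% weights$relative_weight)
  structure(values, class = "prognostic_index", weights = weights,
            method = attr(weights, "method"))
}

#' @export
print.prognostic_index <- function(x, ...) {
  cat(sprintf("<prognostic_index> %d subject(s), method = %s\n",
              length(x), attr(x, "method")))
  print(as.numeric(x))
  invisible(x)
}

#' Construct a risk equation
#'
#' The simple logistic model `logit P(case) = intercept +
#' confounder_coef * gender + pi_coef * PI`. Usually produced by
#' [fit_risk_equation()]; direct construction is useful for evaluating
#' published equations.
#'
#' @param intercept,confounder_coef,pi_coef Finite coefficients.
#' @param se,p_values Optional named numeric vectors (same names as the
#'   coefficients) of Wald standard errors and two-sided p-values.
#' @param label Free-text model label (e.g. `"ANN-RS"`).
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(intercept, confounder_coef = 0, pi_coef,
                          se = NULL, p_values = NULL, label = "") {
  coefs <- c(intercept = intercept, confounder = confounder_coef, pi = pi_coef)
  if (!all(is.finite(coefs))) stop("coefficients must be finite", call. = FALSE)
  structure(list(intercept = intercept, confounder_coef = confounder_coef,
                 pi_coef = pi_coef, se = se, p_values = p_values,
                 label = label),
            class = "risk_equation")
}

#' @export
format.risk_equation <- function(x, ...) {
  sprintf("z = %.3f %+.3f*Gender %+.3f*PI;  P(case) = 1/(1+exp(-z))",
          x$intercept, x$confounder_coef, x$pi_coef)
}

#' @export
print.risk_equation <- function(x, ...) {
  cat(sprintf("<risk_equation> %s\n  %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)", format(x)))
  invisible(x)
}

# Logistic regression by iteratively reweighted least squares with an
# optional ridge penalty (excluding the intercept). Returns coefficients,
# Wald SEs, p-values, convergence flag, and iteration trace.
irls_logistic <- function(X, y, ridge = 0, tol = 1e-8, max_iter = 100L) {
  beta <- numeric(ncol(X))
  penalty <- diag(c(0, rep(ridge, ncol(X) - 1L)), ncol(X))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / wt
    XtWX <- crossprod(X * wt, X) + penalty
    beta_new <- solve(XtWX, crossprod(X * wt, z))
    delta <- max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- as.numeric(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- as.numeric(X %*% beta)
  mu <- plogis(eta)
  wt <- pmax(mu * (1 - mu), 1e-12)
  cov_beta <- solve(crossprod(X * wt, X) + penalty)
  se <- sqrt(diag(cov_beta))
  list(beta = beta, se = se,
       p = 2 * pnorm(-abs(beta / se)),
       converged = converged, trace = trace, fitted = mu)
}

#' Fit the one-covariate logistic risk equation
#'
#' Maximum-likelihood logistic regression of the outcome on the prognostic
#' index (and an optional binary confounder) by iteratively reweighted
#' least squares; convergence when the maximum absolute coefficient change
#' drops below 1e-8, capped at 100 iterations. On perfect separation the
#' fit is flagged with a warning and ridge-stabilized estimates
#' (penalty 1e-4 on the slopes) are returned instead of divergent ones.
#'
#' @param pi Numeric prognostic-index values (e.g. from [compute_pi()]);
#'   must not be constant.
#' @param outcome 0/1 vector with both classes present.
#' @param confounder Optional 0/1 vector (e.g. gender). Retained in the
#'   equation even when matching makes it non-significant.
#' @param label Model label carried into the equation.
#' @return A [risk_equation()] with Wald standard errors and two-sided
#'   p-values.
#' @export
fit_risk_equation <- function(pi, outcome, confounder = NULL, label = "") {
  pi <- as.numeric(pi)
  assert_binary(outcome, "outcome")
  assert_both_classes(outcome)
  if (length(pi) != length(outcome))
    stop("pi and outcome lengths differ", call. = FALSE)
  if (stats::sd(pi) == 0)
    stop("prognostic index is constant; the model is degenerate", call. = FALSE)
  has_conf <- !is.null(confounder)
  if (has_conf) assert_binary(confounder, "confounder")
  X <- cbind(intercept = 1,
             if (has_conf) cbind(confounder = confounder),
             pi = pi)
  fit <- irls_logistic(X, outcome)
  separated <- !fit$converged || max(abs(fit$beta)) > 50
  if (separated) {
    warning("possible separation or non-convergence; ",
            "returning ridge-stabilized estimates", call. = FALSE)
    fit <- irls_logistic(X, outcome, ridge = 1e-4)
    if (!fit$converged)
      stop("risk-equation fit did not converge; iteration trace: ",
           paste(signif(utils::tail(fit$trace, 5), 3), collapse = ", "),
           call. = FALSE)
  }
  nm <- colnames(X)
  names(fit$beta) <- names(fit$se) <- names(fit$p) <- nm
  risk_equation(
    intercept = fit$beta[["intercept"]],
    confounder_coef = if (has_conf) fit$beta[["confounder"]] else 0,
    pi_coef = fit$beta[["pi"]],
    se = fit$se, p_values = fit$p, label = label)
}

#' Predicted case probability from a risk equation
#'
#' `P(case) = 1 / (1 + exp(-(intercept + confounder_coef * confounder +
#' pi_coef * pi)))`; vectorized over subjects.
#'
#' @param eq A [risk_equation()].
#' @param confounder 0/1 value(s); use 0 when the equation has no
#'   confounder term.
#' @param pi_value Prognostic-index value(s).
#' @return Probabilities strictly in (0, 1) for finite inputs.
#' @export
#' @examples
#' predict_risk(reference_equation("ANN-RS"), confounder = 1, pi_value = 40.12)
predict_risk <- function(eq, confounder = 0, pi_value) {
  if (!inherits(eq, "risk_equation"))
    stop("eq must be a risk_equation", call. = FALSE)
  z <- eq$intercept + eq$confounder_coef * confounder + eq$pi_coef * pi_value
  plogis(z)
}

#' Weight-substituted audit matrix
#'
#' The transformed data set in which each "1" entry is replaced by the
#' feature's relative weight; row sums equal the prognostic index. Kept
#' for audit output only — modelling uses [compute_pi()] directly.
#'
#' @inheritParams compute_pi
#' @return A numeric matrix with one column per feature.
#' @export
weight_substituted_matrix <- function(features, weights) {
  X <- as.matrix(features)
  X <- X[, weights$feature, drop = FALSE]
  assert_binary(X, "features")
  sweep(X, 2, weights$relative_weight, `*`)
}

#' Export / import a risk equation as JSON
#'
#' Round trip preserves predictions exactly (coefficients serialized at
#' full precision).
#'
#' @param eq A [risk_equation()].
#' @param path JSON file path.
#' @return `path` invisibly for the writer; a [risk_equation()] for the
#'   reader.
#' @export
write_risk_equation <- function(eq, path) {
  jsonlite::write_json(
    list(label = eq$label, intercept = eq$intercept,
         confounder_coef = eq$confounder_coef, pi_coef = eq$pi_coef,
         se = as.list(eq$se), p_values = as.list(eq$p_values),
         equation = format(eq)),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_risk_equation
#' @export
read_risk_equation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_equation(intercept = x$intercept, confounder_coef = x$confounder_coef,
                pi_coef = x$pi_coef,
                se = if (length(x$se)) unlist(x$se),
                p_values = if (length(x$p_values)) unlist(x$p_values),
                label = x$label %||% "")
}
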