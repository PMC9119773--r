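# Confusion-matrix metrics, AUC, RMSE, and the model-selection scoreboard.

#' Build a confusion matrix from counts or predictions
#'
#' Counts follow the case-control convention: `tp` cases predicted cases,
#' `fn` cases predicted controls, `fp` controls predicted cases, `tn`
#' controls predicted controls.
#'
#' @param tp,fn,fp,tn Nonnegative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
#' @examples
#' confusion_matrix(187, 43, 46, 184)
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) == 0) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param predicted 0/1 vector of hard labels.
#' @param outcome 0/1 vector of true labels.
#' @export
confusion_from_predictions <- function(predicted, outcome) {
  assert_binary(predicted, "predicted"); assert_binary(outcome, "outcome")
  if (length(predicted) != length(outcome))
    stop("predicted and outcome lengths differ", call. = FALSE)
  confusion_matrix(tp = sum(predicted == 1 & outcome == 1),
                   fn = sum(predicted == 0 & outcome == 1),
                   fp = sum(predicted == 1 & outcome == 0),
                   tn = sum(predicted == 0 & outcome == 0))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("case", "control"),
                              predicted = c("case", "control")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy (percent), sensitivity, specificity, and Cohen's kappa.
#' Kappa is `(p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (tp + tn)/n` and chance agreement
#' `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`.
#'
#' @param cm A [confusion_matrix()].
#' @return A list with `accuracy` (percent), `sensitivity`, `specificity`,
#'   `kappa`.
#' @export
#' @examples
#' confusion_metrics(confusion_matrix(187, 43, 46, 184))
confusion_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop("cm must be a confusion_matrix",
                                              call. = FALSE)
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (cm$tp + cm$fn == 0 || cm$fp + cm$tn == 0)
    stop("both outcome classes must be present", call. = FALSE)
  p_o <- (cm$tp + cm$tn) / n
  p_e <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
          (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  list(accuracy = 100 * p_o,
       sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$fp + cm$tn),
       kappa = if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of case-control
#' pairs in which the case receives the higher probability, ties counted
#' one half. Invariant under strictly increasing transforms of the scores.
#'
#' @param probabilities Numeric scores (higher = more case-like).
#' @param outcome 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(probabilities, outcome) {
  assert_binary(outcome, "outcome")
  assert_both_classes(outcome)
  if (length(probabilities) != length(outcome))
    stop("probabilities and outcome lengths differ", call. = FALSE)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  r <- rank(probabilities)  # midranks handle ties as 1/2
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Root mean square error of probabilistic predictions
#'
#' Square root of the mean squared difference between predicted
#' probability and the 0/1 outcome; its square is the Brier score.
#'
#' @inheritParams auc
#' @return Nonnegative real.
#' @export
rmse <- function(probabilities, outcome) {
  if (length(probabilities) != length(outcome))
    stop("probabilities and outcome lengths differ", call. = FALSE)
  sqrt(mean((probabilities - outcome)^2))
}

#' Assemble the six-metric performance report
#'
#' Accuracy, sensitivity, specificity, kappa from the hard labels
#' (threshold 0.5 unless `predicted` is supplied), plus AUC and RMSE from
#' the probabilities.
#'
#' @inheritParams auc
#' @param predicted Optional 0/1 hard labels; default `probabilities >= 0.5`.
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `kappa`,
#'   `auc`, `rmse`, and the underlying `confusion` matrix.
#' @export
performance_report <- function(probabilities, outcome, predicted = NULL) {
  if (is.null(predicted)) predicted <- as.numeric(probabilities >= 0.5)
  cm <- confusion_from_predictions(predicted, outcome)
  c(confusion_metrics(cm),
    list(auc = auc(probabilities, outcome),
         rmse = rmse(probabilities, outcome),
         confusion = cm))
}

metric_names <- c("accuracy", "sensitivity", "specificity", "kappa", "auc", "rmse")

#' Scoreboard of candidates against a baseline
#'
#' For each candidate report, counts on how many of the six criteria
#' (accuracy, sensitivity, specificity, kappa, AUC higher; RMSE lower) it
#' is strictly better than the baseline; ties are not fulfilled.
#' Candidates with more than `select_above` fulfilled criteria are
#' selected for weight extraction.
#'
#' @param candidates Named list of reports, each containing the six metrics.
#' @param baseline A report with the six metrics (typically the logistic
#'   regression model).
#' @param select_above Selection cut: a candidate is selected when its
#'   fulfilled count exceeds this value (default 3).
#' @return A data frame with one row per candidate: per-metric fulfilled
#'   flags, `fulfilled` count out of 6, and `selected`.
#' @export
#' @examples
#' perf <- reference_performance("learner")
#' reports <- split(perf[metric_columns()], perf$model)
#' criteria_scoreboard(reports[setdiff(names(reports), "LR")], reports$LR)
criteria_scoreboard <- function(candidates, baseline, select_above = 3) {
  check <- function(rep, who) {
    missing <- setdiff(metric_names, names(rep))
    if (length(missing))
      stop(sprintf("report '%s' is missing metric(s): %s", who,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  check(baseline, "baseline")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be a named list", call. = FALSE)
  rows <- lapply(names(candidates), function(nm) {
    rep <- candidates[[nm]]
    check(rep, nm)
    flags <- vapply(metric_names, function(m) {
      if (m == "rmse") rep[[m]] < baseline[[m]] else rep[[m]] > baseline[[m]]
    }, logical(1))
    data.frame(model = nm, t(flags), fulfilled = sum(flags),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$fulfilled > select_above
  rownames(out) <- NULL
  out
}

#' Names of the six scoreboard metrics
#'
#' @return Character vector: accuracy, sensitivity, specificity, kappa,
#'   auc, rmse.
#' @export
metric_columns <- function() metric_names
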