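# Accessors for the bundled NLHRS reference tables: the feature-weight
# tables extracted from the finalized ANN and linear-SVM cardiovascular
# models, the fitted risk equations, and the reported performance and
# validation figures they came with. These serve as worked-example inputs
# and as regression anchors for the arithmetic in this package.

ref_path <- function(file) {
  system.file("extdata", file, package = "riskdistill", mustWork = TRUE)
}

#' Bundled reference feature-weight tables
#'
#' Relative feature weights for the 13 nonlaboratory cardiovascular risk
#' factors of the NLHRS heart risk score, as extracted from a finalized
#' single-hidden-layer ANN (connection-weight method; raw contributions sum
#' to the 7 hidden nodes) and a linear SVM (absolute hyperplane
#' coordinates).
#'
#' @param model `"ann"` or `"svm"`.
#' @param relative `"recomputed"` (default) renormalizes the bundled raw
#'   contributions to percentages at full precision; `"published"` takes
#'   the bundled percentage column verbatim (the two differ by under 0.01
#'   points because the raw contributions are stored at 3 decimals).
#' @return A [feature_weight_table()] with the bundled raw contributions
#'   and relative weights (%). The published percentage column is kept in
#'   `published_relative_weight` either way.
#' @export
#' @examples
#' reference_weights("ann")
reference_weights <- function(model = c("ann", "svm"),
                              relative = c("recomputed", "published")) {
  model <- match.arg(model)
  relative <- match.arg(relative)
  df <- read.csv(ref_path("reference_feature_weights.csv"))
  raw <- if (relative == "published") df[[paste0(model, "_relative")]]
         else df[[paste0(model, "_raw")]]
  tab <- feature_weight_table(
    feature_names = df$feature,
    raw_contribution = raw,
    method = if (model == "ann") "cwm_garson" else "svm_hyperplane",
    source_model = paste0("reference_", model, "_", relative))
  tab$published_relative_weight <- df[[paste0(model, "_relative")]]
  tab$label <- df$label
  tab
}

#' Bundled reference risk equations
#'
#' The gender-adjusted one-covariate logistic risk equations of the two
#' NLHRS prognostic indices: ANN-RS (intercept -5.659, gender 0.107,
#' PI 0.160) and SVM-RS (intercept -6.131, gender 0.415, PI 0.174).
#'
#' @param label `"ANN-RS"` or `"SVM-RS"`.
#' @return A [risk_equation()].
#' @export
reference_equation <- function(label = c("ANN-RS", "SVM-RS")) {
  label <- match.arg(label)
  eqs <- jsonlite::read_json(ref_path("reference_risk_equations.json"))
  e <- eqs[[label]]
  risk_equation(intercept = e$intercept, confounder_coef = e$confounder_coef,
                pi_coef = e$pi_coef, label = e$label)
}

#' Bundled reference confusion matrices and performance tables
#'
#' Confusion matrices (counts: tp, fn, fp, tn on a 460-subject matched
#' cohort) and the printed six-metric performance rows for the five
#' candidate learners (`stage = "learner"`) and the two score-based
#' risk prediction models (`stage = "risk_score"`).
#'
#' @param stage `"learner"`, `"risk_score"`, or `"all"`.
#' @return A data frame.
#' @export
reference_confusion <- function(stage = c("all", "learner", "risk_score")) {
  stage <- match.arg(stage)
  df <- read.csv(ref_path("reference_confusion_matrices.csv"))
  if (stage != "all") df <- df[df$stage == stage, , drop = FALSE]
  df
}

#' @rdname reference_confusion
#' @export
reference_performance <- function(stage = c("all", "learner", "risk_score")) {
  stage <- match.arg(stage)
  df <- read.csv(ref_path("reference_performance.csv"))
  if (stage != "all") df <- df[df$stage == stage, , drop = FALSE]
  df
}

#' Bundled reference validation statistics
#'
#' Brier score, Spiegelhalter's Z (with p-value), Hosmer-Lemeshow H
#' statistic (with p-value), and AUC reported for the ANN-RS and SVM-RS
#' risk prediction models.
#'
#' @return A data frame with one row per model.
#' @export
reference_validation <- function() {
  read.csv(ref_path("reference_validation.csv"))
}

#' Bundled worked-example subject
#'
#' A subject positive for physical inactivity, smoking history,
#' high-salty-food consumption, hypertension, and diabetes mellitus (all
#' other risk factors absent), used in the worked example of the
#' prognostic-index computation.
#'
#' @return A one-row 0/1 matrix with the 13 reference feature columns.
#' @export
example_subject <- function() {
  df <- read.csv(ref_path("example_subjects.csv"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject
  m
}
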