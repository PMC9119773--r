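# End-to-end pipeline: cohort -> learners + CV -> scoreboard -> weight
# extraction -> prognostic index -> risk equation -> validation, with all
# artifacts written to disk and summarized in a re-runnable manifest.

#' Configure a full pipeline run
#'
#' @param cohort A [binary_cohort()], a [cohort_spec()] to simulate from,
#'   or a path to a cohort CSV readable by [load_cohort()].
#' @param learners Named list of candidate [learner_config()]s (the
#'   baseline excluded). Default: ann, svm_linear, svm_rbf, tree_ensemble
#'   at reference settings.
#' @param cv A [cv_plan()] (default tenfold stratified).
#' @param select_above Scoreboard selection cut (see
#'   [criteria_scoreboard()]).
#' @param weights Optional [feature_weight_table()] (or path to one
#'   written by [write_weight_table()]): skip training/selection and build
#'   the score directly from these weights.
#' @param weights_label Model name used for artifacts and equation labels
#'   when `weights` is supplied (default: the weight table's method).
#' @param output_dir Directory for artifacts; created if missing.
#' @param seed Integer master seed; propagated to simulation, fold
#'   assignment, and every learner.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, learners = NULL, cv = NULL,
                            select_above = 3, weights = NULL,
                            weights_label = NULL,
                            output_dir = tempfile("riskdistill_run_"),
                            seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(learners))
    learners <- list(
      ann = learner_config("ann", seed = seed),
      svm_linear = learner_config("svm_linear", seed = seed),
      svm_rbf = learner_config("svm_rbf", seed = seed),
      tree_ensemble = learner_config("tree_ensemble", seed = seed))
  if (is.null(cv)) cv <- cv_plan(10L, stratified = TRUE, seed = seed)
  structure(list(cohort = cohort, learners = learners, cv = cv,
                 select_above = select_above, weights = weights,
                 weights_label = weights_label,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

resolve_cohort <- function(x, seed) {
  if (inherits(x, "binary_cohort")) return(x)
  if (inherits(x, "cohort_spec")) return(simulate_cohort(x))
  if (is.character(x) && length(x) == 1L) return(load_cohort(x))
  stop("cohort must be a binary_cohort, a cohort_spec, or a CSV path",
       call. = FALSE)
}

extractor_for <- function(kind) {
  switch(kind,
         ann = function(tl) ann_connection_weights(tl, "garson"),
         svm_linear = svm_hyperplane_weights,
         tree_ensemble = tree_impurity_weights,
         NULL)  # svm_rbf yields ranks only, not percentage weights
}

#' Run the full score-distillation pipeline
#'
#' Executes: cohort simulation/loading; cross-validated benchmarking of
#' the candidate learners against the logistic baseline; the six-criterion
#' scoreboard; feature-weight extraction from the selected models (refit
#' once on the full data); prognostic-index construction; the
#' gender-adjusted one-covariate logistic risk equation; and the
#' validation battery. One log line is emitted per stage. All artifacts
#' (cohort, CV predictions, performance table, scoreboard, weight tables,
#' equations, validation reports, calibration tables) are written under
#' `config$output_dir` and listed in the returned manifest.
#'
#' When `config$weights` is supplied, training and selection are skipped
#' and the score stages run directly on those weights.
#'
#' If no candidate beats the baseline on more than `select_above`
#' criteria, the pipeline stops after the scoreboard with status
#' `"no model selected"`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `run_manifest`: a list with `status`,
#'   `config` echo, `version`, `artifacts` (named file paths), and
#'   per-stage `summaries`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  artifacts <- character(0)
  summaries <- list()
  manifest <- function(status) {
    m <- structure(list(status = status,
                        version = as.character(packageVersion("riskdistill")),
                        seed = config$seed,
                        output_dir = config$output_dir,
                        artifacts = artifacts, summaries = summaries),
                   class = "run_manifest")
    jsonlite::write_json(unclass(m), out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    m
  }

  cohort <- resolve_cohort(config$cohort, config$seed)
  write_cohort(cohort, out("cohort.csv"))
  artifacts["cohort"] <- out("cohort.csv")
  message(sprintf("[cohort] %d subjects, %d features, %d cases",
                  length(cohort$outcome), ncol(cohort$features),
                  sum(cohort$outcome)))
  summaries$cohort <- list(n = length(cohort$outcome),
                           p = ncol(cohort$features),
                           cases = sum(cohort$outcome))

  fixed <- config$weights
  if (is.character(fixed)) fixed <- read_weight_table(fixed)
  selected_weights <- list()

  if (is.null(fixed)) {
    baseline_cfg <- learner_config("logistic", seed = config$seed)
    all_cfg <- c(list(logistic = baseline_cfg), config$learners)
    reports <- list()
    cv_rows <- list()
    for (nm in names(all_cfg)) {
      cv_pred <- cross_validate(cohort, all_cfg[[nm]], config$cv)
      reports[[nm]] <- performance_report(cv_pred$probability, cohort$outcome)
      cv_pred$model <- nm
      cv_rows[[nm]] <- cv_pred
    }
    cv_all <- do.call(rbind, cv_rows)
    write.csv(cv_all, out("cv_predictions.csv"), row.names = FALSE)
    artifacts["cv_predictions"] <- out("cv_predictions.csv")
    perf <- do.call(rbind, lapply(names(reports), function(nm)
      data.frame(model = nm,
                 as.data.frame(reports[[nm]][metric_columns()]))))
    write.csv(perf, out("performance.csv"), row.names = FALSE)
    artifacts["performance"] <- out("performance.csv")
    message(sprintf("[train+cv] %d models benchmarked; baseline AUC %.3f",
                    length(reports), reports$logistic$auc))
    summaries$performance <- perf

    board <- criteria_scoreboard(reports[names(config$learners)],
                                 reports$logistic,
                                 select_above = config$select_above)
    write.csv(board, out("scoreboard.csv"), row.names = FALSE)
    artifacts["scoreboard"] <- out("scoreboard.csv")
    message(sprintf("[scoreboard] fulfilled: %s",
                    paste(sprintf("%s %d/6", board$model, board$fulfilled),
                          collapse = ", ")))
    summaries$scoreboard <- board
    sel <- board$model[board$selected]
    if (!length(sel)) {
      message("[select] no model outperformed the baseline; stopping")
      return(manifest("no model selected"))
    }
    message(sprintf("[select] selected: %s", paste(sel, collapse = ", ")))
    # kernel machines yield an elimination ranking rather than percentage
    # weights; record the ranking and build scores from the other winners
    rank_only <- sel[vapply(sel, function(nm)
      is.null(extractor_for(config$learners[[nm]]$kind)), logical(1))]
    for (nm in rank_only) {
      rk <- rfe_ranking(cohort, config$learners[[nm]])
      f <- out(sprintf("rfe_ranking_%s.csv", nm))
      write.csv(rk, f, row.names = FALSE, quote = FALSE)
      artifacts[paste0("rfe_ranking_", nm)] <- f
      message(sprintf("[weights] %s: rank-only extractor; top feature %s",
                      nm, rk$feature[rk$rank == 1]))
    }
    sel <- setdiff(sel, rank_only)
    if (!length(sel)) {
      message("[select] selected models support ranking only; stopping ",
              "before score construction")
      return(manifest("no percentage-weight model selected"))
    }

    for (nm in sel) {
      full_fit <- train_learner(cohort, config$learners[[nm]])
      tab <- extractor_for(full_fit$kind)(full_fit)
      selected_weights[[nm]] <- tab
      write_weight_table(tab, out(sprintf("weights_%s.json", nm)))
      artifacts[paste0("weights_", nm)] <- out(sprintf("weights_%s.json", nm))
      top <- tab$feature[which.max(tab$relative_weight)]
      message(sprintf("[weights] %s: top feature %s (%.2f%%)", nm, top,
                      max(tab$relative_weight)))
    }
  } else {
    nm <- config$weights_label %||% attr(fixed, "method")
    selected_weights[[nm]] <- fixed
    message(sprintf("[weights] using supplied weight table (%s)",
                    attr(fixed, "method")))
  }

  validation_rows <- list()
  for (nm in names(selected_weights)) {
    tab <- selected_weights[[nm]]
    pi <- compute_pi(cohort$features, tab)
    eq <- fit_risk_equation(pi, cohort$outcome, cohort$confounder,
                            label = paste0(nm, "-RS"))
    write_risk_equation(eq, out(sprintf("equation_%s.json", nm)))
    artifacts[paste0("equation_", nm)] <- out(sprintf("equation_%s.json", nm))
    message(sprintf("[score] %s: PI coefficient %.3f (p = %.2g)", eq$label,
                    eq$pi_coef, eq$p_values[["pi"]]))
    rep <- validate_model(eq, cohort, pi)
    files <- write_validation_report(rep, out(sprintf("validation_%s.csv", nm)))
    artifacts[paste0("validation_", nm)] <- files[1L]
    artifacts[paste0("calibration_", nm)] <- files[2L]
    message(sprintf(
      "[validate] %s: Brier %.3f, Z p %.3f, H %.2f (p %.3f), AUC %.3f",
      eq$label, rep$brier, rep$spiegelhalter$p_value, rep$hosmer_lemeshow$h,
      rep$hosmer_lemeshow$p_value, rep$auc))
    validation_rows[[nm]] <- data.frame(
      model = eq$label, brier = rep$brier, z = rep$spiegelhalter$z,
      z_p = rep$spiegelhalter$p_value, h = rep$hosmer_lemeshow$h,
      h_p = rep$hosmer_lemeshow$p_value, auc = rep$auc)
    summaries[[paste0("equation_", nm)]] <- list(
      label = eq$label, intercept = eq$intercept,
      confounder_coef = eq$confounder_coef, pi_coef = eq$pi_coef)
  }
  summaries$validation <- do.call(rbind, validation_rows)
  manifest("complete")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> status: %s (seed %d)\n", x$status, x$seed))
  cat("  artifacts:\n")
  for (nm in names(x$artifacts))
    cat(sprintf("    %s: %s\n", nm, x$artifacts[[nm]]))
  invisible(x)
}
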