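# Matched case-control cohort simulation and the binary cohort container.

#' Specify a synthetic matched case-control cohort
#'
#' A `cohort_spec` fixes every parameter of the generative model used by
#' [simulate_cohort()]: cohort size, the binary risk-factor features with
#' their ground-truth additive importances, control-group exposure
#' prevalences, the scale mapping importances to case/control log-odds
#' shifts, the matching design, and the seed. The defaults emulate a
#' 1:1 gender-matched cardiovascular case-control study of 460 subjects
#' with 13 binary nonlaboratory risk factors.
#'
#' @param n_subjects Total number of subjects. Must be even when `matched`.
#' @param feature_names Character vector of unique feature labels.
#' @param true_weights Nonnegative reals, one per feature: the ground-truth
#'   additive importance of each feature. Defaults to the bundled reference
#'   ANN relative weights (see [reference_weights()]).
#' @param baseline_prevalence Exposure probability of each feature among
#'   controls, each in (0, 1).
#' @param effect_scale Nonnegative scalar; feature `j` is sampled in cases
#'   with log-odds shifted by `effect_scale * true_weights[j]`. The default
#'   0.123 puts the true generating model at an AUC of about 0.88 for the
#'   default weights and prevalences.
#' @param matched If `TRUE` (default), exactly half the subjects are cases
#'   and each case shares its gender with a paired control.
#' @param confounder_prevalence Probability a subject (pair, when matched)
#'   is female; default 0.322.
#' @param age Optional list with elements `mean`, `sd`, `case_shift` giving
#'   a Gaussian age distribution (years) and an additive mean shift for
#'   cases; set to `NULL` to omit the continuous age column.
#' @param seed Integer seed; identical specs produce identical cohorts.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [dichotomize_continuous()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 80, seed = 7)
#' cohort <- simulate_cohort(spec)
#' table(cohort$outcome)
cohort_spec <- function(n_subjects = 460L,
                        feature_names = reference_weights("ann")$feature,
                        true_weights = reference_weights("ann")$relative_weight,
                        baseline_prevalence = NULL,
                        effect_scale = 0.123,
                        matched = TRUE,
                        confounder_prevalence = 0.322,
                        age = list(mean = 48, sd = 11.31, case_shift = 6),
                        seed = 1L) {
  p <- length(feature_names)
  if (is.null(baseline_prevalence))
    baseline_prevalence <- seq(0.15, 0.45, length.out = p)
  if (n_subjects < 2L || p < 1L)
    stop("n_subjects and the number of features must be positive", call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("feature_names must be unique", call. = FALSE)
  if (length(true_weights) != p || length(baseline_prevalence) != p)
    stop("true_weights and baseline_prevalence must match feature_names in length",
         call. = FALSE)
  if (any(true_weights < 0)) stop("true_weights must be nonnegative", call. = FALSE)
  if (any(baseline_prevalence <= 0 | baseline_prevalence >= 1))
    stop("baseline_prevalence values must lie strictly in (0, 1)", call. = FALSE)
  if (effect_scale < 0) stop("effect_scale must be nonnegative", call. = FALSE)
  if (confounder_prevalence <= 0 || confounder_prevalence >= 1)
    stop("confounder_prevalence must lie strictly in (0, 1)", call. = FALSE)
  if (matched && n_subjects %% 2L != 0L)
    stop("a matched design needs an even n_subjects", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_features = p,
         feature_names = as.character(feature_names),
         true_weights = as.numeric(true_weights),
         baseline_prevalence = as.numeric(baseline_prevalence),
         effect_scale = as.numeric(effect_scale),
         matched = isTRUE(matched),
         confounder_prevalence = as.numeric(confounder_prevalence),
         age = age,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Construct a validated binary cohort
#'
#' The subject-level container used throughout the package: an n-by-p 0/1
#' feature matrix, a binary outcome (1 = case), an optional binary
#' confounder (1 = female), and optional named continuous columns such as
#' age in years.
#'
#' @param features Numeric matrix (or data frame) with entries in {0, 1}
#'   and column names.
#' @param outcome Length-n vector in {0, 1}.
#' @param confounder Optional length-n vector in {0, 1}.
#' @param continuous Optional named list / data frame of length-n numeric
#'   columns kept alongside the binary features.
#' @return An object of class `binary_cohort` with elements `features`,
#'   `outcome`, `confounder`, `continuous`, `feature_names`.
#' @export
binary_cohort <- function(features, outcome, confounder = NULL,
                          continuous = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0L || ncol(features) == 0L)
    stop("features must have at least one row and one column", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature_", seq_len(ncol(features)))
  storage.mode(features) <- "double"
  assert_binary(features, "features")
  if (length(outcome) != nrow(features))
    stop("outcome length must equal the number of feature rows", call. = FALSE)
  assert_binary(outcome, "outcome")
  if (!is.null(confounder)) {
    if (length(confounder) != nrow(features))
      stop("confounder length must equal the number of feature rows", call. = FALSE)
    assert_binary(confounder, "confounder")
  }
  if (!is.null(continuous)) {
    continuous <- as.data.frame(continuous)
    if (nrow(continuous) != nrow(features))
      stop("continuous columns must have one row per subject", call. = FALSE)
  }
  structure(
    list(features = features,
         outcome = as.integer(outcome),
         confounder = if (!is.null(confounder)) as.integer(confounder),
         continuous = continuous,
         feature_names = colnames(features)),
    class = "binary_cohort")
}

#' @export
print.binary_cohort <- function(x, ...) {
  cat(sprintf("<binary_cohort> %d subjects (%d cases / %d controls), %d binary features\n",
              length(x$outcome), sum(x$outcome), sum(1 - x$outcome),
              ncol(x$features)))
  if (!is.null(x$confounder))
    cat(sprintf("  confounder: %.1f%% positive\n", 100 * mean(x$confounder)))
  if (!is.null(x$continuous))
    cat("  continuous columns:", paste(names(x$continuous), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a matched case-control cohort with known feature effects
#'
#' Case status is assigned first (exactly half cases under matching);
#' feature `j` is then drawn Bernoulli with
#' `logit(p) = logit(baseline_prevalence[j]) + effect_scale * true_weights[j] * outcome`,
#' so the spec's `true_weights` are, by construction, the additive signal a
#' downstream weight extractor should recover. Gender is drawn independently
#' of outcome and shared within matched pairs, reproducing a matching design
#' that removes the confounder's marginal association.
#'
#' @param spec A [cohort_spec()].
#' @return A [binary_cohort()]; when `spec$age` is set, a continuous `age`
#'   column is attached.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("spec must be a cohort_spec", call. = FALSE)
  n <- spec$n_subjects
  p <- spec$n_features
  with_seed(spec$seed, {
    if (spec$matched) {
      # adjacent (case, control) pairs sharing gender
      outcome <- rep(c(1L, 0L), times = n / 2L)
      pair_gender <- rbinom(n / 2L, 1L, spec$confounder_prevalence)
      confounder <- rep(pair_gender, each = 2L)
    } else {
      outcome <- rbinom(n, 1L, 0.5)
      confounder <- rbinom(n, 1L, spec$confounder_prevalence)
    }
    base_logit <- qlogis(spec$baseline_prevalence)
    shift <- spec$effect_scale * spec$true_weights
    features <- matrix(0, n, p, dimnames = list(NULL, spec$feature_names))
    for (j in seq_len(p)) {
      prob <- plogis(base_logit[j] + shift[j] * outcome)
      features[, j] <- rbinom(n, 1L, prob)
    }
    continuous <- NULL
    if (!is.null(spec$age)) {
      age <- rnorm(n, spec$age$mean + spec$age$case_shift * (outcome - 0.5),
                   spec$age$sd)
      continuous <- data.frame(age = age)
    }
    binary_cohort(features, outcome, confounder, continuous)
  })
}

#' True case probability under a cohort spec's generating model
#'
#' Posterior probability of being a case given a feature row, by Bayes'
#' rule on the class-conditional Bernoulli model of [simulate_cohort()]
#' (equal priors under matching). Useful as the oracle predictor when
#' checking calibration statistics against a perfectly specified model.
#'
#' @param spec A [cohort_spec()].
#' @param features 0/1 matrix with `spec$n_features` columns.
#' @return Numeric vector of case probabilities.
#' @export
true_case_probability <- function(spec, features) {
  features <- as.matrix(features)
  p0 <- spec$baseline_prevalence
  p1 <- plogis(qlogis(p0) + spec$effect_scale * spec$true_weights)
  # log-likelihood ratio of case vs control; equal class priors
  llr <- features %*% log(p1 / p0) + (1 - features) %*% log((1 - p1) / (1 - p0))
  as.numeric(plogis(llr))
}

#' Dichotomize a continuous variable at its most discriminative cut-point
#'
#' Scans every midpoint between adjacent sorted unique values and returns
#' the threshold maximizing the Pearson chi-square statistic of the 2x2
#' table of dichotomized value against outcome (no continuity correction).
#' Ties are broken toward the lower threshold. This is the data-driven
#' binning used to turn age in years into a binary "age groups" feature.
#'
#' @param values Finite numeric vector, length >= 4.
#' @param outcome 0/1 vector of the same length with both classes present.
#' @return A list with `threshold` (the cut-point), `groups` (0/1 vector,
#'   1 where `values > threshold`), and `statistic` (the chi-square value).
#' @export
#' @examples
#' dichotomize_continuous(c(30, 35, 60, 65), c(0, 0, 1, 1))
dichotomize_continuous <- function(values, outcome) {
  if (length(values) != length(outcome) || length(values) < 4L)
    stop("values and outcome must be the same length, at least 4", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  assert_binary(outcome, "outcome")
  assert_both_classes(outcome)
  u <- sort(unique(values))
  if (length(u) < 2L)
    stop("values are constant; no valid split exists", call. = FALSE)
  cand <- (u[-length(u)] + u[-1L]) / 2
  n <- length(values)
  n_case <- sum(outcome)
  stat <- vapply(cand, function(thr) {
    g <- as.numeric(values > thr)
    a <- sum(g == 1 & outcome == 1); b <- sum(g == 1 & outcome == 0)
    c_ <- n_case - a; d <- n - a - b - c_
    r1 <- a + b; r2 <- c_ + d
    denom <- r1 * r2 * n_case * (n - n_case)
    if (denom == 0) return(-Inf)
    n * (a * d - b * c_)^2 / denom
  }, numeric(1))
  best <- which.max(stat)  # first maximum = lowest threshold on ties
  list(threshold = cand[best],
       groups = as.numeric(values > cand[best]),
       statistic = stat[best])
}

#' Write a binary cohort to CSV
#'
#' One subject per row: feature columns, optional continuous columns,
#' `gender` (when a confounder is present) and `outcome`. UTF-8,
#' comma-delimited, header row.
#'
#' @param cohort A [binary_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort$features)
  if (!is.null(cohort$continuous)) df <- cbind(df, cohort$continuous)
  if (!is.null(cohort$confounder)) df$gender <- cohort$confounder
  df$outcome <- cohort$outcome
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary cohort from CSV
#'
#' Validates that the declared columns exist and that every feature,
#' outcome, and confounder entry is exactly 0 or 1; offending cells are
#' reported with their row and column.
#'
#' @param path CSV file with a header row.
#' @param feature_cols Feature column names; default: every column except
#'   `outcome_col`, `confounder_col`, and `continuous_cols`.
#' @param outcome_col Name of the 0/1 outcome column.
#' @param confounder_col Optional name of a 0/1 confounder column; `NULL`
#'   if absent.
#' @param continuous_cols Optional names of continuous columns to carry
#'   along (e.g. `"age"`).
#' @return A [binary_cohort()].
#' @export
load_cohort <- function(path, feature_cols = NULL, outcome_col = "outcome",
                        confounder_col = "gender", continuous_cols = "age") {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("file '%s' has no data rows", path), call. = FALSE)
  if (!is.null(confounder_col) && !confounder_col %in% names(df)) confounder_col <- NULL
  continuous_cols <- intersect(continuous_cols, names(df))
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(df), c(outcome_col, confounder_col, continuous_cols))
  missing <- setdiff(c(feature_cols, outcome_col), names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  check01 <- function(col) {
    bad <- which(is.na(df[[col]]) | !df[[col]] %in% c(0, 1))
    if (length(bad))
      stop(sprintf("non-binary value in column '%s' at row %d (value: %s)",
                   col, bad[1L], as.character(df[[col]][bad[1L]])), call. = FALSE)
  }
  for (col in c(feature_cols, outcome_col, confounder_col)) check01(col)
  binary_cohort(
    features = as.matrix(df[feature_cols]),
    outcome = df[[outcome_col]],
    confounder = if (!is.null(confounder_col)) df[[confounder_col]],
    continuous = if (length(continuous_cols)) df[continuous_cols])
}

#' Serialize a cohort spec to a key-value config file
#'
#' Keys are exactly the `cohort_spec` field names; vectors are
#' comma-separated. [read_cohort_spec()] inverts the format.
#'
#' @param spec A [cohort_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  fmt <- function(x) paste(x, collapse = ",")
  lines <- c(
    paste0("n_subjects=", spec$n_subjects),
    paste0("feature_names=", fmt(spec$feature_names)),
    paste0("true_weights=", fmt(spec$true_weights)),
    paste0("baseline_prevalence=", fmt(spec$baseline_prevalence)),
    paste0("effect_scale=", spec$effect_scale),
    paste0("matched=", spec$matched),
    paste0("confounder_prevalence=", spec$confounder_prevalence),
    if (!is.null(spec$age))
      paste0("age=", fmt(c(spec$age$mean, spec$age$sd, spec$age$case_shift))),
    paste0("seed=", spec$seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  names(vals) <- keys
  num <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1L]])
  age <- NULL
  if ("age" %in% keys) {
    a <- num("age")
    age <- list(mean = a[1L], sd = a[2L], case_shift = a[3L])
  }
  cohort_spec(
    n_subjects = as.integer(vals[["n_subjects"]]),
    feature_names = strsplit(vals[["feature_names"]], ",")[[1L]],
    true_weights = num("true_weights"),
    baseline_prevalence = num("baseline_prevalence"),
    effect_scale = as.numeric(vals[["effect_scale"]]),
    matched = as.logical(vals[["matched"]]),
    confounder_prevalence = as.numeric(vals[["confounder_prevalence"]]),
    age = age,
    seed = as.integer(vals[["seed"]]))
}
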