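# Internal-validation battery for probabilistic risk models: Brier score,
# Spiegelhalter's Z, Hosmer-Lemeshow H with calibration tables, AUC.

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1
#' outcome, `(1/n) sum (p_i - y_i)^2`; 0 is ideal, 0.25 is the score of a
#' constant 0.5 prediction. Equals `rmse(p, y)^2` exactly.
#'
#' @param probabilities Predictions in \[0, 1\].
#' @param outcome 0/1 vector of the same length.
#' @return Real in \[0, 1\].
#' @export
brier_score <- function(probabilities, outcome) {
  if (length(probabilities) != length(outcome))
    stop("probabilities and outcome lengths differ", call. = FALSE)
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mean((probabilities - outcome)^2)
}

#' Spiegelhalter's Z calibration statistic
#'
#' Decomposes the Brier score to test overall calibration:
#' `z = sum((y_i - p_i) (1 - 2 p_i)) /
#'  sqrt(sum((1 - 2 p_i)^2 p_i (1 - p_i)))`,
#' standard normal under the null that the probabilities are calibrated.
#' Negative values indicate predictions more extreme (closer to 0/1 in the
#' right direction) than the outcomes warrant.
#'
#' @inheritParams brier_score
#' @return A list with `z` and the two-sided `p_value`.
#' @export
spiegelhalter_z <- function(probabilities, outcome) {
  if (length(probabilities) != length(outcome))
    stop("probabilities and outcome lengths differ", call. = FALSE)
  assert_binary(outcome, "outcome")
  num <- sum((outcome - probabilities) * (1 - 2 * probabilities))
  den2 <- sum((1 - 2 * probabilities)^2 * probabilities * (1 - probabilities))
  if (den2 <= 0)
    stop("degenerate calibration: every probability is 0, 1/2, or 1",
         call. = FALSE)
  z <- num / sqrt(den2)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Hosmer-Lemeshow H statistic and calibration table
#'
#' Subjects are sorted by predicted probability and cut into `n_groups`
#' near-equal risk groups (tied probabilities stay together, so fewer
#' groups can result). With observed case count `O_g`, group size `n_g`,
#' and mean predicted probability `pbar_g`,
#' `H = sum_g (O_g - n_g pbar_g)^2 / (n_g pbar_g (1 - pbar_g))`,
#' referred to chi-square with `df = groups - 2`. Groups whose mean
#' predicted probability is exactly 0 or 1 are merged into their neighbor
#' with a warning. Values below 20 indicate acceptable calibration.
#'
#' @inheritParams brier_score
#' @param n_groups Target number of risk groups (default 10).
#' @return A list with `h`, `df`, `p_value`, and `calibration` — a data
#'   frame with one row per group: `n`, `mean_predicted`, `observed_count`,
#'   `observed_rate`.
#' @export
hosmer_lemeshow <- function(probabilities, outcome, n_groups = 10L) {
  n <- length(probabilities)
  if (n < n_groups) stop("need at least n_groups subjects", call. = FALSE)
  assert_binary(outcome, "outcome")
  assert_both_classes(outcome)
  breaks <- unique(quantile(probabilities, probs = seq(0, 1, 1 / n_groups),
                            names = FALSE))
  if (length(breaks) < 2L)
    stop("probabilities are constant; calibration groups are undefined",
         call. = FALSE)
  grp <- cut(probabilities, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  agg <- function(g) {
    idx <- grp == g
    c(n = sum(idx), sum_p = sum(probabilities[idx]), O = sum(outcome[idx]))
  }
  tab <- t(vapply(sort(unique(grp)), agg, numeric(3)))
  # merge groups with degenerate mean prediction into their neighbor
  repeat {
    pbar <- tab[, "sum_p"] / tab[, "n"]
    bad <- which(pbar <= 0 | pbar >= 1)
    if (!length(bad)) break
    if (nrow(tab) <= 3L)
      stop("too few calibration groups after merging degenerate ones",
           call. = FALSE)
    warning("merging a calibration group with degenerate mean prediction",
            call. = FALSE)
    i <- bad[1L]
    j <- if (i == 1L) 2L else i - 1L
    tab[j, ] <- tab[j, ] + tab[i, ]
    tab <- tab[-i, , drop = FALSE]
  }
  n_g <- tab[, "n"]; pbar <- tab[, "sum_p"] / n_g; O <- tab[, "O"]
  h <- sum((O - n_g * pbar)^2 / (n_g * pbar * (1 - pbar)))
  df <- nrow(tab) - 2L
  list(h = h, df = df, p_value = pchisq(h, df, lower.tail = FALSE),
       calibration = data.frame(group = seq_len(nrow(tab)), n = n_g,
                                mean_predicted = pbar, observed_count = O,
                                observed_rate = O / n_g))
}

#' Validate a fitted risk equation on a cohort
#'
#' Assembles the full internal-validation battery for the risk equation's
#' predictions on a cohort: Brier score, Spiegelhalter's Z (two-sided),
#' Hosmer-Lemeshow H over `n_groups` risk groups with its calibration
#' table, and AUC. Each statistic is flagged against its ideal: Brier
#' below `brier_max`, both calibration p-values above `alpha`, H below
#' `h_max`, AUC above `auc_min`.
#'
#' @param eq A [risk_equation()].
#' @param cohort A [binary_cohort()] providing outcome and confounder.
#' @param pi Prognostic-index values aligned with the cohort.
#' @param n_groups Risk groups for the H statistic (default 10).
#' @param brier_max,h_max,auc_min,alpha Pass-flag thresholds; defaults
#'   0.25, 20, 0.7, 0.05.
#' @return An object of class `validation_report`: a list with
#'   `probabilities`, `brier`, `spiegelhalter` (`z`, `p_value`),
#'   `hosmer_lemeshow` (`h`, `df`, `p_value`), `calibration`, `auc`, and
#'   logical `pass` flags.
#' @export
validate_model <- function(eq, cohort, pi, n_groups = 10L,
                           brier_max = 0.25, h_max = 20, auc_min = 0.7,
                           alpha = 0.05) {
  conf <- if (!is.null(cohort$confounder)) cohort$confounder else 0
  prob <- predict_risk(eq, conf, as.numeric(pi))
  report_validation(prob, cohort$outcome, label = eq$label,
                    n_groups = n_groups, brier_max = brier_max,
                    h_max = h_max, auc_min = auc_min, alpha = alpha)
}

#' @rdname validate_model
#' @param probabilities Predicted probabilities (when validating
#'   predictions directly rather than an equation).
#' @param outcome 0/1 outcomes.
#' @param label Model label for reporting.
#' @export
report_validation <- function(probabilities, outcome, label = "",
                              n_groups = 10L, brier_max = 0.25, h_max = 20,
                              auc_min = 0.7, alpha = 0.05) {
  bs <- brier_score(probabilities, outcome)
  sz <- spiegelhalter_z(probabilities, outcome)
  hl <- hosmer_lemeshow(probabilities, outcome, n_groups)
  a <- auc(probabilities, outcome)
  structure(
    list(label = label, probabilities = probabilities, brier = bs,
         spiegelhalter = sz,
         hosmer_lemeshow = hl[c("h", "df", "p_value")],
         calibration = hl$calibration, auc = a,
         pass = c(brier = bs < brier_max,
                  spiegelhalter = sz$p_value > alpha,
                  hosmer_lemeshow = hl$h < h_max & hl$p_value > alpha,
                  auc = a > auc_min)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  Brier score      %.3f  [%s]\n", x$brier,
              ifelse(x$pass["brier"], "ok", "FAIL")))
  cat(sprintf("  Spiegelhalter Z  %.3f (p = %.3f)  [%s]\n",
              x$spiegelhalter$z, x$spiegelhalter$p_value,
              ifelse(x$pass["spiegelhalter"], "ok", "FAIL")))
  cat(sprintf("  H statistic      %.3f (df = %d, p = %.3f)  [%s]\n",
              x$hosmer_lemeshow$h, x$hosmer_lemeshow$df,
              x$hosmer_lemeshow$p_value,
              ifelse(x$pass["hosmer_lemeshow"], "ok", "FAIL")))
  cat(sprintf("  AUC              %.3f  [%s]\n", x$auc,
              ifelse(x$pass["auc"], "ok", "FAIL")))
  invisible(x)
}

#' Write a validation report and its calibration table to CSV
#'
#' The report CSV has rows assessment / test statistic / value / p-value /
#' pass; the calibration table is written alongside with suffix
#' `_calibration.csv` and is directly plottable (mean predicted vs
#' observed rate per risk group).
#'
#' @param report A `validation_report`.
#' @param path Output CSV path.
#' @return Character vector of the files written, invisibly.
#' @export
write_validation_report <- function(report, path) {
  df <- data.frame(
    assessment = c("overall discrimination and calibration",
                   "overall calibration", "calibration", "discrimination"),
    statistic = c("brier_score", "spiegelhalter_z", "h_statistic", "auc"),
    value = c(report$brier, report$spiegelhalter$z, report$hosmer_lemeshow$h,
              report$auc),
    p_value = c(NA, report$spiegelhalter$p_value,
                report$hosmer_lemeshow$p_value, NA),
    pass = as.logical(report$pass))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  cal_path <- sub("\\.csv$", "_calibration.csv", path)
  write.csv(report$calibration, cal_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, cal_path))
}
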