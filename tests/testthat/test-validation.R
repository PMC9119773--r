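# Validation battery: Brier score, Spiegelhalter's Z, Hosmer-Lemeshow H,
# calibration tables, and the assembled report.

test_that("Brier score follows hand arithmetic", {
  expect_equal(brier_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(brier_score(c(0.8, 0.2), c(1, 0)), 0.04)
  with_seed_test(2, {
    y <- stats::rbinom(40, 1, 0.3)
    expect_equal(brier_score(rep(0.5, 40), y), 0.25)
  })
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("Spiegelhalter's Z reproduces the hand-computed example and its
           symmetry", {
  res <- spiegelhalter_z(c(0.4, 0.4), c(1, 0))
  expect_equal(res$z, 0.04 / sqrt(0.0192), tolerance = 1e-12)
  expect_equal(res$z, 0.2887, tolerance = 5e-4)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$z)))

  # invariant under the joint relabelling p -> 1-p, y -> 1-y (both factors
  # of every numerator term change sign), and antisymmetric in the
  # direction of miscalibration
  with_seed_test(6, {
    p <- stats::runif(30, 0.05, 0.95)
    y <- stats::rbinom(30, 1, 0.5)
    a <- spiegelhalter_z(p, y)
    b <- spiegelhalter_z(1 - p, 1 - y)
    expect_equal(a$z, b$z, tolerance = 1e-12)
  })
  expect_error(spiegelhalter_z(c(0, 1, 0.5), c(0, 1, 1)), "degenerate")
})

test_that("Spiegelhalter's Z is standard normal under calibration", {
  with_seed_test(55, {
    inside <- 0
    for (r in 1:300) {
      p <- stats::runif(1000, 0.1, 0.9)
      y <- stats::rbinom(1000, 1, p)
      inside <- inside + (abs(spiegelhalter_z(p, y)$z) <= 1.96)
    }
    expect_gt(inside / 300, 0.91)
    expect_lt(inside / 300, 0.99)
  })
})

test_that("H statistic matches a hand-computed two-group example", {
  # two hand-built groups of 10: low-risk p = 0.2 (3 events), high-risk
  # p = 0.7 (6 events)
  p <- c(rep(0.2, 10), rep(0.7, 10))
  y <- c(rep(1, 3), rep(0, 7), rep(1, 6), rep(0, 4))
  res <- hosmer_lemeshow(p, y, n_groups = 2)
  h_manual <- (3 - 10 * 0.2)^2 / (10 * 0.2 * 0.8) +
              (6 - 10 * 0.7)^2 / (10 * 0.7 * 0.3)
  expect_equal(res$h, h_manual, tolerance = 1e-12)
  expect_equal(res$df, 0)
  expect_equal(res$calibration$n, c(10, 10))
  expect_equal(res$calibration$observed_count, c(3, 6))
})

test_that("perfectly calibrated groups give H = 0 and sane tables", {
  p <- c(rep(0.25, 8), rep(0.5, 8), rep(0.75, 8))
  y <- c(rep(1, 2), rep(0, 6), rep(1, 4), rep(0, 4), rep(1, 6), rep(0, 2))
  res <- hosmer_lemeshow(p, y, n_groups = 3)
  expect_equal(res$h, 0)
  expect_equal(sum(res$calibration$n), 24)
  expect_equal(res$calibration$observed_rate,
               res$calibration$mean_predicted)
})

test_that("H statistic groups are permutation invariant and sum to n", {
  with_seed_test(11, {
    p <- stats::runif(400, 0.05, 0.95)
    y <- stats::rbinom(400, 1, p)
    a <- hosmer_lemeshow(p, y)
    perm <- sample(400)
    b <- hosmer_lemeshow(p[perm], y[perm])
    expect_equal(a$h, b$h, tolerance = 1e-12)
    expect_equal(sum(a$calibration$n), 400)
    # ties kept together: constant probabilities collapse the groups
    expect_error(hosmer_lemeshow(rep(0.4, 50), stats::rbinom(50, 1, 0.4)),
                 "constant")
  })
})

test_that("validation statistics are permutation invariant", {
  with_seed_test(19, {
    p <- stats::runif(200, 0.05, 0.95)
    y <- stats::rbinom(200, 1, p)
    perm <- sample(200)
    expect_equal(brier_score(p, y), brier_score(p[perm], y[perm]))
    expect_equal(spiegelhalter_z(p, y)$z, spiegelhalter_z(p[perm], y[perm])$z,
                 tolerance = 1e-12)
  })
})

test_that("gross miscalibration is detected", {
  with_seed_test(27, {
    p <- stats::runif(2000, 0.1, 0.9)
    y <- stats::rbinom(2000, 1, p)
    res <- spiegelhalter_z(1 - p, y)    # anti-calibrated predictions
    expect_lt(res$p_value, 0.05)
  })
})

test_that("validate_model assembles the battery with pass flags", {
  with_seed_test(33, {
    spec <- cohort_spec(n_subjects = 900, seed = 33)
    co <- simulate_cohort(spec)
    w <- reference_weights("ann")
    pi <- compute_pi(co$features, w)
    eq <- fit_risk_equation(pi, co$outcome, co$confounder, label = "ANN-RS")
    rep <- validate_model(eq, co, pi)
    expect_s3_class(rep, "validation_report")
    expect_named(rep$pass, c("brier", "spiegelhalter", "hosmer_lemeshow",
                             "auc"))
    expect_equal(sum(rep$calibration$n), 900)
    # a refit model on its own data should be well calibrated
    expect_true(rep$pass[["spiegelhalter"]])
    expect_true(rep$pass[["hosmer_lemeshow"]])
    files <- write_validation_report(rep, tempfile(fileext = ".csv"))
    expect_true(all(file.exists(files)))
    expect_equal(nrow(read.csv(files[1])), 4)
  })
})

test_that("the reference validation rows satisfy the package pass rules", {
  ref <- reference_validation()
  expect_true(all(ref$brier < 0.25))
  expect_true(all(ref$spiegelhalter_p > 0.05))
  expect_true(all(ref$h_statistic < 20 & ref$h_p > 0.05))
  expect_true(all(ref$auc > 0.7))
})
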