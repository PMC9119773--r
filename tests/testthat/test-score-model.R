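# Prognostic-index arithmetic and the one-covariate logistic risk
# equation: worked-example sums, IRLS fit vs glm, coefficient recovery,
# and prediction round trips.

test_that("the worked-example subject scores 40.12 (ANN) and 44.968 (SVM)", {
  subj <- example_subject()
  pi_a <- compute_pi(subj, reference_weights("ann", relative = "published"))
  expect_equal(as.numeric(pi_a), 8.024 + 9.067 + 6.128 + 10.527 + 6.371,
               tolerance = 1e-12)
  expect_lt(abs(as.numeric(pi_a) - 40.12), 0.005)
  pi_s <- compute_pi(subj, reference_weights("svm", relative = "published"))
  expect_equal(as.numeric(pi_s), 44.968, tolerance = 1e-9)
})

test_that("PI hits its range endpoints and equals the matrix product", {
  w <- reference_weights("ann")
  zeros <- matrix(0, 1, 13, dimnames = list(NULL, w$feature))
  ones <- zeros + 1
  expect_equal(as.numeric(compute_pi(zeros, w)), 0)
  expect_equal(as.numeric(compute_pi(ones, w)), 100, tolerance = 1e-9)

  with_seed_test(3, {
    X <- matrix(stats::rbinom(20 * 13, 1, 0.4), 20, 13,
                dimnames = list(NULL, w$feature))
    expect_equal(as.numeric(compute_pi(X, w)),
                 as.numeric(X %*% w$relative_weight))
    expect_equal(rowSums(weight_substituted_matrix(X, w)),
                 as.numeric(compute_pi(X, w)))
  })
})

test_that("flipping any feature on never decreases the PI", {
  w <- reference_weights("svm")
  base <- matrix(0, 1, 13, dimnames = list(NULL, w$feature))
  base[1, c(2, 5, 9)] <- 1
  pi0 <- as.numeric(compute_pi(base, w))
  for (j in which(base[1, ] == 0)) {
    up <- base; up[1, j] <- 1
    expect_gte(as.numeric(compute_pi(up, w)), pi0)
  }
})

test_that("PI validation rejects name mismatches and non-binary entries", {
  w <- reference_weights("ann")
  bad <- matrix(1, 1, 2, dimnames = list(NULL, c("x", "y")))
  expect_error(compute_pi(bad, w), "do not match")
  nb <- matrix(0.5, 1, 13, dimnames = list(NULL, w$feature))
  expect_error(compute_pi(nb, w), "0/1")
})

test_that("the IRLS fit agrees with glm as an independent reference", {
  with_seed_test(42, {
    n <- 800
    gender <- stats::rbinom(n, 1, 0.4)
    pi <- stats::runif(n, 0, 100)
    y <- stats::rbinom(n, 1, plogis(-4 + 0.3 * gender + 0.08 * pi))
    eq <- fit_risk_equation(pi, y, gender, label = "test")
    ref <- stats::glm(y ~ gender + pi, family = stats::binomial())
    expect_equal(eq$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
    expect_equal(eq$confounder_coef, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(eq$pi_coef, unname(coef(ref)[3]), tolerance = 1e-6)
    expect_equal(unname(eq$se),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-4)
  })
})

test_that("degenerate fits are caught; separation returns stabilized
           estimates with a warning", {
  expect_error(fit_risk_equation(rep(5, 20), rep(c(0, 1), 10)), "constant")
  # perfectly separated: PI > 50 iff case
  pi <- c(1:10, 91:100)
  y <- rep(c(0, 1), each = 10)
  expect_warning(eq <- fit_risk_equation(pi, y), "separation")
  expect_true(all(is.finite(c(eq$intercept, eq$pi_coef))))
  expect_gt(eq$pi_coef, 0)
})

test_that("Wald test on a null PI keeps its nominal type-I error", {
  with_seed_test(100, {
    hits <- 0
    for (r in 1:400) {
      pi <- stats::runif(300, 0, 100)
      y <- stats::rbinom(300, 1, 0.5)   # outcome independent of PI
      eq <- fit_risk_equation(pi, y)
      hits <- hits + (eq$p_values[["pi"]] < 0.05)
    }
    expect_lt(abs(hits / 400 - 0.05), 0.03)
  })
})

test_that("predict_risk evaluates the logistic equation exactly", {
  eq_a <- reference_equation("ANN-RS")
  z <- -5.659 + 0.107 + 0.160 * 40.12
  expect_equal(predict_risk(eq_a, 1, 40.12), 1 / (1 + exp(-z)))
  expect_equal(round(z, 4), 0.8672)
  expect_equal(predict_risk(eq_a, 1, 40.12), 0.704, tolerance = 5e-4)

  eq_s <- reference_equation("SVM-RS")
  expect_equal(predict_risk(eq_s, 0, 0), 1 / (1 + exp(6.131)))
  expect_equal(round(predict_risk(eq_s, 0, 0), 5), 0.00217)

  null_eq <- risk_equation(0, 0, 0)
  expect_equal(predict_risk(null_eq, 1, 73), 0.5)
  # strictly increasing in PI for a positive coefficient
  expect_true(all(diff(predict_risk(eq_a, 0, seq(0, 100, 5))) > 0))
})

test_that("risk equations survive a JSON round trip to machine precision", {
  with_seed_test(9, {
    pi <- stats::runif(200, 0, 100)
    y <- stats::rbinom(200, 1, plogis(-3 + 0.06 * pi))
    eq <- fit_risk_equation(pi, y, label = "round-trip")
    f <- tempfile(fileext = ".json")
    write_risk_equation(eq, f)
    back <- read_risk_equation(f)
    grid <- seq(0, 100, 0.5)
    expect_equal(predict_risk(back, 0, grid), predict_risk(eq, 0, grid),
                 tolerance = 1e-15)
    expect_identical(back$label, "round-trip")
  })
})
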