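# Weight extraction: connection-weight methods, hyperplane coordinates,
# impurity importances, RFE, and the normalization invariants.

test_that("weight tables normalize to 100 and preserve ordering", {
  with_seed_test(17, {
    for (i in 1:10) {
      raw <- stats::runif(sample(2:15, 1), 0, 5)
      tab <- feature_weight_table(paste0("f", seq_along(raw)), raw,
                                  "tree_impurity")
      expect_equal(sum(tab$relative_weight), 100, tolerance = 1e-9)
      expect_true(all(tab$relative_weight >= 0))
      expect_equal(order(tab$relative_weight), order(tab$raw_contribution))
    }
  })
  expect_error(feature_weight_table("a", -1, "cwm_garson"), "nonnegative")
  expect_error(feature_weight_table(c("a", "b"), c(0, 0), "cwm_garson"),
               "sum to zero")
})

test_that("garson weights: symmetry, oracle agreement, sum-to-h, scale
           invariance", {
  sym <- ann_connection_weights(fake_ann(matrix(c(1, 1), 2, 1), 1))
  expect_equal(sym$relative_weight, c(50, 50))

  with_seed_test(23, {
    for (i in 1:10) {
      p <- sample(2:6, 1); h <- sample(1:5, 1)
      W <- matrix(stats::rnorm(p * h), p, h)
      v <- stats::rnorm(h)
      tab <- ann_connection_weights(fake_ann(W, v), "garson")
      expect_equal(tab$relative_weight, oracle_garson(W, v),
                   tolerance = 1e-12)
      expect_equal(sum(tab$raw_contribution), h, tolerance = 1e-12)
      # positive rescaling of all weights leaves relative weights unchanged
      scaled <- ann_connection_weights(fake_ann(3.7 * W, 3.7 * v), "garson")
      expect_equal(scaled$relative_weight, tab$relative_weight,
                   tolerance = 1e-10)
    }
  })
})

test_that("olden weights are normalized absolute signed sums", {
  W <- matrix(c(1, -2, 0.5, 1), 2, 2)
  v <- c(2, -1)
  tab <- ann_connection_weights(fake_ann(W, v), "olden")
  expected_raw <- abs(as.numeric(W %*% v))
  expect_equal(tab$raw_contribution, expected_raw)
  expect_equal(tab$relative_weight, 100 * expected_raw / sum(expected_raw))
})

test_that("degenerate hidden nodes and wrong learner kinds are rejected", {
  expect_error(ann_connection_weights(fake_ann(matrix(0, 2, 1), 1)),
               "all-zero")
  expect_error(svm_hyperplane_weights(fake_ann(matrix(1, 2, 1), 1)),
               "linear-kernel")
  co <- toy_cohort(40, seed = 2)
  rbf <- train_learner(co, learner_config("svm_rbf", seed = 2))
  expect_error(svm_hyperplane_weights(rbf), "linear-kernel")
})

test_that("hyperplane weights normalize absolute coordinates", {
  tab <- svm_hyperplane_weights(fake_svm_linear(c(a = 3, b = 1)))
  expect_equal(tab$relative_weight, c(75, 25))
  tab0 <- svm_hyperplane_weights(fake_svm_linear(c(a = 2, b = 0, c = -2)))
  expect_equal(tab0$relative_weight, c(50, 0, 50))
})

test_that("impurity importances rank an informative feature above noise", {
  tab1 <- tree_impurity_weights(
    train_learner(binary_cohort(cbind(only = rep(c(0, 1), 20)),
                                rep(c(0, 1), 20)),
                  learner_config("tree_ensemble", n_trees = 30, seed = 1)))
  expect_equal(tab1$relative_weight, 100)

  spec <- cohort_spec(n_subjects = 5000,
                      feature_names = c("strong", "medium", "noise"),
                      true_weights = c(2, 1, 0),
                      baseline_prevalence = c(0.3, 0.3, 0.3),
                      effect_scale = 0.6, seed = 12)
  co <- simulate_cohort(spec)
  tab <- tree_impurity_weights(
    train_learner(co, learner_config("tree_ensemble", n_trees = 100, seed = 12)))
  expect_lt(tab$relative_weight[tab$feature == "noise"],
            min(tab$relative_weight[tab$feature != "noise"]))
  expect_equal(sum(tab$relative_weight), 100, tolerance = 1e-9)
})

test_that("a one-hot ground truth surfaces as the top connection weight", {
  spec <- cohort_spec(n_subjects = 1500, feature_names = paste0("f", 1:5),
                      true_weights = c(0, 0, 10, 0, 0),
                      baseline_prevalence = rep(0.3, 5),
                      effect_scale = 0.15, seed = 4)
  co <- simulate_cohort(spec)
  tl <- train_learner(co, learner_config("ann", seed = 4))
  tab <- ann_connection_weights(tl)
  expect_equal(which.max(tab$relative_weight), 3)
})

test_that("RFE ranks a dominant feature first and returns a permutation", {
  with_seed_test(14, {
    y <- rep(c(0, 1), each = 30)
    X <- cbind(boss = y,  # fully determines the outcome
               n1 = stats::rbinom(60, 1, 0.5),
               n2 = stats::rbinom(60, 1, 0.5),
               n3 = stats::rbinom(60, 1, 0.5))
    co <- binary_cohort(X, y)
    rk <- rfe_ranking(co, learner_config("svm_rbf", seed = 14))
    expect_equal(rk$rank[rk$feature == "boss"], 1)
    expect_setequal(rk$rank, 1:4)
    expect_setequal(rk$eliminated_at, 1:4)
  })
})

test_that("RFE greedy choice agrees with an independent dual-objective
           scan on a 3-feature toy set", {
  with_seed_test(77, {
    y <- rep(c(0, 1), each = 20)
    X <- cbind(f1 = ifelse(stats::runif(40) < 0.9, y, 1 - y),
               f2 = ifelse(stats::runif(40) < 0.7, y, 1 - y),
               f3 = stats::rbinom(40, 1, 0.5))
    co <- binary_cohort(X, y)
    cfg <- learner_config("svm_rbf", seed = 77)
    rk <- rfe_ranking(co, cfg)

    # independent greedy trace: refit at each step, evaluate the dual term
    # (1/2) a'Ka with an explicit double loop over support vectors
    dual <- function(alpha, SV, gamma, cols) {
      tot <- 0
      for (i in seq_along(alpha)) for (j in seq_along(alpha)) {
        d2 <- sum((SV[i, cols] - SV[j, cols])^2)
        tot <- tot + alpha[i] * alpha[j] * exp(-gamma * d2)
      }
      tot / 2
    }
    remaining <- 1:3
    removed <- integer(0)
    while (length(remaining) > 1) {
      sub <- binary_cohort(X[, remaining, drop = FALSE], y)
      fit <- train_learner(sub, cfg)
      a <- fit$parameters$alpha; SV <- fit$parameters$support_vectors
      g <- fit$parameters$gamma
      full <- dual(a, SV, g, seq_along(remaining))
      crit <- sapply(seq_along(remaining), function(f)
        abs(full - dual(a, SV, g, setdiff(seq_along(remaining), f))))
      drop <- which.min(crit)
      removed <- c(removed, remaining[drop])
      remaining <- remaining[-drop]
    }
    removed <- c(removed, remaining)
    expect_equal(rk$eliminated_at, match(1:3, removed))
  })
})

test_that("weight tables round-trip through CSV and JSON", {
  tab <- reference_weights("svm")
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    write_weight_table(tab, f)
    back <- read_weight_table(f)
    expect_equal(back$feature, tab$feature)
    expect_equal(back$relative_weight, tab$relative_weight, tolerance = 1e-12)
    expect_equal(attr(back, "method"), attr(tab, "method"))
  }
})
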