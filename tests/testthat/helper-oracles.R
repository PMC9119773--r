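# Independent reference implementations used as oracles. These are kept
# deliberately naive (loops, enumeration) and separate from the package
# code paths they check.

# AUC by explicit enumeration of all case-control pairs, ties counted 1/2.
oracle_auc <- function(prob, outcome) {
  cases <- prob[outcome == 1]
  controls <- prob[outcome == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# Garson connection-weight importance by double loop over features and
# hidden nodes.
oracle_garson <- function(W, v) {
  p <- nrow(W); h <- ncol(W)
  raw <- numeric(p)
  for (k in seq_len(h)) {
    denom <- 0
    for (j in seq_len(p)) denom <- denom + abs(W[j, k] * v[k])
    for (j in seq_len(p)) raw[j] <- raw[j] + abs(W[j, k] * v[k]) / denom
  }
  100 * raw / sum(raw)
}

# Best chi-square split by brute force over every candidate midpoint,
# using chisq.test (no continuity correction) as the statistic.
oracle_best_split <- function(values, outcome) {
  u <- sort(unique(values))
  cand <- (u[-length(u)] + u[-1]) / 2
  stats <- sapply(cand, function(thr) {
    tab <- table(factor(values > thr, levels = c(FALSE, TRUE)),
                 factor(outcome, levels = c(0, 1)))
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  })
  list(candidates = cand, statistics = as.numeric(stats),
       threshold = cand[which.max(stats)])
}

# Hand-rolled trained_learner shell for testing weight extractors on
# explicit weight matrices without fitting anything.
fake_ann <- function(W, v, feature_names = NULL) {
  p <- nrow(W); h <- ncol(W)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  structure(list(kind = "ann",
                 config = learner_config("ann", hidden_nodes = h),
                 parameters = list(W = W, hidden_bias = numeric(h), v = v,
                                   output_bias = 0),
                 feature_names = feature_names),
            class = "trained_learner")
}

fake_svm_linear <- function(w, feature_names = names(w)) {
  if (is.null(feature_names)) feature_names <- paste0("f", seq_along(w))
  structure(list(kind = "svm_linear", config = learner_config("svm_linear"),
                 parameters = list(w = w, b = 0),
                 feature_names = feature_names),
            class = "trained_learner")
}

# Small deterministic cohort with one strongly informative feature.
toy_cohort <- function(n = 40, seed = 1) {
  with_seed_test(seed, {
    y <- rep(c(0, 1), each = n / 2)
    x1 <- ifelse(stats::runif(n) < 0.85, y, 1 - y)  # informative
    x2 <- stats::rbinom(n, 1, 0.5)                  # noise
    binary_cohort(cbind(signal = x1, noise = x2), y)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
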