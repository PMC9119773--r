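---
title: "Building transparent additive risk scores from supervised classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building transparent additive risk scores from supervised classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskdistill)
```

## The problem

High-capacity classifiers — neural networks, support vector machines, tree
ensembles — routinely out-discriminate logistic regression on clinical
risk-factor data, but clinicians cannot read a risk off them, audit them,
or put them on a laminated card. `riskdistill` implements a distillation
strategy: let the complex models find the signal, extract how much each
risk factor contributes to their decisions, and condense those
contributions into an additive 0–100 score that a *simple* logistic
equation then turns into a calibrated probability. The motivating setting
is cardiovascular risk screening from nonlaboratory binary risk factors
(hypertension, smoking history, physical inactivity, ...) in a
gender-matched case-control cohort, but nothing in the machinery is
specific to that application.

The pipeline has five stages:

1. **Train** candidate learners on the 0/1 feature matrix: a single
   hidden-layer neural network, linear- and RBF-kernel SVMs, a tree
   ensemble, with logistic regression as the baseline.
2. **Benchmark** all of them under stratified tenfold cross-validation on
   six criteria — accuracy, sensitivity, specificity, Cohen's kappa, AUC,
   RMSE — and keep only the models that *strictly* beat the baseline on
   more than half the criteria.
3. **Extract** per-feature relative weights (%) from each winner, using
   the extractor its architecture supports.
4. **Score**: replace each "present" indicator with its relative weight
   and sum. Because relative weights total 100, the prognostic index
   (PI) lives on a 0–100 scale.
5. **Refit and validate** a one-covariate logistic model
   `logit P(case) = β₀ + β₁·gender + β₂·PI`, checked with the Brier
   score, Spiegelhalter's Z, the Hosmer–Lemeshow H statistic, calibration
   tables, and AUC.

The result is a risk equation with three interpretable coefficients that
inherits most of the discrimination of the models it was distilled from.

## Weight extraction

**Connection weights (neural network).** For a network with input-hidden
weights $W \in \mathbb{R}^{p\times h}$ and hidden-output weights
$v \in \mathbb{R}^h$, the Garson variant normalizes absolute
products within each hidden node,

$$Q_{jk} = \frac{|W_{jk} v_k|}{\sum_{j'} |W_{j'k} v_k|}, \qquad
  c_j = \sum_{k=1}^{h} Q_{jk},$$

so the raw contributions $c_j$ sum exactly to $h$; the Olden variant
keeps signed sums $c_j = \sum_k W_{jk} v_k$ and takes absolute values.
Both are then normalized to percentages. Garson is the default
(`ann_connection_weights(fit, "garson")`); it is invariant to a positive
rescaling of all weights, and its per-node normalization damps the
influence of any single large hidden unit.

**Hyperplane coordinates (linear SVM).** The vector orthogonal to the
separating hyperplane, $w = \sum_i \alpha_i y_i x_i$ over the support
vectors, measures how much each coordinate moves a subject across the
boundary; $|w_j|$ normalized to 100 gives the relative weights.

**Impurity decrease (tree ensemble).** Mean decrease in Gini impurity per
feature, normalized to 100.

**Recursive feature elimination (RBF SVM).** A kernel machine has no
per-feature hyperplane coordinates, so features are ranked by repeatedly
removing the one whose deletion least perturbs the dual objective
$\tfrac12 \alpha^\top K \alpha$ (multipliers held fixed, kernel
recomputed without the candidate feature). This yields an elimination
*ranking*, not percentages; the pipeline records the ranking but builds
scores only from percentage-weight extractors, mirroring the practice of
eliminating kernel SVMs at the scoreboard stage.

### Why the network is trained with substantial weight decay

`learner_config("ann")` defaults to `l2_penalty = 1` (nnet's `decay`),
which is larger than typical pure-prediction settings. The reason is
identifiability of the *weights*, not accuracy: an overparameterized
sigmoid network can reach its optimum with large mutually cancelling
hidden-unit weights, and connection-weight importances computed from such
a solution vary wildly between random restarts. With decay of order 1 the
fitted weights are driven to the smallest configuration that explains the
data, restarts agree, and the extracted importances track the generating
signal, while discrimination on cohorts of the size this package targets
is essentially unchanged. If you only need predictions, a smaller decay
is fine; if you intend to read weights off the network, keep it.

## The prognostic index and risk equation

`compute_pi()` is exactly the dot product of the 0/1 row with the
relative-weight vector — flipping any factor to "present" can only raise
the score. `fit_risk_equation()` fits the one-covariate logistic model by
iteratively reweighted least squares (convergence when the largest
coefficient change drops below 1e-8, capped at 100 iterations), reporting
Wald standard errors and two-sided p-values. On perfect separation the
coefficients diverge; the fit is then flagged with a warning and repeated
with a small ridge penalty (1e-4 on the slopes) so the returned equation
is finite and usable. The PI enters on its natural 0–100 scale — the
coefficients are therefore "log-odds per score point" — and the gender
term is retained even when matching makes it non-significant, because the
matched design removes its marginal effect, not its role as an
adjustment.

## Validation battery

- **Brier score** $(1/n)\sum (p_i - y_i)^2$: overall accuracy of the
  probabilities; identically the square of the RMSE reported at the
  benchmarking stage (both are computed on probability-vs-label
  residuals).
- **Spiegelhalter's Z** tests whether the Brier score is compatible with
  the predictions being calibrated; two-sided p-values against the
  standard normal.
- **Hosmer–Lemeshow H**: subjects are cut into 10 near-equal groups by
  predicted risk (tied predictions stay together; a group whose mean
  prediction is exactly 0 or 1 is merged into its neighbour with a
  warning), and
  $H = \sum_g (O_g - n_g\bar p_g)^2 / (n_g \bar p_g (1-\bar p_g))$ is
  referred to $\chi^2_{G-2}$. The $G-2$ degrees of freedom presume the
  probabilities come from a model fitted to the same data — which is how
  the pipeline uses it (on the refitted risk equation). Applied to
  externally supplied probabilities the statistic is stochastically
  larger, roughly $\chi^2_G$; the test suite's null-calibration replicates
  therefore refit the equation in each replicate. H below 20 with
  p > 0.05 is treated as acceptable calibration.
- **AUC** by the Mann–Whitney statistic (ties counted ½), identical to
  trapezoidal ROC integration but with a simpler contract.

Pass flags are reported against: Brier < 0.25 (better than an
uninformative constant), both calibration p-values > 0.05, H < 20, and
AUC > 0.7 (conventional minimum for useful discrimination).

## The synthetic cohort generator

No subject-level data ship with the package; `simulate_cohort()` provides
cohorts with *known* ground truth so every stage is testable. Case status
is assigned first — exactly half cases under 1:1 matching, with gender
drawn once per matched pair so its marginal association with the outcome
is zero by construction. Feature $j$ is then Bernoulli with

$$\operatorname{logit} p_{ij} =
  \operatorname{logit}(\pi_j) + s\, w_j\, y_i,$$

where $\pi_j$ is the control-group prevalence, $w_j$ the ground-truth
importance, and $s$ the effect scale. Additive importances are thus, by
construction, the signal a faithful extractor should recover.

Defaults emulate the motivating study's design: 460 subjects, 1:1
gender-matched (female prevalence 0.322), 13 binary nonlaboratory risk
factors named after the bundled reference tables, ground-truth weights
equal to the bundled ANN relative weights, control prevalences spread
over 0.15–0.45 (the study does not report them; this is a plausible
range for common risk factors), and `effect_scale = 0.123`, chosen once
so that the true generating model's AUC is approximately 0.88 — the
discrimination regime of the reference models. An optional continuous
age column (mean 48, SD 11.31 years, cases shifted +6) feeds
`dichotomize_continuous()`, which scans every midpoint between adjacent
sorted unique values and cuts at the maximum Pearson chi-square of the
resulting 2×2 table (no continuity correction; ties broken toward the
lower threshold). This data-driven split stands in for the
decision-tree-derived "age groups" binning of the original study; no
attempt is made to reproduce the original cut-point, which was never
reported.

What the generator deliberately does **not** emulate: feature-feature
correlation (real risk factors cluster), interactions and nonlinear
effects (the generative model is additive on the logit scale, which is
exactly why the logistic baseline is hard to beat on simulated cohorts),
missing data, and measurement error. Passing recovery tests on these
cohorts therefore shows the extractors are faithful *when an additive
ground truth exists*, not that any particular real data set is additive.

### Choices made in the recovery experiments

Ordering-recovery tests (Spearman between true and extracted weights) use
a ground-truth vector evenly spread over 2–14 with equal control
prevalences. The bundled reference weights are unsuitable as a recovery
target at realistic sample sizes because several of them are near-ties
(5.735 vs 5.770 vs 5.794): no method can recover an ordering the data do
not determine — a correctly specified logistic oracle itself fails to —
so a recovery test built on them would measure noise. Equal prevalences
keep per-feature information comparable, making the intended ordering the
identifiable one. The recovery cohorts use n = 2000 with the effect scale
set for a true-model AUC near 0.85; null-calibration suites use 500
replicates of n = 2000; coefficient-recovery simulations use n = 50000.
These sizes put Monte-Carlo noise well inside the asserted tolerances
while keeping the default test run fast.

## Numerical and design notes

- Strict inequality on all six scoreboard criteria; a tie is not an
  improvement. The selection cut (`fulfilled > 3`) is configurable.
- RMSE (and hence Brier) is computed on probability-vs-label residuals,
  the convention under which RMSE² equals the Brier score.
- Hard classification uses the 0.5 threshold throughout.
- Stratified fold assignment deals each outcome class round-robin after a
  seeded shuffle, so a balanced cohort yields exactly balanced folds.
- Weight extraction always runs on a single full-data refit, never
  per fold: per-split weights vary with the split and the published
  weights are a property of the finalized model.
- All stochastic components draw from one seed threaded through the
  configuration objects; package functions restore the caller's RNG
  state.
- Learner fits delegate to `nnet`, `e1071::svm`, `randomForest`, and
  `glm`-family IRLS; the extractors, score construction, scoreboard,
  and validation statistics are implemented in this package. The ANN is
  optimized by nnet's quasi-Newton method on the penalized cross-entropy
  objective.

## Known limitations

- Connection-weight importances are meaningful for a single hidden layer
  only; deeper architectures are rejected rather than approximated.
- The RFE criterion holds the dual multipliers fixed when scoring a
  feature's removal (the standard kernel-RFE approximation); it is a
  greedy ranking, not a global search.
- Relative weights discard sign: a protective factor (negative hyperplane
  coordinate) still receives a positive weight. With predominantly
  harmful risk-factor codings this matches the intended use; recode
  protective factors before scoring.
- The distilled equation's performance is assessed on the same cohort it
  was fitted to (internal validation); no optimism correction or external
  validation is implemented.
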