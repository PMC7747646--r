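# logsumlr

Sparse penalized logistic regression for high-dimensional biomarker
selection, built around the non-convex **LogSum + L2** penalty and its
closed-form thresholding operator.

## The problem

Gene-expression classification problems are small-n, large-p: a few
hundred samples, thousands of correlated features, and only a handful of
genes that actually carry signal. An unpenalized logistic regression
overfits and selects everything. `logsumlr` fits the penalized logistic
model

    P(y = 1 | x) = f(b0 + x'b),     f(eta) = exp(eta) / (1 + exp(eta))

with the LogSum + L2 penalty

    P(b) = lambda * sum_j [ lambda1 * log(|b_j| + eps) + lambda2 * b_j^2 ],
    lambda1 + lambda2 = 1,

whose log-sum part approximates the L0 norm as `eps -> 0` (aggressive,
nearly unbiased sparsity) and whose ridge part gives the grouping effect
needed to select correlated pathway members together. The estimator is
computed by cyclic coordinate descent inside an IRLS loop; each
coordinate update applies the closed-form LogSum + L2 thresholding
operator

    b = sign(w) * [ (|w| - A*eps) + sqrt((|w| + A*eps)^2 - 4*lambda1*A) ] / (2A),
    A = 1 + 2*lambda2,

when `|w|` exceeds the zero band `2*sqrt(lambda1*A) - A*eps`, and zero
otherwise. Seven comparator penalties (lasso, elastic net, SCAD, MCP,
L1/2 half thresholding, HLR, plain LogSum) run through the same solver,
so method comparisons isolate the penalty. Tuning is stratified k-fold
cross-validation; support recovery is scored by beta-sensitivity /
beta-specificity (fraction of true features recovered / noise features
rejected).

See `vignettes/logsum-l2-methods.Rmd` for the full model, solver and
design discussion.

## Worked example

Generate the grouped-feature benchmark scenario (n = 200, p = 1000, five
true coefficients of 2 in one correlated group), split 70/30, tune
LogSum + L2 by tenfold cross-validation, and inspect the fit:

```r
library(logsumlr)

data  <- simulate_scenario(scenario_spec("scenario1", rho = 0.2), seed = 1)
parts <- split_dataset(data, train_frac = 0.7, seed = 1)

grid <- study_grid("LOGSUM_L2", parts$train$X, parts$train$y)
cv   <- cross_validate(parts$train, grid, k = 10, seed = 1)
cv$best
#> <penalty_config> LOGSUM_L2 (lam = 0.0272656, lam1 = 0.9, lam2 = 0.1, eps = 0.01)

fit <- fit_penalized_logistic(parts$train, cfg = cv$best)
select_support(fit)
#>   g1   g2   g3   g4   g5  g94 g385
#>    1    2    3    4    5   94  385

classification_metrics(parts$test$y,
                       classify(fit, parts$test$X),
                       predict_proba(fit, parts$test$X))
#> accuracy 0.9500  sensitivity 0.8966  specificity 1.0000  AUC 0.9989
#> confusion: TP 26 FP 0 TN 31 FN 3

support_metrics(data$true_beta, fit$beta)
#> beta-sensitivity 1.0000  beta-specificity 0.9980  (TP 5 FP 2 TN 993 FN 0)
```

The cross-validated fit recovers all five true group members
(beta-sensitivity 1) while keeping only two of the 995 noise features
(beta-specificity 0.998), and classifies 95% of held-out samples
correctly.

The same machinery scales to a full study —
`run_study(study_config(...))` crosses scenarios, correlation levels and
methods over seeded replicates and writes per-cell mean (sd) tables —
and to real expression tables via `load_expression_matrix()`, which
reads GEO Series Matrix text files. A small command-line interface is
installed at `inst/cli/logsumlr` (subcommands `simulate`, `fit`, `cv`,
`study`).

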