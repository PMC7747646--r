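---
title: "Sparse logistic regression with the LogSum + L2 penalty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse logistic regression with the LogSum + L2 penalty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Microarray and RNA-seq classification problems routinely have a few dozen
to a few hundred samples and thousands of features, of which only a
handful carry signal. A plain logistic regression overfits badly in this
regime and assigns nonzero weight to essentially every gene. Penalized
logistic regression addresses both problems at once: the penalty shrinks
noise coefficients to exactly zero (feature selection) and regularizes the
rest (overfitting control). When informative genes come in correlated
groups — co-regulated pathway members — the penalty should also exhibit a
*grouping effect*, selecting correlated partners together instead of
arbitrarily picking one.

`logsumlr` is built around the **LogSum + L2** penalty

$$P(\beta) \;=\; \lambda \sum_{j=1}^{p} \Big( \lambda_1 \log(|\beta_j| + \varepsilon) \;+\; \lambda_2 \beta_j^2 \Big), \qquad \lambda_1 + \lambda_2 = 1,$$

a non-convex log-sum term that approximates the $L_0$ norm as
$\varepsilon \to 0$ (aggressive, nearly unbiased sparsity) combined with a
ridge term that supplies the grouping effect and stabilizes strongly
correlated designs. Seven standard comparator penalties (lasso, elastic
net, SCAD, MCP, $L_{1/2}$ half thresholding, HLR, plain LogSum) run
through the same solver, so performance differences between methods
reflect the penalty alone rather than implementation differences.

## Model and estimator

For binary labels $y_i \in \{0,1\}$ (class 1 is the positive/disease
class) and features $x_i \in \mathbb{R}^p$, the model is logistic
regression

$$P(y_i = 1 \mid x_i) = f(\beta_0 + x_i'\beta), \qquad f(\eta) = \frac{e^{\eta}}{1 + e^{\eta}},$$

and the estimator minimizes the penalized negative log-likelihood
$\ell(\beta_0, \beta) + P(\beta)$. The intercept is never penalized.

## Univariate thresholding operators

Coordinate descent reduces each coordinate update to the one-dimensional
problem

$$\hat\beta = \arg\min_\beta \tfrac12 (\beta - w)^2 + P(\beta),$$

whose closed-form solution is the penalty's *thresholding operator*. All
eight operators in the package are odd in $w$, fix zero, and have a
closed zero band (a tie at the band edge resolves to 0). For LogSum + L2
with weights $\lambda_1, \lambda_2$ and offset $\varepsilon$, writing
$A = 1 + 2\lambda_2$:

$$\hat\beta = \operatorname{sign}(w)\,
  \frac{(|w| - A\varepsilon) + \sqrt{(|w| + A\varepsilon)^2 - 4\lambda_1 A}}{2A}
  \quad \text{when } |w| > 2\sqrt{\lambda_1 A} - A\varepsilon,$$

and $0$ otherwise. Every nonzero output solves the stationarity equation
$A\beta - |w| + \lambda_1/(\beta + \varepsilon) = 0$ (checked to $10^{-8}$
in the tests). Configurations whose zero-band half-width
$2\sqrt{\lambda_1 A} - A\varepsilon$ is not positive are rejected with an
error rather than silently producing dense solutions. For large $|w|$ the
operator is asymptotically unbiased when $\lambda_2 = 0$; any
$\lambda_2 > 0$ retains the deliberate ridge shrink $1/(1+2\lambda_2)$.

Because the penalties are even functions, operators derived for $w > 0$
are extended to negative $w$ by odd symmetry ($|w|$ inside the formulas,
multiplied by $\operatorname{sign}(w)$).

### Conventions for SCAD, MCP and the half-thresholding family

The package uses the canonical SCAD operator (soft thresholding below
$2\lambda$, the rescaled soft threshold on $(2\lambda, a\lambda]$,
identity beyond $a\lambda$, with shape $a > 2$) and the canonical MCP
operator ($S(w,\lambda)/(1 - 1/\gamma)$ up to $\gamma\lambda$, identity
beyond, $\gamma > 1$). Both are certified against a brute-force
grid-search minimizer of the univariate objective, which is the package's
ground truth for every operator.

The $L_{1/2}$ *half-thresholding* operator deserves a note on
conventions. Under this package's univariate objective
$\tfrac12(\beta - w)^2 + \lambda|\beta|^{1/2}$, the exact operator is

$$\hat\beta = \tfrac23 w \Big(1 + \cos\tfrac{2(\pi - \phi_\lambda(w))}{3}\Big),
\qquad \phi_\lambda(w) = \arccos\!\Big(\tfrac{\lambda}{4}\big(\tfrac{|w|}{3}\big)^{-3/2}\Big),$$

with zero band $|w| \le \tfrac32 \lambda^{2/3}$. Formulations written for
the unhalved loss $\|y - X\beta\|^2$ quote the same operator with
$\lambda$ doubled, i.e. a $(3/4)\lambda^{2/3}$ band and $\lambda/8$ inside
the arccos; the two parameterizations describe the same rule. The
brute-force oracle resolves the convention: the implementation's output is
the global minimizer of the half-squared-error objective to $10^{-6}$,
and the tests assert exactly that. HLR composes the half operator with a
ridge damping, $\mathrm{HLR}(w, \lambda, a) = \mathrm{Half}(w, \lambda a) / (1 + \lambda(1-a))$,
which implies a $\tfrac12(1-a)\beta^2$ ridge term in the HLR penalty
value (the same half-weighted ridge convention the elastic-net operator
implies); LogSum + L2 keeps its unhalved $\lambda_2\beta^2$, consistent
with the $1 + 2\lambda_2$ factor in its operator.

## The solver

`fit_penalized_logistic()` nests cyclic coordinate descent inside an
IRLS loop:

1. At the current $(\tilde\beta_0, \tilde\beta)$, form the working
   response and weights of the one-term Taylor linearization:
   $W_i = f(\eta_i)(1 - f(\eta_i))$ (clamped below by
   `weight_floor = 1e-5` so saturated probabilities cannot blow up the
   working response) and $Z_i = \eta_i + (y_i - f(\eta_i))/W_i$.
2. Solve the penalized weighted least-squares problem by cyclic
   coordinate sweeps: for coordinate $j$, with curvature
   $v_j = \sum_i W_i x_{ij}^2$ and statistic
   $w_j = \sum_i W_i x_{ij} (Z_i - \tilde Z_i^{(j)})$, set
   $\beta_j \leftarrow \mathrm{op}(w_j / v_j)$ with the penalty
   parameters rescaled by $1/v_j$. This solves
   $\min_b \tfrac{v_j}{2}(b - w_j/v_j)^2 + P(b)$ exactly, and reduces to
   the verbatim operator when $v_j = 1$ — the orthonormal setting the
   closed forms are derived in. The unpenalized intercept is updated to
   the weighted mean of residuals each sweep. Constant columns get their
   coefficient pinned at zero with a warning.
3. Repeat until the largest coefficient change across an outer iteration
   falls below `tol` (default $10^{-4}$; defaults `max_outer = 50`,
   `max_inner = 100`, cyclic coordinate order).

Two numerical choices matter enough to spell out:

* **Standardization.** Columns are centered and scaled to unit
  *population* standard deviation before fitting (coefficients are mapped
  back afterwards). Combined with the weight normalization below this
  keeps $v_j \approx 1$, so the thresholding operators apply essentially
  verbatim, and it makes fits scale-equivariant (tested).
* **Weight normalization.** The IRLS weights are divided by the *fixed*
  null-model total $n/4$ (at $\beta = 0$ every $W_i = 1/4$), not by their
  current sum. A normalization by the iteration-dependent $\sum_i W_i$
  amplifies the data-fit term as probabilities saturate and the weight
  total shrinks, which destabilizes the loop on separable data; the fixed
  $n/4$ scale agrees with the sum normalization exactly at the null model
  (unit curvature, operators verbatim) while defining one fixed penalized
  objective across iterations. With this choice the penalized objective
  trace is monotone for the convex penalties (asserted in tests with
  $10^{-8}$ slack), and the solver's $\lambda$ for the lasso corresponds
  to `4 * lambda` in `glmnet`'s $\ell/n$ convention — an identity the
  test suite exploits to cross-check both the Gaussian and the logistic
  paths against `glmnet` coefficients.

The Gaussian variant `fit_penalized_linear()` is the same sweep with unit
weights scaled by $1/n$, i.e. the objective
$\frac{1}{2n}\|y - \beta_0 - X\beta\|^2 + P(\beta)$; its $p = 2$ fixed
points are verified against an independent two-dimensional grid-search
oracle to $10^{-4}$.

For the non-convex penalties (SCAD, MCP, HALF, HLR, LogSum, LogSum + L2)
coordinate descent converges to a stationary point that can depend on the
starting point; the package mitigates this the standard way, with warm
starts along a decreasing $\lambda$ path, and makes no global-optimality
claim.

## Tuning

`cross_validate()` performs stratified $k$-fold cross-validation (default
$k = 10$; stratification keeps both classes in every fold, which plain
random folds do not guarantee at gene-data sample sizes) and scores each
configuration by held-out classification accuracy at the 0.5 cutoff —
the same metric the study tables report. Ties are broken toward sparser
models: larger $\lambda$, then larger $\lambda_1$.

The paper-facing parameterization $\lambda(\lambda_1 \log + \lambda_2
\beta^2)$ with $\lambda_1 + \lambda_2 = 1$ is redundant with the overall
$\lambda$; internally the operator receives the effective weights
$\lambda\lambda_1$ and $\lambda\lambda_2$, so the overall $\lambda$
traces the path while $\lambda_1$ sets the sparsity/grouping mix.

`default_grid()` builds a 30-point log-spaced $\lambda$ path from
$\lambda_{\max}$ (the smallest $\lambda$ with an all-zero fit at the null
model, computed per family from the closed zero bands) down to
$0.01\,\lambda_{\max}$, crossed with $a \in \{0.1, \dots, 0.9\}$ for
EN/HLR and, for LogSum + L2, $\lambda_1 \in \{0.1, \dots, 0.9\}$ and
$\varepsilon \in \{10^{-3}, 10^{-2}, 10^{-1}\}$ (invalid log-penalty
configurations filtered out). Whether $\varepsilon$ should be tuned or
fixed is genuinely open; the default tunes it over that small set, and
fixing it is a one-argument change. $\varepsilon$ defaults to $0.01$ —
small enough that the log-sum term tracks the $L_0$ norm, large enough to
keep the operator's discriminant well-conditioned in double precision.

The study runner uses the deliberately compact `study_grid()` — the full
30-point path for the lasso, and a 10-point path crossed with mixing
values $\{0.1, 0.5, 0.9\}$ at fixed $\varepsilon = 0.01$ for the
two-parameter families — chosen once to keep a full multi-cell,
multi-replicate study at desktop scale while still covering the
sparse-to-dense range of each family.

## The synthetic-data generator

`simulate_scenario()` emulates grouped-feature expression data on the
logit scale:

* features drawn i.i.d. $N(0,1)$;
* within each group, non-anchor members overwritten by
  $x_i \leftarrow \rho x_{\text{anchor}} + (1-\rho) x_i$. This is applied
  literally, without re-standardization, because it is the generative
  recipe the scenarios define; it shrinks the variance of correlated
  columns (population correlation with the anchor is
  $\rho/\sqrt{\rho^2 + (1-\rho)^2}$, checked in closed form by the
  tests), and the solver's internal standardization absorbs the scale
  difference;
* noisy logit $\eta = X\beta^\ast + \sigma\varepsilon$,
  $\varepsilon \sim N(0,1)$;
* labels $y = \mathbf{1}(\eta > 0)$.

Scenario 1 ($n = 200$, $p = 1000$, $\sigma = 0.3$, five true
coefficients of 2 in one correlated group) probes recovery of a single
group against 995 noise features; scenario 2 ($n = 400$, $\sigma = 0.4$,
twenty true coefficients in two groups with mixed signs) adds scale and
sign heterogeneity. Splits are stratified 70/30.

The deterministic threshold rule $y = \mathbf{1}(\eta > 0)$ is the
default because the generative statement "$\log(y/(1-y)) = X\beta +
\sigma\varepsilon$" defines a continuous response on the logit scale,
binarized at $1/2$; a Bernoulli draw from $f(\eta)$ is available via
`label_rule = "bernoulli"` for sensitivity analysis. Under the default
rule with these $\sigma$ values the signal-to-noise ratio is high (the
linear predictor's scale is an order of magnitude above $\sigma$), so
the Bayes error is small and a well-tuned sparse fit can approach
near-perfect test accuracy — worth keeping in mind when comparing
methods on these scenarios.

What the generator does *not* emulate: heavy-tailed or skewed expression
distributions, probe-level measurement error, batch effects, or
correlation between "noise" features. Tests passing on these scenarios
demonstrate correct recovery of sparse grouped signal under idealized
Gaussian conditions, not performance on real microarray cohorts; the
GEO Series Matrix loader exists precisely so users can run the same
pipeline on real tables, whose preprocessing is their responsibility.

## The simulation study

`run_study()` crosses scenarios, correlation levels and methods; each
replicate $r$ (seed = `base_seed` $+ r$) generates, splits, tunes by
tenfold CV on the training part, refits, and evaluates training/test
accuracy, sensitivity, specificity, rank-based AUC (Mann-Whitney with
tie correction — deterministic and equal to the trapezoidal ROC area),
plus $\beta$-sensitivity and $\beta$-specificity of the recovered
support against the generating coefficients (a coefficient counts as
selected iff it is exactly nonzero; the operators produce exact zeros,
so no magnitude cutoff is needed). Cell aggregates are means and
standard deviations over replicates; failed replicates are counted and
excluded, never silently dropped. The package's own study runs use 10
replicates per cell, a size at which cell means are stable to roughly a
percentage point while a four-cell study completes in a few minutes on
one core.

## Known limitations

* Binary outcomes only; no multinomial or survival extensions.
* No active-set/strong-rule screening — fine at $p \sim 10^3$, wasteful
  at $p \sim 10^6$.
* Non-convex penalties yield warm-start-dependent stationary points, as
  in every coordinate-descent implementation of SCAD/MCP-type penalties.
* The zero band of the LogSum + L2 rule is taken verbatim from the
  closed form (the discriminant boundary); in a narrow band just above
  the threshold a nonzero stationary point can have objective value
  slightly above the value at zero, a known property of this operator
  family that the oracle-based tests document rather than hide.
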