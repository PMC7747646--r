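#' Simulation scenario specification
#'
#' The two grouped-feature benchmark scenarios used throughout the
#' package's simulation study.  Features are standard normal; within
#' each group, non-anchor columns are overwritten by the linear mixing
#' \eqn{x_i \leftarrow \rho x_{\mathrm{anchor}} + (1-\rho) x_i}, which
#' induces pairwise correlation \eqn{\rho/\sqrt{\rho^2 + (1-\rho)^2}}
#' with the anchor.  Labels come from thresholding the noisy logit
#' \eqn{\eta = X\beta + \sigma\varepsilon} at zero (see
#' [simulate_scenario()]).
#'
#' \describe{
#'   \item{scenario1}{n = 200, p = 1000, \eqn{\sigma} = 0.3,
#'     \eqn{\beta} = (2,2,2,2,2, 0 x 995), one group \{1..5\} anchored
#'     at feature 1.}
#'   \item{scenario2}{n = 400, p = 1000, \eqn{\sigma} = 0.4,
#'     \eqn{\beta} = (2,2,2,2,2, 1.5, -2, 1.7, 3, -2.5, 3 x 10,
#'     0 x 980), groups \{1..10\} and \{11..20\} anchored at features 1
#'     and 11.}
#' }
#'
#' @param name `"scenario1"` or `"scenario2"`.
#' @param rho Within-group mixing coefficient in \[0, 1\].
#' @param label_rule `"threshold"` (default): `y = 1` when
#'   \eqn{\eta > 0}, the deterministic rule consistent with a continuous
#'   response on the logit scale; `"bernoulli"`: draw
#'   `y ~ Bernoulli(logistic(eta))`.
#' @return An object of class `scenario_spec` with fields `name`, `n`,
#'   `p`, `sigma`, `rho`, `beta_true`, `groups` (each a list with
#'   `members` and `anchor`) and `label_rule`.
#' @export
scenario_spec <- function(name = c("scenario1", "scenario2"), rho = 0.2,
                          label_rule = c("threshold", "bernoulli")) {
  name <- match.arg(name)
  label_rule <- match.arg(label_rule)
  .check_scalar(rho, "rho")
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]", call. = FALSE)
  if (name == "scenario1") {
    n <- 200L; sigma <- 0.3
    beta <- c(rep(2, 5), rep(0, 995))
    groups <- list(list(members = 1:5, anchor = 1L))
  } else {
    n <- 400L; sigma <- 0.4
    beta <- c(2, 2, 2, 2, 2, 1.5, -2, 1.7, 3, -2.5, rep(3, 10), rep(0, 980))
    groups <- list(list(members = 1:10, anchor = 1L),
                   list(members = 11:20, anchor = 11L))
  }
  structure(list(name = name, n = n, p = 1000L, sigma = sigma, rho = rho,
                 beta_true = beta, groups = groups, label_rule = label_rule),
            class = "scenario_spec")
}

#' Generate a synthetic dataset from a scenario
#'
#' Draws an n x p matrix of independent standard-normal features,
#' applies the within-group mixing
#' \eqn{x_i \leftarrow \rho x_{\mathrm{anchor}} + (1-\rho) x_i} to each
#' non-anchor group member (literally, without re-standardization: the
#' mixing shrinks the variance of correlated columns, and the solver's
#' internal standardization compensates), forms the noisy logit
#' \eqn{\eta = X\beta + \sigma\varepsilon} with
#' \eqn{\varepsilon \sim N(0,1)}, and labels samples by the scenario's
#' label rule.  Pure function of `(spec, seed)`.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with `true_beta` set.
#' @examples
#' d <- simulate_scenario(scenario_spec("scenario1", rho = 0.2), seed = 1)
#' dim(d$X)
#' @export
simulate_scenario <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  withr::with_seed(as.integer(seed), {
    X <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p)
    for (g in spec$groups) {
      anchor <- X[, g$anchor]
      for (i in setdiff(g$members, g$anchor)) {
        X[, i] <- spec$rho * anchor + (1 - spec$rho) * X[, i]
      }
    }
    eta <- drop(X %*% spec$beta_true) + spec$sigma * rnorm(spec$n)
    y <- if (spec$label_rule == "threshold") as.integer(eta > 0)
         else rbinom(spec$n, 1L, plogis(eta))
    labeled_dataset(X, y, feature_ids = paste0("g", seq_len(spec$p)),
                    true_beta = spec$beta_true)
  })
}

#' Stratified train/test split
#'
#' Splits a dataset into training and test parts, stratified by class so
#' both sides keep (approximately) the original class balance.  The
#' training side receives `round(n_c * train_frac)` samples of each
#' class `c`.
#'
#' @param data A [labeled_dataset()].
#' @param train_frac Fraction of samples assigned to training (default
#'   0.7).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both
#'   [labeled_dataset()]s.
#' @export
split_dataset <- function(data, train_frac = 0.7, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("`train_frac` must lie in (0, 1)", call. = FALSE)
  }
  idx <- withr::with_seed(as.integer(seed), {
    tr <- integer(0)
    for (cls in c(0L, 1L)) {
      members <- which(data$y == cls)
      tr <- c(tr, sample(members, round(length(members) * train_frac)))
    }
    sort(tr)
  })
  subset_ld <- function(rows) {
    labeled_dataset(data$X[rows, , drop = FALSE], data$y[rows],
                    feature_ids = data$feature_ids,
                    true_beta = data$true_beta)
  }
  train <- subset_ld(idx)
  test <- subset_ld(setdiff(seq_along(data$y), idx))
  if (length(unique(train$y)) < 2L || length(unique(test$y)) < 2L) {
    stop("split left a side with a single class; adjust `train_frac`",
         call. = FALSE)
  }
  list(train = train, test = test)
}

#' Mean pairwise correlation within a feature group
#'
#' Diagnostic for the generator: the average Pearson correlation over
#' all pairs of the given columns.  Under the mixing construction the
#' anchor/member correlation is \eqn{\rho/\sqrt{\rho^2 + (1-\rho)^2}}.
#'
#' @param data A [labeled_dataset()].
#' @param group Integer vector of column indices (at least 2).
#' @return Scalar mean pairwise correlation.
#' @export
empirical_group_correlation <- function(data, group) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (length(group) < 2L) stop("`group` needs at least 2 columns", call. = FALSE)
  cm <- stats::cor(data$X[, group, drop = FALSE])
  mean(cm[upper.tri(cm)])
}
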