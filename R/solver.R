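#' Solver settings
#'
#' Convergence and preprocessing controls for the coordinate-descent /
#' IRLS solver.
#'
#' @param tol Convergence tolerance: a sweep (inner) or outer iteration
#'   converges when the maximum absolute coefficient change falls below
#'   `tol` (on the standardized scale).
#' @param max_outer Maximum IRLS iterations.
#' @param max_inner Maximum coordinate-descent sweeps per IRLS step.
#' @param weight_floor Lower clamp for the IRLS weights
#'   \eqn{W_i = f(\eta_i)(1 - f(\eta_i))}, preventing working-response
#'   blow-up at saturated probabilities.
#' @param standardize Center and scale columns to unit (population)
#'   standard deviation before fitting; coefficients are mapped back to
#'   the original scale.  On by default and strongly recommended: the
#'   thresholding operators are exact for unit-curvature coordinates.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(tol = 1e-4, max_outer = 50L, max_inner = 100L,
                            weight_floor = 1e-5, standardize = TRUE) {
  .check_scalar(tol, "tol"); .check_scalar(weight_floor, "weight_floor")
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (max_outer < 1 || max_inner < 1) {
    stop("`max_outer` and `max_inner` must be at least 1", call. = FALSE)
  }
  if (weight_floor <= 0) stop("`weight_floor` must be positive", call. = FALSE)
  structure(list(tol = tol, max_outer = as.integer(max_outer),
                 max_inner = as.integer(max_inner),
                 weight_floor = weight_floor,
                 standardize = isTRUE(standardize)),
            class = "solver_settings")
}

#' IRLS working response and weights
#'
#' One-term Taylor linearization of the logistic log-likelihood at the
#' current linear predictor: with \eqn{f} the logistic function,
#' \eqn{W_i = f(\eta_i)(1 - f(\eta_i))} (clamped below by
#' `weight_floor`) and \eqn{Z_i = \eta_i + (y_i - f(\eta_i)) / W_i}.
#'
#' @param fitted Linear predictor \eqn{\eta_i = \beta_0 + X_i\beta}.
#' @param y Binary response vector (0/1).
#' @param weight_floor Lower clamp for the weights.
#' @return List with components `Z` (working response) and `W` (weights).
#' @examples
#' working_response(rep(0, 4), c(0, 1, 0, 1))
#' @export
working_response <- function(fitted, y, weight_floor = 1e-5) {
  if (any(!is.finite(fitted))) {
    stop("non-finite linear predictor in working_response()", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("`y` must be coded 0/1", call. = FALSE)
  if (length(fitted) != length(y)) stop("length mismatch", call. = FALSE)
  f <- plogis(fitted)
  W <- pmax(f * (1 - f), weight_floor)
  Z <- fitted + (y - f) / W
  list(Z = Z, W = W)
}

# integer coding shared with the C++ kernel
.pen_code <- c(L1 = 0L, EN = 1L, SCAD = 2L, MCP = 3L, HALF = 4L, HLR = 5L,
               LOGSUM = 6L, LOGSUM_L2 = 7L)

# effective (lam1', lam2') fed to the LogSum+L2 kernel
.eff_l12 <- function(cfg) {
  if (cfg$kind == "LOGSUM_L2") c(cfg$lam * cfg$lam1, cfg$lam * cfg$lam2)
  else c(0, 0)
}

.cd_args <- function(cfg) {
  l12 <- .eff_l12(cfg)
  list(kind = .pen_code[[cfg$kind]], lam = cfg$lam, a = cfg$a,
       scad_a = cfg$scad_a, gamma = cfg$gamma, l1 = l12[1], l2 = l12[2],
       eps = cfg$eps)
}

#' One coordinate-descent sweep
#'
#' Performs a single cyclic pass over all coordinates (intercept first,
#' unpenalized) for the weighted least-squares problem at fixed working
#' response `Z` and weights `W`.  For coordinate `j` the statistic
#' \eqn{w_j = \sum_i W_i x_{ij} (Z_i - \tilde Z_i^{(j)})} and curvature
#' \eqn{v_j = \sum_i W_i x_{ij}^2} are formed, and the thresholding
#' operator applied to \eqn{w_j / v_j} with penalty parameters rescaled
#' by \eqn{1/v_j}.  Constant columns (zero curvature) have their
#' coefficient pinned at zero.
#'
#' This is the inner building block of [fit_penalized_logistic()]; it is
#' exported for inspection and testing, and expects `X` already
#' standardized if operator-exactness is desired.
#'
#' @param X Design matrix (n x p).
#' @param Z Working response (length n).
#' @param W Weights (length n), used as given; the fitting routines pass
#'   IRLS weights normalized by their null-model total `n/4`, so that
#'   standardized columns have unit curvature at the start and the
#'   operator formulas apply verbatim.
#' @param beta Current coefficient vector (length p).
#' @param beta0 Current intercept.
#' @param cfg A [penalty_config()].
#' @param intercept Update the (unpenalized) intercept as the weighted
#'   mean of residuals?
#' @return List with `beta`, `beta0`, and `max_change` (the sweep's
#'   maximum absolute coefficient change).
#' @export
cd_sweep <- function(X, Z, W, beta, beta0 = 0, cfg, intercept = TRUE) {
  stopifnot(inherits(cfg, "penalty_config"))
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(Z) == n, length(W) == n, length(beta) == p)
  if (any(W <= 0)) stop("weights must be positive", call. = FALSE)
  Wn <- as.numeric(W)
  r <- Z - beta0 - drop(X %*% beta)
  a <- .cd_args(cfg)
  v <- colSums(Wn * X^2)
  if (any(v <= 0 & beta != 0)) {
    warning("zero-curvature column(s): coefficient forced to zero",
            call. = FALSE)
  }
  res <- .cpp_cd_sweep(X, r, Wn, as.numeric(beta), beta0, intercept,
                       a$kind, a$lam, a$a, a$scad_a, a$gamma, a$l1, a$l2,
                       a$eps)
  list(beta = res$beta, beta0 = res$beta0, max_change = res$max_change)
}

# population-sd column standardization (glmnet convention)
.standardize <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  s <- sqrt(colSums(Xc^2) / n)
  const <- s <= .Machine$double.eps * 10
  s[const] <- 1
  list(X = sweep(Xc, 2, s, "/"), mu = mu, s = s, const = const)
}

.validate_xy <- function(X, y, binary = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    stop("`X` must be numeric with no missing values", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (binary) {
    if (!all(y %in% c(0, 1))) stop("`y` must be coded 0/1", call. = FALSE)
    if (length(unique(y)) < 2L) {
      stop("both classes must be present in `y`", call. = FALSE)
    }
  } else if (anyNA(y) || any(!is.finite(y))) {
    stop("`y` must be numeric with no missing values", call. = FALSE)
  }
  X
}

.new_fit <- function(beta0, beta, feature_ids, n_iter_outer, converged,
                     objective_trace, cfg, settings, family) {
  names(beta) <- feature_ids
  structure(list(beta0 = beta0, beta = beta, n_iter_outer = n_iter_outer,
                 converged = converged, objective_trace = objective_trace,
                 penalty = cfg, settings = settings, family = family),
            class = "penfit")
}

#' Fit a penalized logistic regression by IRLS + coordinate descent
#'
#' Minimizes the penalized negative log-likelihood by repeatedly
#' replacing the logistic loss with its weighted least-squares
#' linearization (working response `Z`, weights `W`, normalized by the
#' null-model weight total `n/4` so the objective keeps a fixed scale
#' across iterations) and solving each linearization by cyclic coordinate
#' descent with the closed-form thresholding operator of the chosen
#' penalty.  Columns are standardized internally (see
#' [solver_settings()]); returned coefficients are on the original
#' feature scale.  The fit is deterministic given its inputs.
#'
#' @param X Feature matrix (n x p) or a [labeled_dataset()] (in which
#'   case `y` is taken from it).
#' @param y Binary response (0/1) with both classes present.
#' @param cfg A [penalty_config()].
#' @param settings A [solver_settings()].
#' @param beta_init Optional warm-start list with components `beta0` and
#'   `beta` on the original feature scale.
#' @return An object of class `penfit` with components `beta0`, `beta`
#'   (original scale), `n_iter_outer`, `converged`, `objective_trace`
#'   (penalized objective in the solver's normalized scale, one entry per
#'   outer iteration) and `penalty`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 5), 40, 5)
#' y <- as.integer(X[, 1] - X[, 2] + rnorm(40, sd = 0.3) > 0)
#' fit <- fit_penalized_logistic(X, y, penalty_config("L1", lam = 0.02))
#' which(fit$beta != 0)
#' @export
fit_penalized_logistic <- function(X, y = NULL, cfg,
                                   settings = solver_settings(),
                                   beta_init = NULL) {
  if (inherits(X, "labeled_dataset")) {
    y <- X$y
    feature_ids <- X$feature_ids
    X <- X$X
  } else {
    feature_ids <- colnames(X)
  }
  stopifnot(inherits(cfg, "penalty_config"), inherits(settings, "solver_settings"))
  X <- .validate_xy(X, y, binary = TRUE)
  n <- nrow(X); p <- ncol(X)
  if (is.null(feature_ids)) feature_ids <- paste0("V", seq_len(p))

  if (settings$standardize) {
    std <- .standardize(X)
  } else {
    std <- list(X = X, mu = rep(0, p), s = rep(1, p),
                const = apply(X, 2, function(x) stats::var(x) == 0))
  }
  if (any(std$const)) {
    warning(sum(std$const), " constant column(s): coefficients forced to zero",
            call. = FALSE)
  }
  Xs <- std$X

  if (is.null(beta_init)) {
    beta <- rep(0, p)
    beta0 <- qlogis(mean(y))
  } else {
    beta <- as.numeric(beta_init$beta) * std$s  # to standardized scale
    beta0 <- beta_init$beta0 + sum(beta_init$beta * std$mu)
  }

  a <- .cd_args(cfg)
  trace <- numeric(0)
  converged <- FALSE
  outer <- 0L
  for (outer in seq_len(settings$max_outer)) {
    eta <- beta0 + drop(Xs %*% beta)
    if (any(!is.finite(eta))) {
      stop("non-finite linear predictor at outer iteration ", outer,
           call. = FALSE)
    }
    wr <- working_response(eta, y, settings$weight_floor)
    Wn <- wr$W / (n / 4)  # null-model weight total, fixed across iterations
    r <- wr$Z - eta
    res <- .cpp_cd_solve(Xs, r, Wn, beta, beta0, TRUE,
                         a$kind, a$lam, a$a, a$scad_a, a$gamma, a$l1, a$l2,
                         a$eps, settings$tol, settings$max_inner)
    delta <- max(abs(c(res$beta - beta, res$beta0 - beta0)))
    beta <- res$beta
    beta0 <- res$beta0
    trace <- c(trace, .penalized_logistic_objective(Xs, y, beta, beta0, cfg))
    if (delta < settings$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("IRLS did not converge in ", settings$max_outer,
            " outer iterations", call. = FALSE)
  }

  beta_orig <- beta / std$s
  beta_orig[std$const] <- 0
  beta0_orig <- beta0 - sum(beta_orig * std$mu)
  .new_fit(beta0_orig, beta_orig, feature_ids, outer, converged, trace,
           cfg, settings, "binomial")
}

# penalized objective in the solver's normalized scale: logistic deviance
# contribution per unit of total IRLS weight at the null model (1/(n/4))
# plus the penalty on standardized coefficients.  Used for the trace.
.penalized_logistic_objective <- function(Xs, y, beta, beta0, cfg) {
  eta <- beta0 + drop(Xs %*% beta)
  ll <- -sum(y * eta - log1p(exp(eta)))
  ll / (nrow(Xs) / 4) + sum(penalty_value(beta, cfg))
}

#' Fit a penalized linear regression by coordinate descent
#'
#' Gaussian analogue of [fit_penalized_logistic()]: cyclic coordinate
#' descent on \eqn{\frac{1}{2n}\|y - \beta_0 - X\beta\|^2 + P(\beta)}
#' with unit observation weights (normalized to sum to one, so the
#' operator parameters apply verbatim on standardized columns).
#'
#' @inheritParams fit_penalized_logistic
#' @param y Numeric response vector.
#' @return A `penfit` object (family `"gaussian"`).
#' @export
fit_penalized_linear <- function(X, y, cfg, settings = solver_settings(),
                                 beta_init = NULL) {
  stopifnot(inherits(cfg, "penalty_config"), inherits(settings, "solver_settings"))
  feature_ids <- colnames(X)
  X <- .validate_xy(X, y, binary = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (is.null(feature_ids)) feature_ids <- paste0("V", seq_len(p))

  if (settings$standardize) std <- .standardize(X)
  else std <- list(X = X, mu = rep(0, p), s = rep(1, p),
                   const = apply(X, 2, function(x) stats::var(x) == 0))
  if (any(std$const)) {
    warning(sum(std$const), " constant column(s): coefficients forced to zero",
            call. = FALSE)
  }
  Xs <- std$X

  if (is.null(beta_init)) {
    beta <- rep(0, p); beta0 <- mean(y)
  } else {
    beta <- as.numeric(beta_init$beta) * std$s
    beta0 <- beta_init$beta0 + sum(beta_init$beta * std$mu)
  }

  a <- .cd_args(cfg)
  Wn <- rep(1 / n, n)
  r <- y - beta0 - drop(Xs %*% beta)
  res <- .cpp_cd_solve(Xs, r, Wn, beta, beta0, TRUE,
                       a$kind, a$lam, a$a, a$scad_a, a$gamma, a$l1, a$l2,
                       a$eps, settings$tol, settings$max_inner)
  converged <- res$max_change < settings$tol
  if (!converged) {
    warning("coordinate descent did not converge in ", settings$max_inner,
            " sweeps", call. = FALSE)
  }
  beta <- res$beta; beta0 <- res$beta0
  obj <- 0.5 * mean((y - beta0 - drop(Xs %*% beta))^2) +
    sum(penalty_value(beta, cfg))
  beta_orig <- beta / std$s
  beta_orig[std$const] <- 0
  beta0_orig <- beta0 - sum(beta_orig * std$mu)
  .new_fit(beta0_orig, beta_orig, feature_ids, 1L, converged, obj,
           cfg, settings, "gaussian")
}

#' @export
print.penfit <- function(x, ...) {
  cat("<penfit> ", x$family, " model, penalty ", x$penalty$kind,
      " (lam = ", signif(x$penalty$lam, 4), ")\n", sep = "")
  cat("  nonzero coefficients: ", sum(x$beta != 0), " / ", length(x$beta),
      "; converged: ", x$converged, " (", x$n_iter_outer, " outer iterations)\n",
      sep = "")
  invisible(x)
}

#' @export
coef.penfit <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}
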