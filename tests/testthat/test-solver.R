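# IRLS + coordinate-descent solver.

test_that("working response and weights follow the linearization formulas", {
  y <- c(0, 1, 1, 0)
  wr <- working_response(rep(0, 4), y)
  expect_equal(wr$W, rep(0.25, 4))
  expect_equal(wr$Z, 4 * (y - 0.5))  # +-2

  # saturated probability: weight clamped, working response finite
  wr2 <- working_response(c(20, 0), c(1, 0), weight_floor = 1e-5)
  expect_gte(min(wr2$W), 1e-5)
  expect_true(all(is.finite(wr2$Z)))

  # direct substitution at p = 0.8
  wr3 <- working_response(qlogis(0.8), 1)
  expect_equal(wr3$Z, qlogis(0.8) + 0.2 / 0.16)

  expect_error(working_response(c(Inf, 0), c(0, 1)), "non-finite")
  expect_error(working_response(0, 2), "0/1")
})

test_that("a coordinate-descent sweep honors the univariate contracts", {
  # all-zero column keeps a zero coefficient
  withr::with_seed(3, {
    X <- cbind(rnorm(12), 0)
    Z <- rnorm(12)
  })
  sw <- suppressWarnings(
    cd_sweep(X, Z, rep(1, 12), beta = c(0, 0), beta0 = 0,
             cfg = penalty_config("L1", lam = 0.1)))
  expect_identical(sw$beta[2], 0)
  expect_warning(
    cd_sweep(X, Z, rep(1, 12), beta = c(0, 1), beta0 = 0,
             cfg = penalty_config("L1", lam = 0.1)),
    "zero-curvature")

  # single orthonormal feature, unit weights: exact soft threshold
  withr::with_seed(4, {
    x <- rnorm(10); x <- (x - mean(x)); x <- x / sqrt(sum(x^2))
    Z <- rnorm(10)
  })
  sw <- cd_sweep(matrix(x), Z, rep(1, 10), beta = 0, beta0 = 0,
                 cfg = penalty_config("L1", lam = 0.3), intercept = FALSE)
  expect_equal(sw$beta, soft_threshold(sum(x * Z), 0.3), tolerance = 1e-12)
})

test_that("p = 2 coordinate-descent fixed points match the 2-D grid oracle", {
  toy <- toy_p2(seed = 42, n = 20)
  settings <- solver_settings(tol = 1e-10, max_inner = 5000)
  cases <- list(penalty_config("L1", lam = 0.15),
                penalty_config("EN", lam = 0.2, a = 0.5),
                penalty_config("LOGSUM_L2", lam = 0.08, lam1 = 0.7,
                               lam2 = 0.3, eps = 0.01))
  s <- std_pop(toy$X)
  for (cfg in cases) {
    # grid oracle works on effective per-coordinate weights for LOGSUM_L2
    ocfg <- if (cfg$kind == "LOGSUM_L2") {
      penalty_config("LOGSUM_L2", lam = cfg$lam, lam1 = cfg$lam1,
                     lam2 = cfg$lam2, eps = cfg$eps)
    } else cfg
    fit <- fit_penalized_linear(toy$X, toy$y, cfg, settings)
    beta_std <- fit$beta * s$s  # back to the standardized scale
    oracle <- grid_oracle_p2(toy$X, toy$y, ocfg)
    expect_equal(unname(beta_std), oracle, tolerance = 1e-4,
                 info = cfg$kind)
  }
})

test_that("penalized linear fits recover noiseless signals and closed forms", {
  withr::with_seed(11, X <- matrix(rnorm(30 * 4), 30, 4))
  y <- X[, 1]
  fit <- fit_penalized_linear(X, y, penalty_config("L1", lam = 1e-6),
                              solver_settings(tol = 1e-10, max_inner = 2000))
  expect_equal(unname(fit$beta), c(1, 0, 0, 0), tolerance = 1e-4)

  # orthonormal single column: operator applied verbatim
  withr::with_seed(12, x <- rnorm(25))
  x <- (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 25)  # population sd 1
  y2 <- 2 * x + withr::with_seed(13, rnorm(25, sd = 0.1))
  lam <- 0.4
  fit2 <- fit_penalized_linear(matrix(x), y2, penalty_config("L1", lam = lam),
                               solver_settings(tol = 1e-12, max_inner = 2000))
  w <- mean(x * (y2 - mean(y2)))
  expect_equal(unname(fit2$beta), soft_threshold(w, lam), tolerance = 1e-8)
})

test_that("every penalty shrinks to the exact null model at large lambda", {
  toy <- toy_separable(seed = 21, n = 50)
  for (kind in c("L1", "EN", "SCAD", "MCP", "HALF", "HLR", "LOGSUM",
                 "LOGSUM_L2")) {
    lam <- 10 * lambda_max(toy$X, toy$y, kind, a = 0.5, lam1 = 0.5,
                           eps = 0.01)
    cfg <- switch(kind,
      EN = penalty_config("EN", lam = lam, a = 0.5),
      HLR = penalty_config("HLR", lam = lam, a = 0.5),
      LOGSUM = penalty_config("LOGSUM", lam = lam, eps = 0.01),
      LOGSUM_L2 = penalty_config("LOGSUM_L2", lam = lam, lam1 = 0.5,
                                 lam2 = 0.5, eps = 0.01),
      penalty_config(kind, lam = lam))
    fit <- fit_penalized_logistic(toy$X, toy$y, cfg)
    expect_true(all(fit$beta == 0), info = kind)
    expect_equal(fit$beta0, qlogis(mean(toy$y)), tolerance = 1e-6,
                 info = kind)
  }
})

test_that("small-lambda fits separate a separable toy exactly", {
  toy <- toy_separable(seed = 7, n = 40)
  fit <- fit_penalized_logistic(toy$X, toy$y,
                                penalty_config("L1", lam = 0.01))
  expect_equal(mean(classify(fit, toy$X) == toy$y), 1)
})

test_that("the penalized objective trace is nonincreasing for convex penalties", {
  for (seed in c(1, 5, 9)) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(80 * 15), 80, 15)
      y <- as.integer(X[, 1] - X[, 2] + rnorm(80, sd = 0.8) > 0)
    })
    for (cfg in list(penalty_config("L1", lam = 0.05),
                     penalty_config("EN", lam = 0.08, a = 0.5))) {
      fit <- fit_penalized_logistic(X, y, cfg)
      expect_true(all(diff(fit$objective_trace) <= 1e-8),
                  info = paste(cfg$kind, seed))
    }
  }
})

test_that("standardization makes fits scale-equivariant", {
  toy <- toy_separable(seed = 31, n = 60)
  cfg <- penalty_config("EN", lam = 0.1, a = 0.5)
  f1 <- fit_penalized_logistic(toy$X, toy$y, cfg)
  X10 <- toy$X; X10[, 1] <- X10[, 1] * 10
  f2 <- fit_penalized_logistic(X10, toy$y, cfg)
  expect_equal(predict_proba(f2, X10), predict_proba(f1, toy$X),
               tolerance = 1e-8)
  expect_equal(f2$beta[1] * 10, f1$beta[1], tolerance = 1e-8)
})

test_that("fits are deterministic and idempotent at their fixed point", {
  toy <- toy_separable(seed = 15, n = 50)
  cfg <- penalty_config("LOGSUM_L2", lam = 0.3, lam1 = 0.5, lam2 = 0.5)
  f1 <- fit_penalized_logistic(toy$X, toy$y, cfg)
  f2 <- fit_penalized_logistic(toy$X, toy$y, cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$beta0, f2$beta0)

  # refit warm-started from the solution stays at the solution
  f3 <- fit_penalized_logistic(toy$X, toy$y, cfg,
                               beta_init = list(beta0 = f1$beta0,
                                                beta = f1$beta))
  expect_equal(f3$beta, f1$beta, tolerance = 1e-3)
  expect_identical(which(f3$beta != 0), which(f1$beta != 0))

  # at convergence one more sweep moves nothing beyond tol
  s <- std_pop(toy$X)
  beta_std <- f1$beta * s$s
  beta0_std <- f1$beta0 + sum(f1$beta * s$mu)
  eta <- beta0_std + drop(s$X %*% beta_std)
  wr <- working_response(eta, toy$y)
  sw <- cd_sweep(s$X, wr$Z, wr$W / (length(toy$y) / 4), beta_std, beta0_std,
                 cfg)
  expect_lt(sw$max_change, solver_settings()$tol)
})

test_that("degenerate inputs are rejected with clear errors", {
  toy <- toy_separable(seed = 2, n = 20)
  expect_error(fit_penalized_logistic(toy$X, rep(1, 20),
                                      penalty_config("L1", lam = 0.1)),
               "both classes")
  Xna <- toy$X; Xna[1, 1] <- NA
  expect_error(fit_penalized_logistic(Xna, toy$y,
                                      penalty_config("L1", lam = 0.1)),
               "missing")
  expect_warning(
    fit_penalized_logistic(toy$X, toy$y, penalty_config("L1", lam = 1e-4),
                           solver_settings(max_outer = 1)),
    "did not converge")
})

test_that("the lasso path agrees with glmnet on both families", {
  library(glmnet)
  withr::with_seed(8, {
    X <- matrix(rnorm(90 * 12), 90, 12)
    y <- drop(X %*% c(2, -1, rep(0, 10))) + rnorm(90, sd = 0.5)
    yb <- as.integer(y > 0)
  })
  tight <- solver_settings(tol = 1e-9, max_inner = 5000, max_outer = 200)
  for (lam in c(0.3, 0.1, 0.02)) {
    ours <- fit_penalized_linear(X, y, penalty_config("L1", lam = lam), tight)
    ref <- glmnet(X, y, family = "gaussian", lambda = lam,
                  standardize = TRUE, thresh = 1e-14)
    expect_equal(unname(ours$beta), as.numeric(ref$beta), tolerance = 1e-6)
    expect_equal(ours$beta0, as.numeric(ref$a0), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # logistic: our loss is scaled by n/4, so glmnet's lambda is lam/4
  for (lam in c(0.2, 0.05)) {
    ours <- fit_penalized_logistic(X, yb, penalty_config("L1", lam = lam),
                                   tight)
    ref <- glmnet(X, yb, family = "binomial", lambda = lam / 4,
                  standardize = TRUE, thresh = 1e-14)
    expect_equal(unname(ours$beta), as.numeric(ref$beta), tolerance = 1e-5)
    expect_equal(ours$beta0, as.numeric(ref$a0), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})
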