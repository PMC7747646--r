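# Thresholding operators: closed forms, invariants, and the brute-force
# univariate-objective oracle.

ops <- list(
  soft   = function(w) soft_threshold(w, 1),
  en     = function(w) en_threshold(w, 1, 0.4),
  scad   = function(w) scad_threshold(w, 1, 3.7),
  mcp    = function(w) mcp_threshold(w, 1, 3),
  half   = function(w) half_threshold(w, 1),
  hlr    = function(w) hlr_threshold(w, 1, 0.6),
  logsum = function(w) logsum_threshold(w, 1, 0.01),
  ll2    = function(w) logsum_l2_threshold(w, 0.5, 0.5, 0.01)
)

test_that("closed-form operators reproduce hand-derived values", {
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-3, 1), -2)

  expect_equal(en_threshold(3, 1, 1), 2)
  expect_equal(en_threshold(3, 1, 0), 1.5)
  expect_equal(en_threshold(0.5, 1, 1), 0)

  expect_equal(scad_threshold(0.8, 0.5, 3.7), 0.3)
  expect_equal(scad_threshold(5, 1, 3.7), 5)
  # middle branch: S(3, 3.7/2.7) / (1 - 1/2.7)
  expect_equal(scad_threshold(3, 1, 3.7),
               (3 - 3.7 / 2.7) / (1 - 1 / 2.7), tolerance = 1e-12)

  expect_equal(mcp_threshold(5, 1, 3), 5)
  expect_equal(mcp_threshold(2, 1, 3), 1.5)
  expect_equal(mcp_threshold(3, 1, 3), 3)  # continuity at gamma * lam

  expect_equal(half_threshold(0, 1), 0)
  expect_equal(half_threshold(0.5, 1), 0)

  expect_equal(hlr_threshold(2, 1, 1), half_threshold(2, 1))
  expect_equal(hlr_threshold(2, 1, 0), 1)
  expect_equal(hlr_threshold(0, 1, 0.5), 0)

  expect_equal(logsum_threshold(0, 1, 0.01), 0)
  expect_equal(logsum_threshold(3, 1, 0.01),
               (2.99 + sqrt(2.99^2 - 4 * (1 - 0.03))) / 2, tolerance = 1e-12)
  expect_equal(logsum_threshold(-3, 1, 0.01),
               -logsum_threshold(3, 1, 0.01))

  expect_equal(logsum_l2_threshold(1, 1, 0, 0.01), 0)  # |w| <= 1.99
  expect_equal(logsum_l2_threshold(3, 1, 0, 0.01),
               logsum_threshold(3, 1, 0.01), tolerance = 1e-12)
  expect_equal(logsum_l2_threshold(3, 0.5, 0.5, 0.01),
               ((3 - 0.02) + sqrt(3.02^2 - 4)) / 4, tolerance = 1e-12)
})

test_that("every operator fixes zero and is odd in w", {
  w <- seq(-6, 6, by = 0.37)
  for (nm in names(ops)) {
    f <- ops[[nm]]
    expect_identical(f(0), 0, info = nm)
    expect_equal(f(-w), -f(w), tolerance = 1e-14, info = nm)
  }
})

test_that("operator magnitudes are nondecreasing in |w|", {
  w <- seq(0, 10, by = 0.01)
  for (nm in names(ops)) {
    out <- abs(ops[[nm]](w))
    expect_true(all(diff(out) >= -1e-10), info = nm)
  }
})

test_that("zero bands match their stated thresholds", {
  check_band <- function(f, thr, info) {
    step <- 1e-4
    w <- seq(max(0, thr - 50 * step), thr + 50 * step, by = step)
    out <- f(w)
    # all-zero up to the threshold, nonzero strictly beyond it
    expect_true(all(out[w <= thr] == 0), info = info)
    expect_true(all(out[w > thr + step] != 0), info = info)
  }
  check_band(function(w) soft_threshold(w, 0.8), 0.8, "soft")
  check_band(function(w) en_threshold(w, 0.8, 0.5), 0.8 * 0.5, "en")
  # half-squared-error convention: band is (3/2) lam^(2/3)
  check_band(function(w) half_threshold(w, 0.7), 1.5 * 0.7^(2 / 3), "half")
  A <- 1 + 2 * 0.4
  check_band(function(w) logsum_l2_threshold(w, 0.6, 0.4, 0.01),
             2 * sqrt(0.6 * A) - A * 0.01, "logsum_l2")
})

test_that("convex and folded-concave operators equal the grid-search oracle", {
  w <- seq(-8, 8, by = 0.25)
  cases <- list(
    list(cfg = penalty_config("L1", lam = 0.7),
         f = function(w) soft_threshold(w, 0.7)),
    list(cfg = penalty_config("EN", lam = 1.2, a = 0.3),
         f = function(w) en_threshold(w, 1.2, 0.3)),
    list(cfg = penalty_config("SCAD", lam = 0.9, scad_a = 3.7),
         f = function(w) scad_threshold(w, 0.9, 3.7)),
    list(cfg = penalty_config("MCP", lam = 0.8, gamma = 2.5),
         f = function(w) mcp_threshold(w, 0.8, 2.5)),
    list(cfg = penalty_config("HALF", lam = 1),
         f = function(w) half_threshold(w, 1)))
  for (cs in cases) {
    oracle <- vapply(w, oracle_minimize, numeric(1), cfg = cs$cfg)
    expect_equal(cs$f(w), oracle, tolerance = 1e-6, info = cs$cfg$kind)
  }
})

test_that("nonzero log-penalty outputs are stationary points", {
  w <- seq(-8, 8, by = 0.05)
  # LOGSUM: beta - w + lam * sign(beta) / (|beta| + eps) = 0
  for (lam in c(0.5, 1, 2)) {
    b <- logsum_threshold(w, lam, 0.01)
    nz <- b != 0
    g <- b[nz] - w[nz] + lam * sign(b[nz]) / (abs(b[nz]) + 0.01)
    expect_true(all(abs(g) < 1e-8))
  }
  # LOGSUM_L2: (1 + 2*lam2)*beta - w + lam1 * sign(beta)/(|beta| + eps) = 0
  for (l1 in c(0.3, 0.5, 0.9)) {
    b <- logsum_l2_threshold(w, l1, 1 - l1, 0.01)
    nz <- b != 0
    g <- (1 + 2 * (1 - l1)) * b[nz] - w[nz] +
      l1 * sign(b[nz]) / (abs(b[nz]) + 0.01)
    expect_true(all(abs(g) < 1e-8))
  }
})

test_that("reduction identities hold pointwise", {
  w <- seq(-10, 10, by = 0.01)
  expect_equal(en_threshold(w, 1.3, 1), soft_threshold(w, 1.3),
               tolerance = 1e-12)
  expect_equal(hlr_threshold(w, 1.3, 1), half_threshold(w, 1.3),
               tolerance = 1e-12)
  expect_equal(logsum_l2_threshold(w, 1, 0, 0.02),
               logsum_threshold(w, 1, 0.02), tolerance = 1e-12)
  # the unconstrained kernel collapses for any lam1 when lam2 = 0
  expect_equal(logsumlr:::.logsum_l2_core(w, 0.6, 0, 0.01),
               logsum_threshold(w, 0.6, 0.01), tolerance = 1e-12)
})

test_that("the LogSum+L2 operator is asymptotically unbiased at lam2 = 0", {
  b <- logsum_l2_threshold(1e3, 1, 0, 0.01)
  expect_lt(abs(b - 1e3) / 1e3, 1e-2)
  # lam2 > 0 keeps a persistent ridge shrink of 1/(1 + 2*lam2)
  b2 <- logsum_l2_threshold(1e3, 0.5, 0.5, 0.01)
  expect_equal(b2 / 1e3, 1 / (1 + 2 * 0.5), tolerance = 1e-2)
})

test_that("the LogSum+L2 zero band can disagree with the oracle just above threshold", {
  # The closed-form rule turns on where the discriminant produces a real
  # root, not where the objective value at the root crosses the value at
  # zero; immediately above the threshold the nonzero output may have a
  # (slightly) higher objective than zero.  This property is recorded
  # here rather than hidden: the operator follows the closed form, and
  # the band where it departs from the global minimizer is narrow.
  l1 <- 0.7; l2 <- 0.3; eps <- 0.01
  thr <- logsumlr:::logsum_l2_zero_band(l1, l2, eps)
  w <- thr + 1e-3
  b <- logsum_l2_threshold(w, l1, l2, eps)
  expect_gt(b, 0)  # closed form fires
  cfg <- penalty_config("LOGSUM_L2", lam = 1, lam1 = l1, lam2 = l2,
                        eps = eps)
  expect_gt(univariate_objective(b, w, cfg),
            univariate_objective(0, w, cfg))
  expect_equal(oracle_minimize(w, cfg), 0)  # the oracle stays at zero
  # well above the threshold the two agree again
  w2 <- thr + 2
  expect_equal(logsum_l2_threshold(w2, l1, l2, eps),
               oracle_minimize(w2, cfg), tolerance = 1e-6)
})

test_that("invalid operator arguments are rejected", {
  expect_error(soft_threshold(NA_real_, 1), "finite")
  expect_error(soft_threshold(1, -1), "positive")
  expect_error(en_threshold(1, 1, 1.5), "\\[0, 1\\]")
  expect_error(scad_threshold(1, 1, 2), "exceed 2")
  expect_error(mcp_threshold(1, 1, 1), "exceed 1")
  expect_error(half_threshold(1, 0), "positive")
  expect_error(logsum_threshold(1, 1, 1.2), "sqrt")
  expect_error(logsum_l2_threshold(1, 0.5, 0.2, 0.01), "lam1 \\+ lam2")
  # eps large enough to close the zero band entirely
  expect_error(logsum_l2_threshold(1, 1e-5, 1 - 1e-5, 0.1), "zero-band")
  expect_error(penalty_config("LOGSUM", lam = 0.0001, eps = 0.02), "sqrt")
  expect_error(penalty_config("LOGSUM_L2", lam = 1e-4, lam1 = 0.5,
                              lam2 = 0.5, eps = 0.1), "zero-band")
})

test_that("univariate objective and oracle reproduce derived values", {
  expect_equal(univariate_objective(0, 0, penalty_config("L1", lam = 1)), 0)
  expect_equal(univariate_objective(2, 3, penalty_config("L1", lam = 1)), 2.5)
  cfg <- penalty_config("LOGSUM_L2", lam = 1, lam1 = 0.5, lam2 = 0.5,
                        eps = 0.01)
  expect_equal(univariate_objective(1, 1, cfg), 0.5 * log(1.01) + 0.5)

  expect_equal(oracle_minimize(3, penalty_config("L1", lam = 1)), 2,
               tolerance = 1e-6)
  expect_equal(oracle_minimize(0.5, penalty_config("LOGSUM_L2", lam = 1,
                                                   lam1 = 1, lam2 = 0,
                                                   eps = 0.01)), 0)
  expect_equal(oracle_minimize(3, penalty_config("EN", lam = 1, a = 0)), 1.5,
               tolerance = 1e-6)
  expect_equal(oracle_minimize(2, penalty_config("HALF", lam = 1)),
               half_threshold(2, 1), tolerance = 1e-6)
})

test_that("the C++ kernel matches the R operators, including curvature scaling", {
  w <- seq(-5, 5, by = 0.11)
  kernels <- list(
    list(code = 0L, r = function(w) soft_threshold(w, 0.8),
         lam = 0.8, l1 = 0, l2 = 0),
    list(code = 1L, r = function(w) en_threshold(w, 0.8, 0.4),
         lam = 0.8, l1 = 0, l2 = 0),
    list(code = 2L, r = function(w) scad_threshold(w, 0.8, 3.7),
         lam = 0.8, l1 = 0, l2 = 0),
    list(code = 3L, r = function(w) mcp_threshold(w, 0.8, 3),
         lam = 0.8, l1 = 0, l2 = 0),
    list(code = 4L, r = function(w) half_threshold(w, 0.8),
         lam = 0.8, l1 = 0, l2 = 0),
    list(code = 5L, r = function(w) hlr_threshold(w, 0.8, 0.4),
         lam = 0.8, l1 = 0, l2 = 0),
    list(code = 6L, r = function(w) logsum_threshold(w, 0.8, 0.01),
         lam = 0.8, l1 = 0, l2 = 0),
    list(code = 7L, r = function(w) logsum_l2_threshold(w, 0.7, 0.3, 0.01),
         lam = 1, l1 = 0.7, l2 = 0.3))
  for (kr in kernels) {
    got <- logsumlr:::.cpp_threshold(w, 1, kr$code, kr$lam, 0.4, 3.7, 3,
                                     kr$l1, kr$l2, 0.01)
    expect_equal(got, kr$r(w), tolerance = 1e-14, info = kr$code)
  }
  # curvature scaling: solving v/2 (b - w/v)^2 + P(b) via rescaled operator
  v <- 0.6
  got <- logsumlr:::.cpp_threshold(w, v, 0L, 0.8, 0, 0, 0, 0, 0, 0)
  expect_equal(got, soft_threshold(w / v, 0.8 / v), tolerance = 1e-14)
  cfg <- penalty_config("MCP", lam = 0.5, gamma = 3)
  for (wi in c(-3, -1.2, 0.4, 2.5)) {
    got <- logsumlr:::.cpp_threshold(wi, v, 3L, 0.5, 0, 0, 3, 0, 0, 0.01)
    oracle <- optimize(function(b) 0.5 * v * (b - wi / v)^2 +
                         penalty_value(b, cfg), c(-8, 8), tol = 1e-10)
    cand <- c(oracle$minimum, 0)
    obj <- function(b) 0.5 * v * (b - wi / v)^2 + penalty_value(b, cfg)
    best <- cand[which.min(vapply(cand, obj, numeric(1)))]
    expect_equal(got, best, tolerance = 1e-5)
  }
})
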