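#' Penalty configuration
#'
#' Bundles the penalty family and its tuning parameters into a validated
#' configuration object consumed by the thresholding operators, the
#' coordinate-descent solver and the cross-validation tuner.
#'
#' Families and the parameters they consult (all others are ignored):
#' \describe{
#'   \item{`L1`}{lasso, \eqn{\lambda |\beta|}; uses `lam`.}
#'   \item{`EN`}{elastic net, \eqn{\lambda(a|\beta| + (1-a)\beta^2/2)};
#'     uses `lam`, `a`.}
#'   \item{`SCAD`}{smoothly clipped absolute deviation; uses `lam`,
#'     `scad_a` (shape, must exceed 2).}
#'   \item{`MCP`}{minimax concave penalty; uses `lam`, `gamma` (> 1).}
#'   \item{`HALF`}{\eqn{L_{1/2}}, \eqn{\lambda |\beta|^{1/2}}; uses `lam`.}
#'   \item{`HLR`}{half lasso + ridge,
#'     \eqn{\lambda(a|\beta|^{1/2} + (1-a)\beta^2/2)}; uses `lam`, `a`.}
#'   \item{`LOGSUM`}{log-sum, \eqn{\lambda \log(|\beta|+\epsilon)};
#'     uses `lam`, `eps`, with \eqn{0 < \epsilon < \sqrt{\lambda}}.}
#'   \item{`LOGSUM_L2`}{log-sum plus ridge,
#'     \eqn{\lambda(\lambda_1 \log(|\beta|+\epsilon) + \lambda_2 \beta^2)}
#'     with \eqn{\lambda_1 + \lambda_2 = 1}; uses `lam`, `lam1`, `lam2`,
#'     `eps`.  The effective log-sum and ridge weights passed to the
#'     operator are \eqn{\lambda \lambda_1} and \eqn{\lambda \lambda_2},
#'     so the overall `lam` traces the regularization path while the
#'     mixing `lam1` controls the sparsity/grouping tradeoff.}
#' }
#'
#' For `LOGSUM_L2` the zero-band half-width is
#' \eqn{2\sqrt{\lambda_1'(1+2\lambda_2')} - (1+2\lambda_2')\epsilon}
#' (primes denoting the effective weights); configurations for which this
#' is not positive are rejected, since they would have an empty zero band
#' and produce dense solutions.
#'
#' @param kind Penalty family, one of `"L1"`, `"EN"`, `"SCAD"`, `"MCP"`,
#'   `"HALF"`, `"HLR"`, `"LOGSUM"`, `"LOGSUM_L2"`.
#' @param lam Overall regularization level \eqn{\lambda > 0}.
#' @param a Mixing weight in \[0, 1\] for `EN` and `HLR` (1 = pure
#'   sparsity-inducing part, 0 = pure ridge).
#' @param scad_a SCAD shape parameter, must be > 2 (default 3.7).
#' @param gamma MCP concavity parameter, must be > 1 (default 3).
#' @param lam1,lam2 Log-sum and ridge weights for `LOGSUM_L2`; must be
#'   nonnegative and sum to 1 (within 1e-12).
#' @param eps Log-sum offset \eqn{\epsilon > 0} (default 0.01).
#'
#' @return An object of class `penalty_config` (a named list).
#' @examples
#' penalty_config("L1", lam = 0.5)
#' penalty_config("LOGSUM_L2", lam = 1, lam1 = 0.7, lam2 = 0.3)
#' @export
penalty_config <- function(kind = c("L1", "EN", "SCAD", "MCP", "HALF", "HLR",
                                    "LOGSUM", "LOGSUM_L2"),
                           lam = 1, a = 0.5, scad_a = 3.7, gamma = 3,
                           lam1 = 0.5, lam2 = 0.5, eps = 0.01) {
  kind <- match.arg(kind)
  .check_scalar(lam, "lam")
  if (lam <= 0) stop("`lam` must be positive", call. = FALSE)
  if (kind %in% c("EN", "HLR")) {
    .check_scalar(a, "a")
    if (a < 0 || a > 1) stop("mixing `a` must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "SCAD") {
    .check_scalar(scad_a, "scad_a")
    if (scad_a <= 2) stop("`scad_a` must exceed 2", call. = FALSE)
  }
  if (kind == "MCP") {
    .check_scalar(gamma, "gamma")
    if (gamma <= 1) stop("`gamma` must exceed 1", call. = FALSE)
  }
  if (kind %in% c("LOGSUM", "LOGSUM_L2", "HALF")) {
    # eps only used by the log penalties, harmless elsewhere
  }
  if (kind == "LOGSUM") {
    .check_scalar(eps, "eps")
    if (eps <= 0) stop("`eps` must be positive", call. = FALSE)
    if (eps >= sqrt(lam)) {
      stop("LOGSUM requires 0 < eps < sqrt(lam); got eps = ", eps,
           " with sqrt(lam) = ", signif(sqrt(lam), 6), call. = FALSE)
    }
  }
  if (kind == "LOGSUM_L2") {
    .check_scalar(lam1, "lam1"); .check_scalar(lam2, "lam2")
    .check_scalar(eps, "eps")
    if (lam1 < 0 || lam2 < 0) stop("`lam1`, `lam2` must be nonnegative", call. = FALSE)
    if (abs(lam1 + lam2 - 1) > 1e-12) {
      stop("LOGSUM_L2 requires lam1 + lam2 = 1; got ", lam1 + lam2, call. = FALSE)
    }
    if (eps <= 0) stop("`eps` must be positive", call. = FALSE)
    thr <- logsum_l2_zero_band(lam * lam1, lam * lam2, eps)
    if (!is.finite(thr) || thr <= 0) {
      stop("LOGSUM_L2 zero-band half-width 2*sqrt(lam1'(1+2*lam2')) - ",
           "(1+2*lam2')*eps must be positive; got ", signif(thr, 6),
           " for effective lam1' = ", lam * lam1, ", lam2' = ", lam * lam2,
           ", eps = ", eps, call. = FALSE)
    }
  }
  structure(list(kind = kind, lam = lam, a = a, scad_a = scad_a,
                 gamma = gamma, lam1 = lam1, lam2 = lam2, eps = eps),
            class = "penalty_config")
}

#' @export
print.penalty_config <- function(x, ...) {
  pars <- switch(x$kind,
    L1        = sprintf("lam = %g", x$lam),
    EN        = sprintf("lam = %g, a = %g", x$lam, x$a),
    SCAD      = sprintf("lam = %g, scad_a = %g", x$lam, x$scad_a),
    MCP       = sprintf("lam = %g, gamma = %g", x$lam, x$gamma),
    HALF      = sprintf("lam = %g", x$lam),
    HLR       = sprintf("lam = %g, a = %g", x$lam, x$a),
    LOGSUM    = sprintf("lam = %g, eps = %g", x$lam, x$eps),
    LOGSUM_L2 = sprintf("lam = %g, lam1 = %g, lam2 = %g, eps = %g",
                        x$lam, x$lam1, x$lam2, x$eps))
  cat("<penalty_config> ", x$kind, " (", pars, ")\n", sep = "")
  invisible(x)
}

# zero-band half-width of the LogSum+L2 operator for (raw) weights l1, l2
logsum_l2_zero_band <- function(l1, l2, eps) {
  A <- 1 + 2 * l2
  2 * sqrt(l1 * A) - A * eps
}

.check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(TRUE)
}
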