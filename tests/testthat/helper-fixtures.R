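# Shared fixtures and independent oracles for the test suite.

# population-sd standardization, mirroring the solver's convention
std_pop <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  s <- sqrt(colSums(Xc^2) / nrow(X))
  list(X = sweep(Xc, 2, s, "/"), mu = mu, s = s)
}

# small two-feature regression fixture with correlated columns
toy_p2 <- function(seed = 42, n = 20) {
  withr::with_seed(seed, {
    x1 <- rnorm(n)
    x2 <- 0.5 * x1 + rnorm(n)
    X <- cbind(x1, x2)
    y <- drop(X %*% c(1.5, -1)) + rnorm(n, sd = 0.4)
    list(X = X, y = y)
  })
}

# separable two-feature classification toy
toy_separable <- function(seed = 7, n = 40) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 2), n, 2)
    y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
    list(X = X, y = y)
  })
}

# independent 2-D grid oracle for the penalized Gaussian objective
#   0.5 * mean((yc - Xs b)^2) + P(b1) + P(b2)
# on standardized columns (intercept decouples to mean(y)); two-stage
# grid refinement down to `step_fine`.
grid_oracle_p2 <- function(X, y, cfg, lim = 3, step_coarse = 0.01,
                           step_fine = 1e-5) {
  s <- std_pop(X)
  yc <- y - mean(y)
  obj_vec <- function(b1, b2) {
    # residual cross terms expanded to stay vectorized over the grid
    n <- length(yc)
    g11 <- sum(s$X[, 1]^2) / n; g22 <- sum(s$X[, 2]^2) / n
    g12 <- sum(s$X[, 1] * s$X[, 2]) / n
    c1 <- sum(s$X[, 1] * yc) / n; c2 <- sum(s$X[, 2] * yc) / n
    0.5 * (mean(yc^2) - 2 * (b1 * c1 + b2 * c2) +
             b1^2 * g11 + b2^2 * g22 + 2 * b1 * b2 * g12) +
      penalty_value(b1, cfg) + penalty_value(b2, cfg)
  }
  search <- function(c1, c2, half, step) {
    b1 <- seq(c1 - half, c1 + half, by = step)
    b2 <- seq(c2 - half, c2 + half, by = step)
    gg <- expand.grid(b1 = b1, b2 = b2)
    v <- obj_vec(gg$b1, gg$b2)
    gg[which.min(v), ]
  }
  best <- search(0, 0, lim, step_coarse)
  best <- search(best$b1, best$b2, 2 * step_coarse, step_coarse / 20)
  best <- search(best$b1, best$b2, step_coarse / 10, step_fine)
  c(best$b1, best$b2)
}

# brute-force AUC over all positive/negative pairs
auc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (sp in pos) for (sn in neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(pos) * length(neg))
}

# write a small GEO-style series matrix fixture; returns the path
write_series_matrix_fixture <- function(path,
                                        dup_probe = FALSE,
                                        bad_cell = FALSE) {
  samples <- c("GSM1", "GSM2", "GSM3", "GSM4")
  titles <- c("tumor_a", "normal_a", "tumor_b", "normal_b")
  probes <- c("1007_s_at", "1053_at", "117_at")
  if (dup_probe) probes[2] <- probes[1]
  set.seed(99)
  vals <- matrix(round(rnorm(12, 8, 2), 3), 3, 4)
  if (bad_cell) vals[2, 3] <- NA
  rows <- vapply(seq_len(3), function(i) {
    cells <- if (bad_cell && i == 2) {
      v <- as.character(vals[i, ]); v[3] <- "null"; v
    } else as.character(vals[i, ])
    paste(c(sprintf('"%s"', probes[i]), cells), collapse = "\t")
  }, character(1))
  lines <- c(
    "!Series_title\t\"synthetic lung cancer fixture\"",
    paste(c("!Sample_title", sprintf('"%s"', titles)), collapse = "\t"),
    paste(c("!Sample_geo_accession", sprintf('"%s"', samples)),
          collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c('"ID_REF"', sprintf('"%s"', samples)), collapse = "\t"),
    rows,
    "!series_matrix_table_end")
  writeLines(lines, path)
  path
}
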