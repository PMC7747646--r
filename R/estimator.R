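#' Labeled dataset container
#'
#' Couples a numeric feature matrix with binary labels, feature
#' identifiers and (for simulated data) the true coefficient vector used
#' to generate the labels, enabling support-recovery metrics downstream.
#' Label coding: `y = 1` is the positive class (e.g. tumor), `y = 0` the
#' reference class.
#'
#' @param X Numeric matrix, samples x features, no missing values.
#' @param y Binary vector (0/1), length `nrow(X)`.
#' @param feature_ids Unique feature identifiers (defaults to column
#'   names, or `V1..Vp`).
#' @param true_beta Optional true coefficient vector (length `ncol(X)`).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(X, y, feature_ids = colnames(X), true_beta = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    stop("`X` must contain only finite values", call. = FALSE)
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("`y` must be coded 0/1", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- paste0("V", seq_len(ncol(X)))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(X)) {
    stop("`feature_ids` must have one entry per column", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("`feature_ids` must be unique", call. = FALSE)
  }
  if (!is.null(true_beta)) {
    true_beta <- as.numeric(true_beta)
    if (length(true_beta) != ncol(X)) {
      stop("`true_beta` must have one entry per feature", call. = FALSE)
    }
  }
  colnames(X) <- feature_ids
  structure(list(X = X, y = y, feature_ids = feature_ids,
                 true_beta = true_beta),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$X), " samples x ", ncol(x$X), " features; ",
      sum(x$y == 1L), " positive / ", sum(x$y == 0L), " negative",
      if (!is.null(x$true_beta)) sprintf("; %d true nonzero coefficients",
                                         sum(x$true_beta != 0)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Predicted class-1 probabilities
#'
#' Evaluates \eqn{P(y = 1 \mid x) = \mathrm{logistic}(\beta_0 + x\beta)}
#' for a fitted model.
#'
#' @param fit A `penfit` from [fit_penalized_logistic()].
#' @param X Feature matrix with the same number of columns as the fit.
#' @return Probability vector in (0, 1).
#' @export
predict_proba <- function(fit, X) {
  stopifnot(inherits(fit, "penfit"))
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta)) {
    stop("`X` has ", ncol(X), " columns but the fit has ", length(fit$beta),
         " coefficients", call. = FALSE)
  }
  plogis(fit$beta0 + drop(X %*% fit$beta))
}

#' Classify samples at a probability cutoff
#'
#' Labels a sample 1 when its predicted class-1 probability is greater
#' than or equal to `cut` (the boundary case maps to 1).
#'
#' @inheritParams predict_proba
#' @param cut Probability cutoff in (0, 1).
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(fit, X, cut = 0.5) {
  if (!(cut > 0 && cut < 1)) stop("`cut` must lie in (0, 1)", call. = FALSE)
  as.integer(predict_proba(fit, X) >= cut)
}

#' @export
predict.penfit <- function(object, newx,
                           type = c("response", "class", "link"),
                           cut = 0.5, ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  eta <- object$beta0 + drop(newx %*% object$beta)
  switch(type,
         link = eta,
         response = plogis(eta),
         class = as.integer(plogis(eta) >= cut))
}

#' Indices of selected features
#'
#' Features whose fitted coefficient exceeds `tol` in absolute value;
#' the thresholding operators produce exact zeros, so the default
#' `tol = 0` reports the model's support directly.  The length of the
#' result is the "number of selected genes" in expression applications.
#'
#' @param fit A `penfit`.
#' @param tol Nonnegative magnitude threshold.
#' @return Sorted integer indices (1-based).
#' @export
select_support <- function(fit, tol = 0) {
  stopifnot(inherits(fit, "penfit"))
  sort(which(abs(fit$beta) > tol))
}

#' Largest penalty level with an all-zero solution
#'
#' Smallest overall `lam` at which every coordinate of the null-model
#' partial-residual statistic falls inside the operator's zero band, so
#' the fitted coefficient vector is exactly zero.  Used as the top of
#' the warm-start path in [default_grid()].
#'
#' @param X Feature matrix (standardized internally, matching the solver).
#' @param y Binary labels.
#' @param kind Penalty family.
#' @param a,lam1,eps Family parameters where relevant.
#' @return Positive scalar.
#' @export
lambda_max <- function(X, y, kind = "L1", a = 1, lam1 = 0.5, eps = 0.01) {
  X <- .validate_xy(X, y, binary = TRUE)
  std <- .standardize(X)
  f <- mean(y)
  # null-model w_j under the solver's weight normalization (W / (n/4))
  w <- 4 * drop(crossprod(std$X, y - f)) / nrow(X)
  wmax <- max(abs(w))
  switch(kind,
    L1 = , SCAD = , MCP = wmax,
    EN = wmax / max(a, 1e-3),
    HALF = (wmax / 1.5)^1.5,
    HLR = (wmax / 1.5)^1.5 / max(a, 1e-3),
    LOGSUM = (wmax + eps)^2 / 4,
    LOGSUM_L2 = {
      lam <- (wmax + eps)^2 / (4 * lam1)
      for (i in 1:100) {
        if (logsum_l2_zero_band(lam * lam1, lam * (1 - lam1), eps) >= wmax) break
        lam <- lam * 1.5
      }
      lam
    },
    stop("unknown penalty kind ", kind, call. = FALSE))
}

#' Default cross-validation grid
#'
#' Builds the search grid for [cross_validate()]: a log-spaced path of
#' `nlambda` overall penalty levels from [lambda_max()] down to
#' `lambda_min_ratio` times it, crossed with the family's mixing
#' parameters (`a` for EN/HLR; `lam1` and `eps` for LOGSUM_L2, with
#' `lam2 = 1 - lam1`).  Log-penalty configurations violating
#' \eqn{\epsilon < \sqrt{\lambda}} or with a nonpositive zero band are
#' filtered out.  Within each mixing block the path is strictly
#' decreasing in `lam`, which [cross_validate()] exploits for warm
#' starts.
#'
#' @param kind Penalty family.
#' @param X,y Data used to anchor the path at `lambda_max`.
#' @param nlambda Path length (default 30).
#' @param lambda_min_ratio Ratio of the smallest to largest `lam`.
#' @param a_values Mixing values for EN/HLR.
#' @param lam1_values Log-sum weights for LOGSUM_L2.
#' @param eps_values Offsets tried for LOGSUM/LOGSUM_L2.
#' @return List of [penalty_config()] objects.
#' @export
default_grid <- function(kind, X, y, nlambda = 30L, lambda_min_ratio = 0.01,
                         a_values = seq(0.1, 0.9, by = 0.1),
                         lam1_values = seq(0.1, 0.9, by = 0.1),
                         eps_values = c(1e-3, 1e-2, 1e-1)) {
  path <- function(lmax) {
    exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  grid <- list()
  add <- function(cfg) grid[[length(grid) + 1L]] <<- cfg
  if (kind %in% c("L1", "SCAD", "MCP", "HALF")) {
    for (lam in path(lambda_max(X, y, kind))) {
      add(penalty_config(kind, lam = lam))
    }
  } else if (kind %in% c("EN", "HLR")) {
    for (a in a_values) {
      for (lam in path(lambda_max(X, y, kind, a = a))) {
        add(penalty_config(kind, lam = lam, a = a))
      }
    }
  } else if (kind == "LOGSUM") {
    for (eps in eps_values) {
      for (lam in path(lambda_max(X, y, kind, eps = eps))) {
        if (eps < sqrt(lam)) add(penalty_config(kind, lam = lam, eps = eps))
      }
    }
  } else if (kind == "LOGSUM_L2") {
    for (eps in eps_values) {
      for (l1 in lam1_values) {
        lmax <- lambda_max(X, y, kind, lam1 = l1, eps = eps)
        for (lam in path(lmax)) {
          if (eps >= sqrt(lam)) next
          cfg <- tryCatch(
            penalty_config(kind, lam = lam, lam1 = l1, lam2 = 1 - l1,
                           eps = eps),
            error = function(e) NULL)
          if (!is.null(cfg)) add(cfg)
        }
      }
    }
  } else {
    stop("unknown penalty kind ", kind, call. = FALSE)
  }
  grid
}

# stratified fold assignment; every sample appears in exactly one fold
.stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k) {
    stop("cannot build ", k, " stratified folds: smallest class has ",
         min(table(y)), " samples", call. = FALSE)
  }
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# can cfg be warm-started from prev (same family block, decreasing lam)?
.warmable <- function(prev, cfg) {
  !is.null(prev) && prev$kind == cfg$kind && prev$lam >= cfg$lam &&
    isTRUE(all.equal(prev[c("a", "lam1", "lam2", "eps")],
                     cfg[c("a", "lam1", "lam2", "eps")], tolerance = 0))
}

#' Cross-validated tuning
#'
#' Stratified k-fold cross-validation over a grid of penalty
#' configurations, scoring each by held-out classification accuracy at
#' the 0.5 cutoff.  Fits within a mixing block are warm-started along
#' the decreasing `lam` path.  Ties in mean accuracy are broken toward
#' sparser models: larger `lam`, then larger `lam1`.
#'
#' @param data A [labeled_dataset()].
#' @param grid List of [penalty_config()], e.g. from [default_grid()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param settings A [solver_settings()].
#' @return An object of class `cv_penlr` with the grid, the fold-by-grid
#'   accuracy matrix, mean accuracies, and the selected `best`
#'   configuration.
#' @export
cross_validate <- function(data, grid, k = 10L, seed = 1L,
                           settings = solver_settings()) {
  stopifnot(inherits(data, "labeled_dataset"), length(grid) >= 1L)
  k <- as.integer(k)
  if (k < 2L || k > nrow(data$X)) stop("need 2 <= k <= n", call. = FALSE)
  fold <- .stratified_folds(data$y, k, seed)
  acc <- matrix(NA_real_, nrow = length(grid), ncol = k)
  for (f in seq_len(k)) {
    tr <- fold != f
    Xtr <- data$X[tr, , drop = FALSE]; ytr <- data$y[tr]
    Xva <- data$X[!tr, , drop = FALSE]; yva <- data$y[!tr]
    prev_cfg <- NULL; prev_fit <- NULL
    for (g in seq_along(grid)) {
      cfg <- grid[[g]]
      init <- if (.warmable(prev_cfg, cfg)) {
        list(beta0 = prev_fit$beta0, beta = prev_fit$beta)
      }
      fit <- suppressWarnings(
        fit_penalized_logistic(Xtr, ytr, cfg, settings, beta_init = init))
      acc[g, f] <- mean(classify(fit, Xva) == yva)
      prev_cfg <- cfg; prev_fit <- fit
    }
  }
  mean_acc <- rowMeans(acc)
  best_ix <- which(mean_acc == max(mean_acc))
  if (length(best_ix) > 1L) {
    lams <- vapply(grid[best_ix], `[[`, numeric(1), "lam")
    l1s <- vapply(grid[best_ix], function(cfg)
      if (cfg$kind == "LOGSUM_L2") cfg$lam1 else 0, numeric(1))
    best_ix <- best_ix[order(-lams, -l1s)][1L]
  }
  structure(list(grid = grid, fold_accuracy = acc, mean_accuracy = mean_acc,
                 best = grid[[best_ix]], best_index = best_ix,
                 k = k, seed = as.integer(seed)),
            class = "cv_penlr")
}

#' @export
print.cv_penlr <- function(x, ...) {
  cat("<cv_penlr> ", length(x$grid), " configurations x ", x$k, " folds\n",
      "  best mean accuracy ", signif(max(x$mean_accuracy), 4), " at:\n",
      sep = "")
  print(x$best)
  invisible(x)
}

#' Read and write labeled datasets as delimited text
#'
#' Layout: header row of feature identifiers, first column the sample
#' identifier, and a final column named `label` holding 0/1.  The
#' delimiter is inferred from the file extension (`.csv` = comma,
#' otherwise tab).
#'
#' @param data A [labeled_dataset()].
#' @param path File path.
#' @return `read_dataset()`: a [labeled_dataset()];
#'   `write_dataset()`: `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = paste0("S", seq_len(nrow(data$X))),
                   data$X, label = data$y, check.names = FALSE)
  colnames(df) <- c("sample_id", data$feature_ids, "label")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"label" %in% colnames(df)) {
    stop("dataset file must contain a `label` column", call. = FALSE)
  }
  feat <- setdiff(colnames(df), c("sample_id", "label"))
  X <- as.matrix(df[, feat, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric feature values in ", path, call. = FALSE)
  labeled_dataset(X, df$label, feature_ids = feat)
}

#' Serialize and restore a fitted model
#'
#' Writes a fit as plain text: a commented metadata block (penalty,
#' parameters, convergence) followed by tab-separated
#' `feature_id  coefficient` rows, with the intercept stored in the
#' metadata.
#'
#' @param fit A `penfit`.
#' @param path File path.
#' @return `write_fit()`: `path` invisibly; `read_fit()`: a list with
#'   `beta0`, `beta` (named), and `meta` (character metadata).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "penfit"))
  p <- fit$penalty
  meta <- c(
    sprintf("# penalty: %s", p$kind),
    sprintf("# lam: %.17g", p$lam),
    sprintf("# a: %.17g", p$a),
    sprintf("# scad_a: %.17g", p$scad_a),
    sprintf("# gamma: %.17g", p$gamma),
    sprintf("# lam1: %.17g", p$lam1),
    sprintf("# lam2: %.17g", p$lam2),
    sprintf("# eps: %.17g", p$eps),
    sprintf("# family: %s", fit$family),
    sprintf("# converged: %s", fit$converged),
    sprintf("# n_iter_outer: %d", fit$n_iter_outer),
    sprintf("# intercept: %.17g", fit$beta0))
  rows <- sprintf("%s\t%.17g", names(fit$beta), fit$beta)
  writeLines(c(meta, "feature_id\tcoefficient", rows), path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\035\\2", m)
    kv <- strsplit(kv, "\035", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[-1L]  # header row
  parts <- strsplit(body, "\t", fixed = TRUE)
  beta <- vapply(parts, function(x) as.numeric(x[2]), numeric(1))
  names(beta) <- vapply(parts, `[[`, character(1), 1L)
  list(beta0 = as.numeric(meta$intercept), beta = beta, meta = meta)
}
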