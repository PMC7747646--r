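#' Study configuration
#'
#' Describes a full simulation study: which scenarios, correlation
#' levels and penalty methods to run, how many seeded replicates, and
#' how to tune.  Each replicate generates a dataset, splits it 70/30,
#' tunes the penalty by stratified k-fold cross-validation on the
#' training part, refits at the selected configuration and evaluates
#' classification and support-recovery metrics on both parts.
#'
#' @param scenarios Subset of `c("scenario1", "scenario2")`.
#' @param rhos Correlation levels, subset of typical `c(0.2, 0.6)`.
#' @param methods Penalty families to compare, subset of
#'   `c("L1", "EN", "HLR", "LOGSUM_L2")` (any [penalty_config()] kind is
#'   accepted).
#' @param n_reps Replicates per cell; replicate `r` uses seed
#'   `base_seed + r`.
#' @param base_seed Base integer seed.
#' @param cv_k Cross-validation folds (default 10).
#' @param train_frac Training fraction of each split (default 0.7).
#' @param grids Optional named list (by method) of grid-builder
#'   functions `function(X, y)` returning lists of [penalty_config()];
#'   defaults to [study_grid()].
#' @param out_dir Optional directory for the written report tables.
#' @param settings A [solver_settings()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(scenarios = c("scenario1", "scenario2"),
                         rhos = c(0.2, 0.6),
                         methods = c("L1", "EN", "HLR", "LOGSUM_L2"),
                         n_reps = 30L, base_seed = 2020L, cv_k = 10L,
                         train_frac = 0.7, grids = NULL, out_dir = NULL,
                         settings = solver_settings()) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (n_reps < 1L) stop("`n_reps` must be at least 1", call. = FALSE)
  if (!all(methods %in% names(.pen_code))) {
    stop("unknown method(s): ",
         paste(setdiff(methods, names(.pen_code)), collapse = ", "),
         call. = FALSE)
  }
  structure(list(scenarios = scenarios, rhos = rhos, methods = methods,
                 n_reps = as.integer(n_reps),
                 base_seed = as.integer(base_seed), cv_k = as.integer(cv_k),
                 train_frac = train_frac, grids = grids, out_dir = out_dir,
                 settings = settings),
            class = "study_config")
}

#' Reduced tuning grid used by the study runner
#'
#' A deliberately compact cross-validation grid keeping the study
#' runner's cost proportionate: the lasso keeps a 30-point
#' log-spaced `lam` path, while the two-parameter families pair a
#' 10-point path with three mixing values (`a` or `lam1` in
#' \{0.1, 0.5, 0.9\}) at fixed `eps = 0.01`.  See [default_grid()] for
#' the full grid.
#'
#' @inheritParams default_grid
#' @return List of [penalty_config()] objects.
#' @export
study_grid <- function(kind, X, y) {
  switch(kind,
    L1 = default_grid("L1", X, y, nlambda = 30L),
    EN = default_grid("EN", X, y, nlambda = 10L, a_values = c(0.1, 0.5, 0.9)),
    HLR = default_grid("HLR", X, y, nlambda = 10L,
                       a_values = c(0.1, 0.5, 0.9)),
    LOGSUM_L2 = default_grid("LOGSUM_L2", X, y, nlambda = 10L,
                             lam1_values = c(0.1, 0.5, 0.9),
                             eps_values = 0.01),
    default_grid(kind, X, y, nlambda = 10L))
}

# one replicate of one study cell; returns a one-row data.frame
.study_replicate <- function(scenario, rho, method, rep, cfg) {
  seed <- cfg$base_seed + rep
  spec <- scenario_spec(scenario, rho = rho)
  data <- simulate_scenario(spec, seed = seed)
  parts <- split_dataset(data, train_frac = cfg$train_frac, seed = seed)
  grid_fun <- if (!is.null(cfg$grids[[method]])) cfg$grids[[method]]
              else function(X, y) study_grid(method, X, y)
  grid <- grid_fun(parts$train$X, parts$train$y)
  cv <- cross_validate(parts$train, grid, k = cfg$cv_k, seed = seed,
                       settings = cfg$settings)
  fit <- suppressWarnings(
    fit_penalized_logistic(parts$train, cfg = cv$best,
                           settings = cfg$settings))
  eval_part <- function(part) {
    pr <- predict_proba(fit, part$X)
    classification_metrics(part$y, as.integer(pr >= 0.5), pr)
  }
  mtr <- eval_part(parts$train)
  mte <- eval_part(parts$test)
  msup <- support_metrics(data$true_beta, fit$beta)
  data.frame(scenario = scenario, rho = rho, method = method, rep = rep,
             seed = seed,
             train_accuracy = mtr$accuracy, train_sensitivity = mtr$sensitivity,
             train_specificity = mtr$specificity, train_auc = mtr$auc,
             test_accuracy = mte$accuracy, test_sensitivity = mte$sensitivity,
             test_specificity = mte$specificity, test_auc = mte$auc,
             beta_sensitivity = msup$beta_sensitivity,
             beta_specificity = msup$beta_specificity,
             n_selected = length(select_support(fit)),
             best_lam = cv$best$lam,
             best_lam1 = if (cv$best$kind == "LOGSUM_L2") cv$best$lam1 else NA_real_,
             cv_accuracy = max(cv$mean_accuracy),
             stringsAsFactors = FALSE)
}

#' Run a simulation study
#'
#' Executes every (scenario, rho, method, replicate) combination of a
#' [study_config()]: generate, split, cross-validate, refit, evaluate.
#' Replicate failures are caught, counted and excluded from the
#' aggregates (with a warning), never silently dropped.  The run is
#' fully determined by the configuration.
#'
#' @param cfg A [study_config()].
#' @return An object of class `study_report`: `replicates` (long
#'   per-replicate data frame), `train_table`, `test_table`,
#'   `support_table` (per-cell mean and sd), `n_failed`, and `config`.
#'   If `cfg$out_dir` is set, the three tables (formatted as
#'   "mean% (sd%)") and the long results are also written there as TSV.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- list()
  failures <- character(0)
  for (scenario in cfg$scenarios) {
    for (rho in cfg$rhos) {
      for (method in cfg$methods) {
        for (rep in seq_len(cfg$n_reps)) {
          res <- tryCatch(.study_replicate(scenario, rho, method, rep, cfg),
                          error = function(e) e)
          if (inherits(res, "error")) {
            failures <- c(failures,
                          sprintf("%s rho=%g %s rep %d: %s", scenario, rho,
                                  method, rep, conditionMessage(res)))
          } else {
            rows[[length(rows) + 1L]] <- res
          }
        }
      }
    }
  }
  if (length(failures)) {
    warning(length(failures), " replicate(s) failed and were excluded:\n",
            paste(failures, collapse = "\n"), call. = FALSE)
  }
  reps <- do.call(rbind, rows)
  agg <- function(cols) {
    out <- list()
    for (cell in split(reps, reps[c("scenario", "rho", "method")], drop = TRUE)) {
      row <- data.frame(scenario = cell$scenario[1], rho = cell$rho[1],
                        method = cell$method[1], n_reps = nrow(cell))
      for (cl in cols) {
        row[[paste0(cl, "_mean")]] <- mean(cell[[cl]], na.rm = TRUE)
        row[[paste0(cl, "_sd")]] <- if (nrow(cell) > 1L) stats::sd(cell[[cl]])
                                    else 0
      }
      out[[length(out) + 1L]] <- row
    }
    out <- do.call(rbind, out)
    out[order(out$scenario, out$rho, out$method), , drop = FALSE]
  }
  report <- structure(list(
    replicates = reps,
    train_table = agg(c("train_accuracy", "train_sensitivity",
                        "train_specificity", "train_auc")),
    test_table = agg(c("test_accuracy", "test_sensitivity",
                       "test_specificity", "test_auc")),
    support_table = agg(c("beta_sensitivity", "beta_specificity",
                          "n_selected")),
    n_failed = length(failures), config = cfg), class = "study_report")
  if (!is.null(cfg$out_dir)) write_study_report(report, cfg$out_dir)
  report
}

#' Write study report tables
#'
#' Emits the three per-cell summary tables (training metrics, test
#' metrics, support recovery) with entries formatted "mean% (sd%)",
#' plus the long per-replicate results, as tab-separated files.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_table <- function(tab, percent_cols) {
    out <- tab[c("scenario", "rho", "method", "n_reps")]
    for (cl in percent_cols) {
      m <- tab[[paste0(cl, "_mean")]]
      s <- tab[[paste0(cl, "_sd")]]
      out[[cl]] <- ifelse(grepl("n_selected", cl),
                          sprintf("%.1f (%.2f)", m, s),
                          sprintf("%.2f%% (%.2f%%)", 100 * m, 100 * s))
    }
    out
  }
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(fmt_table(report$train_table,
              c("train_accuracy", "train_sensitivity", "train_specificity",
                "train_auc")), "table_train.tsv")
  w(fmt_table(report$test_table,
              c("test_accuracy", "test_sensitivity", "test_specificity",
                "test_auc")), "table_test.tsv")
  w(fmt_table(report$support_table,
              c("beta_sensitivity", "beta_specificity", "n_selected")),
    "table_support.tsv")
  w(report$replicates, "replicates.tsv")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$replicates), " replicates across ",
      nrow(x$test_table), " cells (", x$n_failed, " failures)\n", sep = "")
  print(x$test_table, digits = 4)
  invisible(x)
}

#' Load a GEO-style expression matrix
#'
#' Reads a probes x samples expression table -- either a plain
#' tab-separated file with probe identifiers in the first column and
#' sample identifiers in the header, or a GEO Series Matrix file whose
#' table is delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end` marker lines (metadata lines starting
#' with `!` are skipped) -- and transposes it to a samples x features
#' [labeled_dataset()].
#'
#' Labels are supplied through `label_spec`, either a named 0/1 vector
#' keyed by sample identifier, or a list
#' `list(phenotype_row = "!Sample_title", positive = "tumor")` matching
#' a metadata row's fields against a regular expression (matches are
#' labeled 1).  Any sample without a label is an error naming the
#' sample.  Duplicate probe identifiers are suffix-deduplicated with a
#' warning; non-numeric expression cells are rejected.
#'
#' @param path File path.
#' @param label_spec Named 0/1 vector or a `phenotype_row`/`positive`
#'   list (see Details).
#' @return A [labeled_dataset()] with probe identifiers as features.
#' @export
load_expression_matrix <- function(path, label_spec) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  meta <- grep("^!", lines, value = TRUE)
  tbl_lines <- if (length(beg) && length(end)) {
    lines[(beg[1] + 1L):(end[1] - 1L)]
  } else {
    lines[!grepl("^!", lines) & nzchar(lines)]
  }
  strip <- function(x) gsub('^"|"$', "", x)
  cells <- lapply(strsplit(tbl_lines, "\t", fixed = TRUE),
                  function(x) strip(x))
  header <- cells[[1L]]
  samples <- header[-1L]
  probes <- vapply(cells[-1L], `[[`, character(1), 1L)
  vals <- lapply(cells[-1L], function(x) {
    v <- suppressWarnings(as.numeric(x[-1L]))
    if (anyNA(v)) {
      stop("non-numeric expression value(s) in probe row '", x[1L], "'",
           call. = FALSE)
    }
    v
  })
  if (anyDuplicated(probes)) {
    warning("duplicate probe identifier(s) suffix-deduplicated", call. = FALSE)
    probes <- make.unique(probes, sep = "_dup")
  }
  M <- do.call(rbind, vals)  # probes x samples
  rownames(M) <- probes
  colnames(M) <- samples

  if (is.list(label_spec)) {
    row_name <- label_spec$phenotype_row
    pat <- label_spec$positive
    mrow <- grep(paste0("^", row_name, "\\b"), meta, value = TRUE)
    if (!length(mrow)) {
      stop("phenotype row '", row_name, "' not found in metadata", call. = FALSE)
    }
    fields <- strip(strsplit(mrow[1L], "\t", fixed = TRUE)[[1L]][-1L])
    if (length(fields) != length(samples)) {
      stop("phenotype row has ", length(fields), " fields for ",
           length(samples), " samples", call. = FALSE)
    }
    labels <- as.integer(grepl(pat, fields))
    names(labels) <- samples
  } else {
    labels <- label_spec
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing)) {
    stop("no label for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- as.integer(labels[samples])
  labeled_dataset(t(M), y, feature_ids = probes)
}
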