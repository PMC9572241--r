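#' f1-score
#'
#' Per-class f1 (harmonic mean of precision and recall) combined either
#' by the unweighted mean over classes (`"macro"`) or weighted by class
#' support in the truth (`"weighted"`, the default, matching the
#' class-imbalance motivation for using f1 at all). Classes absent from
#' both truth and prediction are excluded; a class with no true or no
#' predicted instances contributes f1 = 0.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param average `"weighted"` or `"macro"`.
#' @return Scalar in [0, 1].
#' @export
f1_score <- function(y_true, y_pred, average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (!length(y_true)) stop_cfg("empty input")
  if (length(y_true) != length(y_pred)) stop_cfg("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  labels <- sort(union(unique(y_true), unique(y_pred)))
  cm <- table(factor(y_true, labels), factor(y_pred, labels))
  tp <- diag(cm)
  n_true <- rowSums(cm); n_pred <- colSums(cm)
  P <- ifelse(n_pred > 0, tp / n_pred, 0)
  R <- ifelse(n_true > 0, tp / n_true, 0)
  f1 <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  if (average == "macro") mean(f1) else sum(f1 * n_true) / sum(n_true)
}

#' Train and evaluate one model family on one task
#'
#' Runs the hyperparameter grid (by default the full 3 learning rates x
#' 3 batch sizes) on the task's training windows: per run, a fresh
#' seeded initialization and validation split, training under the shared
#' protocol, prediction on the task's test windows from the checkpointed
#' parameters, and the f1-score. Handcrafted features are scaled by a
#' Z-score scaler fitted on this task's training rows only; window
#' inputs are normalized by a global (mean, sd) pair from the training
#' windows. Run r uses seed `base_seed + r`. Failed runs are recorded as
#' `NA` with a warning and flagged, never silently dropped.
#'
#' @param task A `task_spec`.
#' @param family Model family name (see [model_spec()]).
#' @param ws The full `window_set`.
#' @param features The unscaled handcrafted `[n x 192]` matrix, rows
#'   aligned with `ws` (required for feature-based and hybrid families).
#' @param base_seed Base integer seed.
#' @param grid data.frame of (learning_rate, batch_size) combinations.
#' @param max_epochs,patience Protocol overrides (defaults 140 / 30).
#' @param average f1 averaging mode.
#' @param class_weight_mode Passed to [class_weights()].
#' @param spec_args Extra arguments forwarded to [model_spec()] (e.g.
#'   `pool_stride`, `filters`) for scaled-down configurations.
#' @return An object of class `task_result`: per-run f1 values, their
#'   mean/sd, the run manifest, and an `incomplete` flag.
#' @export
run_task <- function(task, family, ws, features = NULL, base_seed = 1,
                     grid = hyper_grid(), max_epochs = 140, patience = 30,
                     average = "weighted",
                     class_weight_mode = "inverse-frequency",
                     spec_args = list()) {
  stopifnot(inherits(task, "task_spec"), inherits(ws, "window_set"))
  spec <- do.call(model_spec, c(list(family), spec_args))
  tr_idx <- match(task$train_ids, ws$meta$window_id)
  ts_idx <- match(task$test_ids, ws$meta$window_id)
  if (anyNA(tr_idx) || anyNA(ts_idx)) stop_cfg("task ids missing from window set")
  classes <- canonical_activities()

  need_feat <- spec$input_kind %in% c("features-192", "both")
  need_win <- spec$input_kind %in% c("window", "both")
  if (need_feat && is.null(features)) {
    stop_cfg("family '%s' needs handcrafted features", family)
  }
  ftr <- fte <- NULL
  if (need_feat) {
    sc <- fit_scaler(features[tr_idx, , drop = FALSE])
    ftr <- apply_scaler(sc, features[tr_idx, , drop = FALSE])
    fte <- apply_scaler(sc, features[ts_idx, , drop = FALSE])
  }
  wtr <- wte <- NULL
  if (need_win) {
    wsc <- fit_window_scaler(ws$values[tr_idx, , , drop = FALSE])
    wtr <- apply_window_scaler(wsc, ws$values[tr_idx, , , drop = FALSE])
    wte <- apply_window_scaler(wsc, ws$values[ts_idx, , , drop = FALSE])
  }
  train_data <- list(windows = wtr, features = ftr,
                     labels = ws$meta$label[tr_idx], classes = classes)
  test_data <- list(windows = wte, features = fte)
  y_true <- ws$meta$label[ts_idx]

  f1s <- rep(NA_real_, nrow(grid))
  manifest <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- train_config(learning_rate = grid$learning_rate[r],
                        batch_size = grid$batch_size[r],
                        max_epochs = max_epochs, patience = patience,
                        class_weight_mode = class_weight_mode,
                        seed = base_seed + r)
    res <- tryCatch({
      trained <- train_model(build_model(spec, length(classes)),
                             train_data, cfg)
      pred <- predict(trained, test_data)
      list(f1 = f1_score(y_true, pred, average = average),
           stop_epoch = trained$stop_epoch,
           checkpoint_epoch = trained$checkpoint_epoch)
    }, error = function(e) {
      warning(sprintf("run %d of %s on %s failed: %s", r, family,
                      task$setting, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      f1s[r] <- res$f1
      manifest[[r]] <- data.frame(
        family = family, setting = task$setting,
        target = task$target_dataset,
        source = paste(task$source_datasets, collapse = "+"),
        learning_rate = grid$learning_rate[r], batch_size = grid$batch_size[r],
        seed = base_seed + r, stop_epoch = res$stop_epoch,
        checkpoint_epoch = res$checkpoint_epoch, f1 = res$f1)
    }
  }
  ok <- !is.na(f1s)
  structure(list(family = family, setting = task$setting,
                 target_dataset = task$target_dataset,
                 source_datasets = task$source_datasets,
                 f1_runs = f1s, mean = mean(f1s[ok]),
                 sd = if (sum(ok) > 1) stats::sd(f1s[ok]) else 0,
                 incomplete = any(!ok),
                 manifest = do.call(rbind, manifest)),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result> %s @ %s->%s: f1 = %.3f +/- %.3f over %d run(s)%s\n",
              x$family, paste(x$source_datasets, collapse = "+"),
              x$target_dataset, x$mean, x$sd, sum(!is.na(x$f1_runs)),
              if (x$incomplete) " [INCOMPLETE]" else ""))
  invisible(x)
}

#' Aggregate task results into a per-family, per-setting table
#'
#' Single-source held-out-dataset tasks are first averaged over source
#' datasets per target, so every setting contributes one value per
#' (family, dataset); cells are then mean and sd over datasets, and an
#' `Avg. OOD` column averages the three OOD setting means. Incomplete
#' results trigger a warning and their cells are flagged.
#'
#' @param results List of `task_result`s.
#' @return An object of class `result_table`: long-form data.frame
#'   `cells` plus the formatted wide table `table` (f1 in percent).
#' @export
summarize_results <- function(results) {
  stopifnot(length(results) > 0)
  if (any(vapply(results, function(r) isTRUE(r$incomplete), logical(1)))) {
    warning("some task results are incomplete (failed runs)")
  }
  long <- do.call(rbind, lapply(results, function(r) {
    data.frame(family = r$family, setting = r$setting,
               target = r$target_dataset, mean_f1 = r$mean)
  }))
  # average OOD-SD over sources per target first
  agg <- stats::aggregate(mean_f1 ~ family + setting + target, long, mean)
  cells <- do.call(rbind, lapply(split(agg, agg[c("family", "setting")]),
                                 function(g) {
    if (!nrow(g)) return(NULL)
    data.frame(family = g$family[1], setting = g$setting[1],
               mean = mean(g$mean_f1),
               sd = if (nrow(g) > 1) stats::sd(g$mean_f1) else 0,
               n_datasets = nrow(g))
  }))
  rownames(cells) <- NULL
  settings <- c("ID", "OOD-U", "OOD-MD", "OOD-SD")
  fams <- unique(cells$family)
  wide <- data.frame(family = fams)
  for (s in settings) {
    wide[[s]] <- vapply(fams, function(f) {
      r <- cells[cells$family == f & cells$setting == s, ]
      if (!nrow(r)) return(NA_character_)
      sprintf("%.2f±%.2f", 100 * r$mean, 100 * r$sd)
    }, character(1))
  }
  wide[["Avg. OOD"]] <- vapply(fams, function(f) {
    r <- cells[cells$family == f & cells$setting != "ID", ]
    if (!nrow(r)) return(NA_character_)
    sprintf("%.2f", 100 * mean(r$mean))
  }, character(1))
  structure(list(cells = cells, table = wide), class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Average OOD f1 of one family from a result table
#'
#' @param rt A `result_table`.
#' @param family Family name.
#' @param setting Optionally a single setting instead of the OOD average.
#' @return Scalar mean f1 in [0, 1].
#' @export
result_cell <- function(rt, family, setting = NULL) {
  cells <- rt$cells
  sub <- if (is.null(setting)) {
    cells[cells$family == family & cells$setting != "ID", ]
  } else {
    cells[cells$family == family & cells$setting == setting, ]
  }
  if (!nrow(sub)) return(NA_real_)
  mean(sub$mean)
}

#' Regress f1 on the log distance ratio
#'
#' Least-squares line of per-task mean f1 on the natural logarithm of
#' the task's distance ratio, per family. Performance decaying with
#' distance from the training distribution shows up as a negative slope.
#'
#' @param results List of `task_result`s for one family.
#' @param ratios Named numeric vector of distance-ratio means, one per
#'   task, keyed like `results`' names (or in matching order if
#'   unnamed), from a single representation source.
#' @return An object of class `trend_fit`: `slope`, `intercept`,
#'   `points` (log_ratio, f1_mean, f1_sd per task).
#' @export
trend_fit <- function(results, ratios) {
  stopifnot(length(results) == length(ratios))
  if (length(results) < 3) stop_cfg("need at least 3 tasks for a trend fit")
  pts <- data.frame(
    log_ratio = log(as.numeric(ratios)),
    f1_mean = vapply(results, function(r) r$mean, numeric(1)),
    f1_sd = vapply(results, function(r) r$sd, numeric(1)))
  fit <- stats::lm(f1_mean ~ log_ratio, data = pts)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 points = pts),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> f1 = %.3f %+.3f * ln(ratio) over %d tasks\n",
              x$intercept, x$slope, nrow(x$points)))
  invisible(x)
}

#' Run a full benchmark experiment
#'
#' End-to-end orchestration: build the four-setting task list over a
#' harmonized window set, run every requested family on every task,
#' compute per-task Wasserstein distance ratios on the handcrafted
#' features, and fit the f1-versus-log-ratio trend per family.
#'
#' @param ws Harmonized `window_set`.
#' @param features Handcrafted feature matrix aligned with `ws`.
#' @param families Character vector of family names.
#' @param base_seed Integer seed governing splits, runs and ratios.
#' @param grid Hyperparameter grid (default the full 9 combinations).
#' @param max_epochs,patience Protocol parameters.
#' @param ratio_metric Metric for the per-task ratios.
#' @param n_repeats Bootstrap repeats per ratio.
#' @param spec_args Extra arguments forwarded to [model_spec()].
#' @param ratios Optional precomputed named ratio vector (one per task,
#'   as produced by a previous run with the same `ws` and `split_seed`);
#'   skips the bootstrap stage.
#' @param split_seed Seed for the task splits (defaults to `base_seed`);
#'   keeping it fixed while varying `base_seed` repeats the identical
#'   tasks under fresh training randomness.
#' @return List with `tasks`, `results` (per family), `table`
#'   (a `result_table`), `ratios` (per task), and `trends` (per family).
#' @export
run_experiment <- function(ws, features, families = c("LR", "CNN-base"),
                           base_seed = 1, grid = hyper_grid(),
                           max_epochs = 140, patience = 30,
                           ratio_metric = "wasserstein", n_repeats = 30,
                           spec_args = list(), ratios = NULL,
                           split_seed = base_seed) {
  tasks <- build_tasks(ws, seed = split_seed)
  if (is.null(ratios)) {
    ratios <- vapply(names(tasks), function(nm) {
      task <- tasks[[nm]]
      tr <- features[match(task$train_ids, ws$meta$window_id), , drop = FALSE]
      te <- features[match(task$test_ids, ws$meta$window_id), , drop = FALSE]
      distance_ratio(ratio_metric, tr, te, n_repeats = n_repeats,
                     seed = split_seed)$mean
    }, numeric(1))
  }
  results <- list()
  trends <- list()
  for (fam in families) {
    fam_res <- lapply(tasks, function(task) {
      run_task(task, fam, ws, features, base_seed = base_seed, grid = grid,
               max_epochs = max_epochs, patience = patience,
               spec_args = spec_args)
    })
    results[[fam]] <- fam_res
    trends[[fam]] <- trend_fit(fam_res, ratios)
  }
  list(tasks = tasks, results = results,
       table = summarize_results(unlist(results, recursive = FALSE)),
       ratios = ratios, trends = trends)
}
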