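#' Task specification: one (setting, train, test) evaluation unit
#'
#' @param setting One of `"ID"`, `"OOD-U"`, `"OOD-MD"`, `"OOD-SD"`.
#' @param train_ids,test_ids Disjoint character vectors of window ids.
#' @param source_datasets Datasets contributing training windows.
#' @param target_dataset Dataset whose windows are tested.
#' @param seed Seed that produced the split.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(setting, train_ids, test_ids, source_datasets,
                      target_dataset, seed = NULL) {
  setting <- match.arg(setting, c("ID", "OOD-U", "OOD-MD", "OOD-SD"))
  if (length(intersect(train_ids, test_ids))) {
    stop_cfg("train/test window ids overlap")
  }
  if (!length(train_ids) || !length(test_ids)) {
    stop_cfg("degenerate split: empty train or test side")
  }
  structure(list(setting = setting, train_ids = train_ids,
                 test_ids = test_ids,
                 source_datasets = sort(unique(source_datasets)),
                 target_dataset = target_dataset, seed = seed),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s: %s -> %s | %d train / %d test windows\n",
              x$setting, paste(x$source_datasets, collapse = "+"),
              x$target_dataset, length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

#' In-distribution split of one dataset
#'
#' A uniformly random `test_fraction` of the dataset's windows (without
#' replacement) is held out for testing; subjects may appear on both
#' sides, which is precisely what makes this the in-distribution
#' baseline.
#'
#' @param ws A `window_set` restricted to one dataset.
#' @param test_fraction Fraction of windows for the test side.
#' @param seed Integer seed.
#' @return A `task_spec` with setting `"ID"`.
#' @export
split_id <- function(ws, test_fraction = 0.3, seed = 1) {
  stopifnot(inherits(ws, "window_set"))
  ds <- unique(ws$meta$dataset)
  if (length(ds) != 1) stop_cfg("split_id expects windows of a single dataset")
  n <- n_windows(ws)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n) {
    stop_cfg("test_fraction %.2f yields a degenerate split for %d windows",
             test_fraction, n)
  }
  with_seed(seed, {
    test_idx <- sample.int(n, n_test)
    task_spec("ID", ws$meta$window_id[-test_idx], ws$meta$window_id[test_idx],
              ds, ds, seed)
  })
}

#' Held-out-users split of one dataset
#'
#' Approximately `user_fraction` of the dataset's subjects (at least one,
#' at most all but one) are assigned wholly to the test side; the rest
#' wholly to train, so no subject crosses sides.
#'
#' @param ws A `window_set` restricted to one dataset.
#' @param user_fraction Fraction of subjects held out.
#' @param seed Integer seed.
#' @return A `task_spec` with setting `"OOD-U"`.
#' @export
split_ood_u <- function(ws, user_fraction = 0.3, seed = 1) {
  stopifnot(inherits(ws, "window_set"))
  ds <- unique(ws$meta$dataset)
  if (length(ds) != 1) stop_cfg("split_ood_u expects windows of a single dataset")
  subjects <- unique(ws$meta$subject)
  if (length(subjects) < 2) {
    stop_cfg("held-out-user split impossible with a single subject")
  }
  n_test <- min(max(1, round(user_fraction * length(subjects))),
                length(subjects) - 1)
  with_seed(seed, {
    test_subj <- sample(subjects, n_test)
    test <- ws$meta$subject %in% test_subj
    task_spec("OOD-U", ws$meta$window_id[!test], ws$meta$window_id[test],
              ds, ds, seed)
  })
}

#' Held-out-dataset split with multiple source datasets
#'
#' Training uses all windows of every dataset except the held-out one;
#' the test set is exactly the held-out-users test set of the held-out
#' dataset, so all OOD settings targeting a dataset are evaluated on the
#' identical windows.
#'
#' @param ws The full multi-dataset `window_set`.
#' @param held_out Dataset id to hold out.
#' @param ood_u_tasks Named list (by dataset id) of `"OOD-U"` task specs.
#' @return A `task_spec` with setting `"OOD-MD"`.
#' @export
split_ood_md <- function(ws, held_out, ood_u_tasks) {
  stopifnot(inherits(ws, "window_set"))
  datasets <- unique(ws$meta$dataset)
  if (length(datasets) < 2) stop_cfg("need at least 2 datasets")
  if (!held_out %in% datasets) stop_cfg("unknown dataset '%s'", held_out)
  u <- ood_u_tasks[[held_out]]
  if (is.null(u)) stop_cfg("no held-out-user task for dataset '%s'", held_out)
  train <- ws$meta$window_id[ws$meta$dataset != held_out]
  task_spec("OOD-MD", train, u$test_ids, setdiff(datasets, held_out), held_out)
}

#' Single-source held-out-dataset split
#'
#' Training uses all windows of one source dataset; testing uses the
#' held-out-users test set of a different target dataset.
#'
#' @param ws The full multi-dataset `window_set`.
#' @param source,target Distinct dataset ids.
#' @param ood_u_tasks Named list (by dataset id) of `"OOD-U"` task specs.
#' @return A `task_spec` with setting `"OOD-SD"`.
#' @export
split_ood_sd <- function(ws, source, target, ood_u_tasks) {
  stopifnot(inherits(ws, "window_set"))
  if (identical(source, target)) stop_cfg("source and target must differ")
  u <- ood_u_tasks[[target]]
  if (is.null(u)) stop_cfg("no held-out-user task for dataset '%s'", target)
  train <- ws$meta$window_id[ws$meta$dataset == source]
  task_spec("OOD-SD", train, u$test_ids, source, target)
}

#' Build the full set of domain-generalization tasks
#'
#' One ID and one held-out-users task per dataset, one multi-source
#' held-out-dataset task per dataset, and all N(N-1) ordered
#' single-source pairs. The held-out-users test sets are constructed
#' first and reused as the test side of every OOD task targeting that
#' dataset.
#'
#' @param ws The full multi-dataset `window_set`.
#' @param test_fraction,user_fraction Fractions for the ID and
#'   held-out-users splits.
#' @param seed Integer seed (per-dataset seeds derived deterministically).
#' @return Named list of `task_spec`s.
#' @export
build_tasks <- function(ws, test_fraction = 0.3, user_fraction = 0.3, seed = 1) {
  stopifnot(inherits(ws, "window_set"))
  datasets <- sort(unique(ws$meta$dataset))
  if (length(datasets) < 2) stop_cfg("need at least 2 datasets")
  tasks <- list()
  ood_u <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[i]
    sub <- ws_subset(ws, which(ws$meta$dataset == d))
    tasks[[paste0("ID.", d)]] <- split_id(sub, test_fraction, seed + i)
    ood_u[[d]] <- split_ood_u(sub, user_fraction, seed + 100 + i)
    tasks[[paste0("OOD-U.", d)]] <- ood_u[[d]]
  }
  for (d in datasets) {
    tasks[[paste0("OOD-MD.", d)]] <- split_ood_md(ws, d, ood_u)
  }
  for (src in datasets) for (tgt in setdiff(datasets, src)) {
    tasks[[sprintf("OOD-SD.%s.%s", src, tgt)]] <-
      split_ood_sd(ws, src, tgt, ood_u)
  }
  tasks
}

#' Write / read a task spec as structured text
#'
#' YAML serialization of the full spec including explicit id lists, so
#' any run is exactly re-creatable from disk.
#'
#' @param task A `task_spec`.
#' @param path File path.
#' @return Reader returns the `task_spec`.
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "task_spec"))
  yaml::write_yaml(unclass(task), path)
  invisible(path)
}

#' @rdname write_task
#' @export
read_task <- function(path) {
  x <- yaml::read_yaml(path)
  task_spec(x$setting, unlist(x$train_ids), unlist(x$test_ids),
            unlist(x$source_datasets), x$target_dataset, x$seed)
}
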