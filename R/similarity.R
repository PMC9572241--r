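# Distribution-shift metrics between two sets of representation vectors,
# the bootstrap distance-ratio protocol, and the degree-of-correspondence
# (DC) permutation test.

set_metrics <- c("euclidean", "cosine", "wasserstein", "mmd")

#' One-dimensional Wasserstein-1 distance between two samples
#'
#' Closed form via the quantile-function integral of the two empirical
#' distributions (equal-size samples reduce to the mean absolute
#' difference of sorted values).
#'
#' @param x,y Numeric vectors.
#' @return Non-negative scalar.
#' @export
wasserstein_1d <- function(x, y) {
  all_v <- sort(c(x, y))
  if (length(all_v) < 2) return(0)
  deltas <- diff(all_v)
  cut <- all_v[-length(all_v)]
  Fx <- findInterval(cut, sort(x)) / length(x)
  Fy <- findInterval(cut, sort(y)) / length(y)
  sum(abs(Fx - Fy) * deltas)
}

#' Unbiased linear-kernel maximum mean discrepancy
#'
#' The unbiased two-sample estimator with k(x, y) = x . y: within-set
#' averages over ordered pairs i != j plus the all-pairs cross term.
#' Computed in O(n d) via sum identities; can be negative for close
#' distributions (the estimator is unbiased, not non-negative).
#'
#' @param A,B Numeric matrices (rows = samples) with matching columns and
#'   at least 2 rows each.
#' @return Scalar MMD estimate.
#' @export
mmd_linear <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A); m <- nrow(B)
  if (n < 2 || m < 2) stop_cfg("mmd needs at least 2 rows per set")
  if (ncol(A) != ncol(B)) stop_cfg("dimension mismatch")
  sa <- colSums(A); sb <- colSums(B)
  within_a <- (sum(sa^2) - sum(A^2)) / (n * (n - 1))
  within_b <- (sum(sb^2) - sum(B^2)) / (m * (m - 1))
  cross <- 2 * sum(sa * sb) / (n * m)
  within_a + within_b - cross
}

#' Distance or similarity between two representation sets
#'
#' Four set-level measures: `"euclidean"` — Euclidean distance between
#' the column-mean centroids; `"cosine"` — cosine similarity between the
#' centroids (larger = closer, unlike the other three); `"wasserstein"`
#' — the mean over dimensions of the 1-D Wasserstein-1 distance between
#' the empirical marginals; `"mmd"` — the unbiased linear-kernel MMD.
#'
#' @param metric One of `"euclidean"`, `"cosine"`, `"wasserstein"`,
#'   `"mmd"`.
#' @param A,B Numeric matrices (rows = samples, columns = dimensions).
#' @return Scalar.
#' @export
set_distance <- function(metric = set_metrics, A, B) {
  metric <- match.arg(metric)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop_cfg("dimension mismatch")
  switch(metric,
         euclidean = sqrt(sum((colMeans(A) - colMeans(B))^2)),
         cosine = {
           ca <- colMeans(A); cb <- colMeans(B)
           na <- sqrt(sum(ca^2)); nb <- sqrt(sum(cb^2))
           if (na == 0 || nb == 0) 0 else sum(ca * cb) / (na * nb)
         },
         wasserstein = mean(vapply(seq_len(ncol(A)), function(j) {
           wasserstein_1d(A[, j], B[, j])
         }, numeric(1))),
         mmd = mmd_linear(A, B))
}

#' Bootstrap distance-ratio between train and test representations
#'
#' Raw set distances are scale-dependent, so each repeat computes the
#' ratio of a between-set distance to a within-train baseline:
#' numerator distance between a train subset and a test subset,
#' denominator distance between two further train subsets, all four
#' subsets sampled with replacement at size
#' `floor(min(n_train, n_test) / 2)`. The reported estimate is the mean
#' and standard deviation over repeats. Values near 1 indicate the test
#' set is no farther from the train set than the train set is from
#' itself. Denominator draws smaller than `epsilon` in magnitude are
#' rejected and redrawn.
#'
#' @param metric Passed to [set_distance()].
#' @param train_rep,test_rep Representation matrices.
#' @param n_repeats Number of bootstrap repeats (default 30).
#' @param seed Integer seed.
#' @param epsilon Degeneracy threshold for the denominator.
#' @return An object of class `ratio_estimate`: `metric`, `mean`, `sd`,
#'   `values`, `n_repeats`, `subset_size`, `n_redraws`.
#' @export
distance_ratio <- function(metric, train_rep, test_rep, n_repeats = 30,
                           seed = 1, epsilon = 1e-12) {
  train_rep <- as.matrix(train_rep); test_rep <- as.matrix(test_rep)
  n_tr <- nrow(train_rep); n_ts <- nrow(test_rep)
  if (min(n_tr, n_ts) < 4) stop_cfg("need at least 4 rows on each side")
  if (n_repeats < 2) stop_cfg("n_repeats must be at least 2")
  s <- floor(min(n_tr, n_ts) / 2)
  with_seed(seed, {
    vals <- numeric(n_repeats)
    redraws <- 0
    for (r in seq_len(n_repeats)) {
      for (attempt in seq_len(100)) {
        tr1 <- train_rep[sample.int(n_tr, s, replace = TRUE), , drop = FALSE]
        ts1 <- test_rep[sample.int(n_ts, s, replace = TRUE), , drop = FALSE]
        tr2 <- train_rep[sample.int(n_tr, s, replace = TRUE), , drop = FALSE]
        tr3 <- train_rep[sample.int(n_tr, s, replace = TRUE), , drop = FALSE]
        den <- set_distance(metric, tr2, tr3)
        if (abs(den) >= epsilon) break
        redraws <- redraws + 1
        if (attempt == 100) stop_cfg("denominator degenerate in every redraw")
      }
      vals[r] <- set_distance(metric, tr1, ts1) / den
    }
    structure(list(metric = metric, mean = mean(vals), sd = stats::sd(vals),
                   values = vals, n_repeats = n_repeats, subset_size = s,
                   n_redraws = redraws),
              class = "ratio_estimate")
  })
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate> %s: %.3f +/- %.3f (%d repeats, subsets of %d)\n",
              x$metric, x$mean, x$sd, x$n_repeats, x$subset_size))
  invisible(x)
}

# Fast two-sample Kolmogorov-Smirnov statistic (max |ecdf difference|),
# tie-safe; the p-value machinery of stats::ks.test is not needed here.
ks_stat <- function(x, y) {
  n_x <- length(x); n_y <- length(y)
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= n_x, 1 / n_x, -1 / n_y))
  ws <- sort(w)
  keep <- c(diff(ws) != 0, TRUE)
  max(abs(z[keep]))
}

# Pairwise distances within a representation matrix as a flat vector.
pairwise_d <- function(X, d = c("euclidean", "cosine")) {
  d <- match.arg(d)
  if (d == "euclidean") return(as.vector(stats::dist(X)))
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  Xn <- X / nrm
  sim <- tcrossprod(Xn)
  1 - sim[lower.tri(sim)]
}

dc_delta <- function(Tm, Vm, d) {
  dT <- pairwise_d(Tm, d)
  # nearest neighbor of each v in T (ties -> lowest index)
  cross <- if (d == "euclidean") {
    t2 <- rowSums(Tm^2); v2 <- rowSums(Vm^2)
    outer(t2, v2, `+`) - 2 * tcrossprod(Tm, Vm)
  } else {
    nt <- sqrt(rowSums(Tm^2)); nt[nt == 0] <- 1
    nv <- sqrt(rowSums(Vm^2)); nv[nv == 0] <- 1
    1 - tcrossprod(Tm / nt, Vm / nv)
  }
  matched <- unique(apply(cross, 2, which.min))
  TV <- rbind(Tm[-matched, , drop = FALSE], Vm)
  dTV <- pairwise_d(TV, d)
  ks_stat(dT, dTV)
}

#' Degree-of-correspondence permutation test
#'
#' Tests whether a sample `V` is drawn from the same distribution as a
#' reference sample `T`. The observed statistic replaces each `V` point's
#' nearest neighbor in `T` by the point itself and measures how much the
#' within-set pairwise-distance distribution changes (two-sample
#' Kolmogorov-Smirnov statistic between the two distance multisets). The
#' null distribution comes from `B` random re-partitions of the pooled
#' rows into pieces of sizes (|T|, |V|). Small p-values mean `V` is
#' likely out-of-distribution relative to `T`.
#'
#' @param T_rep Reference representation matrix (more rows than `V_rep`).
#' @param V_rep Query representation matrix (at least 2 rows).
#' @param d Base distance for pairwise/nearest-neighbor computations:
#'   `"euclidean"` or `"cosine"`.
#' @param B Number of permutations (at least 19, for p-value resolution).
#' @param seed Integer seed.
#' @param max_rows Each input is subsampled (seeded) to at most this many
#'   rows to bound the quadratic pairwise cost.
#' @return An object of class `dc_result`: `p_value`
#'   (= (1 + #\{delta' >= delta\}) / (B + 1)), `observed_delta`,
#'   `n_permutations`, `base_distance`.
#' @export
dc <- function(T_rep, V_rep, d = c("euclidean", "cosine"), B = 99, seed = 1,
               max_rows = 300) {
  d <- match.arg(d)
  Tm <- as.matrix(T_rep); Vm <- as.matrix(V_rep)
  if (B < 19) stop_cfg("B must be at least 19 for usable p-value resolution")
  with_seed(seed, {
    if (nrow(Tm) > max_rows) Tm <- Tm[sample.int(nrow(Tm), max_rows), , drop = FALSE]
    if (nrow(Vm) > max_rows) Vm <- Vm[sample.int(nrow(Vm), max_rows), , drop = FALSE]
    if (nrow(Vm) < 2) stop_cfg("V needs at least 2 rows")
    if (nrow(Tm) <= nrow(Vm)) stop_cfg("T must have more rows than V")
    delta <- dc_delta(Tm, Vm, d)
    pool <- rbind(Tm, Vm)
    n_t <- nrow(Tm); n_all <- nrow(pool)
    exceed <- 0
    for (b in seq_len(B)) {
      idx <- sample.int(n_all, n_t)
      dp <- dc_delta(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE], d)
      if (dp >= delta) exceed <- exceed + 1
    }
    structure(list(p_value = (1 + exceed) / (B + 1), observed_delta = delta,
                   n_permutations = B, base_distance = d),
              class = "dc_result")
  })
}

#' @export
print.dc_result <- function(x, ...) {
  cat(sprintf("<dc_result> p = %.3f (delta = %.4f, B = %d, d = %s)\n",
              x$p_value, x$observed_delta, x$n_permutations, x$base_distance))
  invisible(x)
}

#' Per-setting shift report over a collection of tasks
#'
#' For every task, computes the distance ratios of the requested metrics
#' (and raw DC p-values, which are already normalized to [0, 1]) between
#' the train and test representations, then aggregates mean and sd per
#' setting, with an `Avg. OOD` column averaging the three OOD settings.
#'
#' @param tasks Named list of `task_spec`s.
#' @param reps Named list (same names) of lists with elements `train` and
#'   `test`: the representation matrices of each task's two sides, all
#'   from one representation source.
#' @param metrics Ratio metrics to include.
#' @param dc_metrics Base distances for DC rows (`character(0)` to skip).
#' @param n_repeats,seed,max_rows Passed to [distance_ratio()] and [dc()].
#' @return An object of class `shift_report`: data.frame `summary`
#'   (rows = metrics, columns = settings + `Avg. OOD`, mean and sd), plus
#'   the per-task values.
#' @export
shift_report <- function(tasks, reps,
                         metrics = c("wasserstein", "mmd", "euclidean", "cosine"),
                         dc_metrics = c("euclidean", "cosine"),
                         n_repeats = 30, seed = 1, max_rows = 300) {
  stopifnot(length(tasks) == length(reps), !is.null(names(tasks)))
  rows <- list()
  for (nm in names(tasks)) {
    task <- tasks[[nm]]
    rp <- reps[[nm]]
    for (m in metrics) {
      est <- distance_ratio(m, rp$train, rp$test, n_repeats = n_repeats,
                            seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        task = nm, setting = task$setting, metric = m, value = est$mean)
    }
    for (dm in dc_metrics) {
      n_tr <- nrow(rp$train)
      tr <- rp$train
      # DC requires |T| > |V|; cap V at half of T
      n_v_max <- min(nrow(rp$test), max(2, floor(min(n_tr, max_rows) / 2) - 1))
      vs <- with_seed(seed, rp$test[sample.int(nrow(rp$test),
                                               n_v_max), , drop = FALSE])
      p <- dc(tr, vs, d = dm, B = 99, seed = seed, max_rows = max_rows)$p_value
      rows[[length(rows) + 1]] <- data.frame(
        task = nm, setting = task$setting, metric = paste0("dc_", dm),
        value = p)
    }
  }
  per_task <- do.call(rbind, rows)
  settings <- c("ID", "OOD-U", "OOD-MD", "OOD-SD")
  present <- intersect(settings, unique(per_task$setting))
  miss <- setdiff(settings, present)
  if (length(miss)) warning(sprintf("no tasks for setting(s): %s",
                                    paste(miss, collapse = ", ")))
  all_metrics <- unique(per_task$metric)
  summary <- do.call(rbind, lapply(all_metrics, function(m) {
    sub <- per_task[per_task$metric == m, ]
    means <- sapply(present, function(s) mean(sub$value[sub$setting == s]))
    sds <- sapply(present, function(s) {
      v <- sub$value[sub$setting == s]
      if (length(v) > 1) stats::sd(v) else 0
    })
    ood <- setdiff(present, "ID")
    data.frame(metric = m, setting = present, mean = means, sd = sds,
               avg_ood = if (length(ood)) mean(means[ood]) else NA_real_,
               row.names = NULL)
  }))
  structure(list(summary = summary, per_task = per_task),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  wide <- format_shift_report(x)
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Format or write a shift report as a delimited table
#'
#' Rows are metrics, columns the four settings plus `Avg. OOD`, cells
#' `mean±sd`.
#'
#' @param report A `shift_report`.
#' @return data.frame of formatted cells.
#' @export
format_shift_report <- function(report) {
  s <- report$summary
  settings <- unique(s$setting)
  out <- data.frame(metric = unique(s$metric))
  for (set in settings) {
    out[[set]] <- vapply(out$metric, function(m) {
      r <- s[s$metric == m & s$setting == set, ]
      sprintf("%.2f±%.2f", r$mean, r$sd)
    }, character(1))
  }
  out[["Avg. OOD"]] <- vapply(out$metric, function(m) {
    sprintf("%.2f", s$avg_ood[s$metric == m][1])
  }, character(1))
  out
}

#' @rdname format_shift_report
#' @param path Output path for a tab-delimited version.
#' @export
write_shift_report <- function(report, path) {
  utils::write.table(format_shift_report(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
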