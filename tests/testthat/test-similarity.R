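test_that("linear-kernel MMD matches direct summation on the worked example", {
  X <- rbind(c(1, 0), c(0, 1))
  expect_equal(mmd_linear(X, X), -1.0)
  expect_equal(mmd_oracle(X, X), -1.0)
  expect_error(mmd_linear(X[1, , drop = FALSE], X), "at least 2 rows")
  expect_error(mmd_linear(X, matrix(0, 3, 3)), "dimension mismatch")
})

test_that("vectorized MMD equals the triple-loop oracle on random pairs", {
  set.seed(14)
  for (i in 1:50) {
    A <- matrix(rnorm(100, sd = runif(1, 0.5, 2)), 20, 5)
    B <- matrix(rnorm(75, mean = runif(1, -1, 1)), 15, 5)
    expect_equal(mmd_linear(A, B), mmd_oracle(A, B), tolerance = 1e-9)
  }
})

test_that("1-D Wasserstein matches the quantile-integral oracle", {
  expect_equal(wasserstein_1d(0, 1), 1.0)
  expect_equal(wasserstein_1d(c(1, 5, 2), c(1, 5, 2)), 0.0)
  set.seed(15)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    m <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- rnorm(m, mean = runif(1, -2, 2))
    expect_equal(wasserstein_1d(x, y), w1_oracle(x, y), tolerance = 1e-9)
  }
  # equal sizes: mean absolute difference of sorted samples
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(wasserstein_1d(x, y), mean(abs(sort(x) - sort(y))),
               tolerance = 1e-12)
})

test_that("set-level distances behave canonically on identical sets", {
  set.seed(16)
  A <- matrix(rnorm(60), 12, 5)
  expect_equal(set_distance("euclidean", A, A), 0)
  expect_equal(set_distance("cosine", A, A), 1)
  expect_equal(set_distance("wasserstein", A, A), 0)
  # all metrics are invariant to row permutations of either argument
  B <- matrix(rnorm(40), 8, 5)
  for (m in c("euclidean", "cosine", "wasserstein", "mmd")) {
    expect_equal(set_distance(m, A, B),
                 set_distance(m, A[sample(12), ], B[sample(8), ]),
                 tolerance = 1e-12, info = m)
  }
})

test_that("the internal KS statistic agrees with stats::ks.test", {
  set.seed(17)
  for (i in 1:25) {
    x <- rnorm(sample(10:60, 1))
    y <- rnorm(sample(10:60, 1), mean = runif(1, 0, 1))
    expect_equal(harshift:::ks_stat(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
    # with heavy ties
    xt <- sample(1:4, 30, replace = TRUE)
    yt <- sample(2:5, 25, replace = TRUE)
    expect_equal(harshift:::ks_stat(xt, yt),
                 unname(suppressWarnings(stats::ks.test(xt, yt)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("distance ratios are near 1 when test matches train", {
  set.seed(18)
  X <- matrix(rnorm(200 * 5), 200, 5)
  tr <- X[1:120, ]
  te <- X[121:200, ]
  for (m in c("wasserstein", "euclidean")) {
    est <- distance_ratio(m, tr, te, n_repeats = 30, seed = 3)
    expect_gt(est$mean, 0.8)
    expect_lt(est$mean, 1.25)
    expect_equal(est$subset_size, floor(min(120, 80) / 2))
  }
  expect_identical(distance_ratio("wasserstein", tr, te, seed = 3)$values,
                   distance_ratio("wasserstein", tr, te, seed = 3)$values)
  expect_error(distance_ratio("wasserstein", tr[1:3, ], te), "at least 4")
})

test_that("distance ratios blow up under a strong mean shift", {
  set.seed(19)
  tr <- matrix(rnorm(500), 100, 5)
  te <- matrix(rnorm(400), 80, 5) + 10  # +10 sd on every dimension
  est <- distance_ratio("wasserstein", tr, te, n_repeats = 30, seed = 2)
  expect_gt(est$mean, 3)
})

test_that("the DC statistic is zero and p maximal when V duplicates T", {
  set.seed(20)
  Tm <- matrix(rnorm(40 * 3), 40, 3)
  Vm <- Tm[1:10, ]
  res <- dc(Tm, Vm, B = 99, seed = 1)
  expect_equal(res$observed_delta, 0)
  expect_equal(res$p_value, 1)
})

test_that("DC input contracts are enforced", {
  Tm <- matrix(rnorm(30), 10, 3)
  expect_error(dc(Tm, Tm, B = 99), "more rows")
  expect_error(dc(Tm, Tm[1:3, ], B = 10), "at least 19")
  expect_error(dc(Tm, Tm[1, , drop = FALSE], B = 99), "at least 2 rows")
})

test_that("DC rejects shifted samples and accepts in-distribution ones", {
  set.seed(21)
  null_p <- replicate(30, {
    dc(matrix(rnorm(200), 40, 5), matrix(rnorm(60), 12, 5), B = 99,
       seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(null_p), 0.3)
  expect_lt(mean(null_p), 0.7)
  shift_p <- replicate(20, {
    dc(matrix(rnorm(200), 40, 5), matrix(rnorm(60), 12, 5) + 5, B = 99,
       seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(shift_p <= 0.05), 0.9)
})

test_that("shift reports aggregate per setting with an OOD average", {
  set.seed(22)
  mk_rep <- function(shift) {
    list(train = matrix(rnorm(200), 40, 5),
         test = matrix(rnorm(100), 20, 5) + shift)
  }
  ws <- toy_window_set(2, 4, per_subject = 10)
  tasks <- build_tasks(ws, seed = 2)
  tasks <- tasks[c("ID.D1", "ID.D2", "OOD-U.D1", "OOD-MD.D1", "OOD-SD.D2.D1")]
  reps <- list(mk_rep(0), mk_rep(0), mk_rep(0.5), mk_rep(1), mk_rep(3))
  names(reps) <- names(tasks)
  rep_out <- shift_report(tasks, reps, metrics = "wasserstein",
                          dc_metrics = "euclidean", n_repeats = 10, seed = 4)
  s <- rep_out$summary
  expect_setequal(unique(s$setting), c("ID", "OOD-U", "OOD-MD", "OOD-SD"))
  expect_setequal(unique(s$metric), c("wasserstein", "dc_euclidean"))
  ww <- s[s$metric == "wasserstein", ]
  expect_equal(unique(ww$avg_ood),
               mean(ww$mean[ww$setting != "ID"]), tolerance = 1e-12)
  # monotone in the injected shift
  expect_lt(ww$mean[ww$setting == "ID"], ww$mean[ww$setting == "OOD-SD"])
  fmt <- format_shift_report(rep_out)
  expect_true(all(c("metric", "ID", "Avg. OOD") %in% names(fmt)))
})
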