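make_rec <- function(samples, rate, labels, subject = "S1", dataset = "D1") {
  harshift:::new_recording(as.matrix(samples), rate, labels, subject, dataset)
}

test_that("resampling adjusts length and preserves content", {
  t100 <- (0:499) / 100
  sig <- cbind(x = sin(2 * pi * 2 * t100), y = t100, z = rep(1, 500))
  rec <- make_rec(sig, 100, rep("walk", 500))
  out <- resample_recording(rec, 50)
  expect_equal(nrow(out$samples), 250)
  expect_equal(out$rate, 50)
  # already at target rate: identity
  rec50 <- make_rec(sig[1:250, ], 50, rep("walk", 250))
  expect_identical(resample_recording(rec50, 50), rec50)
  # a 2 Hz sine at 200 Hz still peaks at 2 Hz after resampling to 50 Hz
  t200 <- (0:999) / 200
  rec200 <- make_rec(cbind(sin(2 * pi * 2 * t200), 0 * t200, 0 * t200),
                     200, rep("run", 1000))
  res <- resample_recording(rec200, 50)
  expect_equal(fft_peak_oracle(res$samples[, 1], 50), 2, tolerance = 0.06)
  expect_error(resample_recording(make_rec(matrix(0, 0, 3), 50, character(0))),
               "empty")
})

test_that("resampling carries labels by nearest time", {
  labs <- c(rep("walk", 300), rep("run", 200))
  rec <- make_rec(matrix(0, 500, 3), 100, labs)
  out <- resample_recording(rec, 50)
  expect_equal(sum(out$labels == "walk"), 150)
  expect_equal(sum(out$labels == "run"), 100)
})

test_that("magnitude channel is the per-sample Euclidean norm", {
  rec <- make_rec(rbind(c(3, 4, 0), c(0, 0, 0), c(1, 2, 2)), 50,
                  rep("sit", 3))
  out <- add_magnitude(rec)
  expect_equal(ncol(out$samples), 4)
  expect_equal(unname(out$samples[, 4]), c(5, 0, 3))
  expect_error(add_magnitude(out), "3-channel")
})

test_that("magnitude channel is invariant to sensor orientation", {
  set.seed(11)
  S <- matrix(rnorm(300), 100, 3)
  R <- rotation_matrix(rnorm(3), 1.2)
  m1 <- add_magnitude(make_rec(S, 50, rep("walk", 100)))$samples[, 4]
  m2 <- add_magnitude(make_rec(S %*% t(R), 50, rep("walk", 100)))$samples[, 4]
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("label mapping merges stairs, drops marked labels, errors on unknown", {
  labs <- c(rep("upstairs", 5), rep("downstairs", 5), rep("biking", 3),
            rep("walk", 4))
  rec <- make_rec(matrix(seq_len(17 * 3), 17, 3), 50, labs)
  out <- map_labels(rec, c(upstairs = "stairs", downstairs = "stairs",
                           biking = NA))
  expect_setequal(unique(out$labels), c("stairs", "walk"))
  expect_equal(nrow(out$samples), 14)  # biking samples removed
  expect_error(map_labels(rec, c(upstairs = "stairs", downstairs = "stairs")),
               "biking")
  # identity on canonical labels
  rec2 <- make_rec(matrix(0, 4, 3), 50, rep("run", 4))
  expect_identical(map_labels(rec2)$labels, rec2$labels)
})

test_that("windowing follows the single-label no-overlap contract", {
  mk <- function(n, labs) {
    r <- make_rec(matrix(rnorm(n * 3), n, 3), 50, labs)
    add_magnitude(r)
  }
  # 61 s of one activity -> floor(61/5) = 12 windows
  ws <- windowize(mk(3050, rep("walk", 3050)))
  expect_equal(n_windows(ws), 12)
  # label change at 4 s within 10 s: only the 6 s run yields one window
  ws2 <- windowize(mk(500, c(rep("walk", 200), rep("run", 300))))
  expect_equal(n_windows(ws2), 1)
  expect_equal(ws2$meta$label, "run")
  # too short for a single window
  expect_equal(n_windows(windowize(mk(200, rep("sit", 200)))), 0)
  # window count equals the sum of floor(run_length / 250) over label runs
  set.seed(21)
  runs <- sample(100:700, 6)
  labs <- unlist(mapply(rep, sample(canonical_activities(), 6, TRUE), runs))
  ws3 <- windowize(mk(length(labs), labs))
  rl <- rle(labs)
  expect_equal(n_windows(ws3), sum(rl$lengths %/% 250))
  expect_error(windowize(mk(500, rep("walk", 500)), overlap = 0.5),
               "non-overlapping")
})

test_that("subsampling is exact, seeded, and identity at fraction 1", {
  ws <- toy_window_set(1, 1, per_subject = 300)
  sub <- subsample_windows(ws, 1 / 3, seed = 5)
  expect_equal(n_windows(sub), 100)
  expect_identical(subsample_windows(ws, 1 / 3, seed = 5)$meta, sub$meta)
  expect_identical(subsample_windows(ws, 1), ws)
  expect_error(subsample_windows(ws, 0), "fraction")
})

test_that("window sets round-trip losslessly through delimited text", {
  ws <- small_benchmark_ws(seed = 3, subjects = 2, duration = 10)
  f <- tempfile(fileext = ".tsv")
  write_window_set(ws, f)
  back <- read_window_set(f)
  expect_equal(back$values, ws$values, tolerance = 1e-9)
  expect_identical(back$meta$window_id, ws$meta$window_id)
  expect_identical(back$meta$label, ws$meta$label)
  expect_true(file.exists(paste0(f, ".idx")))
})

test_that("harmonization of an already-harmonized recording is the identity", {
  t50 <- (0:1499) / 50
  sig <- cbind(x = sin(2 * pi * 2 * t50), y = cos(2 * pi * 2 * t50),
               z = rep(9.8, 1500))
  rec <- add_magnitude(make_rec(sig, 50, rep("walk", 1500)))
  ws1 <- harmonize_recordings(list(rec))
  ws2 <- harmonize_recordings(list(rec))
  expect_identical(ws1, ws2)
  expect_equal(n_windows(ws1), 6)
  # window contents are untouched slices of the input
  expect_equal(ws1$values[1, , 1], unname(sig[1:250, 1]))
})
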