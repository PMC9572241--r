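test_that("activity model constructor enforces its contract", {
  expect_error(activity_model("jumping", 2, 1), "unknown activity")
  expect_error(activity_model("sit", 2, 0), "base_frequency = 0")
  expect_error(activity_model("walk", 0, 1), "base_frequency > 0")
  expect_error(activity_model("walk", 2, 1, gravity_axis_weights = c(1, 1, 1)),
               "unit 3-vector")
  m <- activity_model("walk", 2, 3)
  expect_s3_class(m, "activity_model")
  expect_equal(sqrt(sum(m$gravity_axis_weights^2)), 1)
})

test_that("domain params validate rotation and rate floor", {
  expect_error(domain_params("D", "S", orientation = matrix(1, 3, 3)),
               "proper rotation")
  # reflections (det -1) are rejected even though orthonormal
  refl <- diag(c(1, 1, -1))
  expect_error(domain_params("D", "S", orientation = refl), "proper rotation")
  expect_error(domain_params("D", "S", native_rate = 40), "50 Hz")
  expect_silent(domain_params("D", "S", native_rate = 48))  # within tolerance
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("noise-free sitting is the constant gravity vector", {
  m <- activity_model("sit", 0, 0, c(0, 0, 1), noise_floor = 0)
  dom <- domain_params("D1", "S1", native_rate = 50)
  rec <- generate_recording(m, dom, 10, seed = 1)
  expect_equal(nrow(rec$samples), 500)
  expect_equal(unname(rec$samples[1, ]), c(0, 0, 9.81))
  expect_true(all(apply(rec$samples, 2, function(ch) length(unique(ch))) == 1))
  expect_true(all(rec$labels == "sit"))
})

test_that("periodic activities carry their stride frequency", {
  m <- activity_model("walk", 2, 3, c(0, 0, 1), noise_floor = 0)
  dom <- domain_params("D1", "S1", native_rate = 100)
  rec <- generate_recording(m, dom, 20, seed = 5)
  # dominant non-DC peak of the vertical channel sits at the 2 Hz fundamental
  expect_equal(fft_peak_oracle(rec$samples[, 3], 100), 2, tolerance = 0.06)
  # subject frequency scaling moves the peak proportionally
  dom2 <- domain_params("D1", "S2", native_rate = 100,
                        subject_freq_scale = 1.5)
  rec2 <- generate_recording(m, dom2, 20, seed = 5)
  expect_equal(fft_peak_oracle(rec2$samples[, 3], 100), 3, tolerance = 0.06)
})

test_that("generation is deterministic under a seed", {
  m <- default_activity_models()$run
  dom <- domain_params("D1", "S1", device_noise_sd = 0.4)
  r1 <- generate_recording(m, dom, 5, seed = 42)
  r2 <- generate_recording(m, dom, 5, seed = 42)
  expect_identical(r1, r2)
  r3 <- generate_recording(m, dom, 5, seed = 43)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("benchmark generation keeps the declared structure", {
  cfg <- benchmark_config(n_datasets = 3, subjects_per_dataset = 2,
                          duration_per_activity = 10)
  bench <- make_benchmark(cfg, seed = 9)
  expect_length(bench$recordings, 3 * 2 * 5)
  expect_identical(bench$dataset_ids, c("D1", "D2", "D3"))
  labs <- unlist(lapply(bench$recordings, function(r) unique(r$labels)))
  expect_true(all(labs %in% canonical_activities()))
  # every activity present in every dataset
  per_ds <- split(labs, rep(vapply(bench$recordings, `[[`, "", "dataset_id"),
                            each = 1))
  for (d in names(per_ds)) {
    expect_setequal(unique(per_ds[[d]]), canonical_activities())
  }
  expect_identical(make_benchmark(cfg, seed = 9), bench)
  expect_error(benchmark_config(n_datasets = 1), "at least 2 datasets")
  expect_error(benchmark_config(subjects_per_dataset = 1),
               "at least 2 subjects")
})

test_that("dataset-level shift magnitude moves datasets apart monotonically", {
  centroid_gap <- function(sigma_ds, seed) {
    ws <- small_benchmark_ws(seed = seed, subjects = 2, duration = 15,
                             sigma_dataset = sigma_ds)
    X <- extract_features(ws)
    cs <- lapply(split(seq_len(nrow(X)), ws$meta$dataset),
                 function(i) colMeans(X[i, , drop = FALSE]))
    ds <- utils::combn(length(cs), 2, function(p) {
      sqrt(sum((cs[[p[1]]] - cs[[p[2]]])^2))
    })
    mean(ds)
  }
  seeds <- 1:20
  gap0 <- vapply(seeds, function(s) centroid_gap(0, s), numeric(1))
  gap2 <- vapply(seeds, function(s) centroid_gap(1.5, s), numeric(1))
  expect_gt(mean(gap2), mean(gap0))
})

test_that("recording and benchmark round-trip through plain text", {
  m <- default_activity_models()$walk
  dom <- domain_params("D2", "S3", native_rate = 100, device_noise_sd = 0.2)
  rec <- generate_recording(m, dom, 3, seed = 4)
  f <- tempfile(fileext = ".txt")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_equal(back$samples, rec$samples, tolerance = 1e-10)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$rate, rec$rate)
  expect_identical(back$dataset_id, "D2")

  bench <- make_benchmark(benchmark_config(subjects_per_dataset = 2,
                                           duration_per_activity = 5),
                          seed = 2)
  d <- tempfile()
  write_benchmark(bench, d)
  back2 <- read_benchmark(d)
  expect_length(back2$recordings, length(bench$recordings))
  expect_equal(back2$recordings[[4]]$samples, bench$recordings[[4]]$samples,
               tolerance = 1e-10)
  unlink(d, recursive = TRUE)
})
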