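# Independent oracles and small fixture builders shared across tests.

# Brute-force triple-sum evaluation of the unbiased linear-kernel MMD.
mmd_oracle <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  s1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) s1 <- s1 + sum(A[i, ] * A[j, ])
  }
  s2 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) s2 <- s2 + sum(B[i, ] * B[j, ])
  }
  s3 <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) s3 <- s3 + sum(A[i, ] * B[j, ])
  s1 / (n * (n - 1)) + s2 / (m * (m - 1)) - 2 * s3 / (n * m)
}

# 1-D Wasserstein-1 via the quantile-function integral on an exact grid
# (n*m cells make both empirical quantile functions piecewise constant).
w1_oracle <- function(x, y) {
  N <- length(x) * length(y)
  u <- (seq_len(N) - 0.5) / N
  qx <- stats::quantile(x, u, type = 1, names = FALSE)
  qy <- stats::quantile(y, u, type = 1, names = FALSE)
  mean(abs(qx - qy))
}

# FFT-argmax dominant (non-DC) frequency of a signal.
fft_peak_oracle <- function(x, rate) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- p[2:(floor(n / 2) + 1)]
  freqs <- (seq_along(half)) * rate / n
  freqs[which.max(half)]
}

# Hand confusion-matrix macro f1.
f1_macro_oracle <- function(y_true, y_pred) {
  labs <- sort(union(y_true, y_pred))
  f <- vapply(labs, function(l) {
    tp <- sum(y_true == l & y_pred == l)
    fp <- sum(y_true != l & y_pred == l)
    fn <- sum(y_true == l & y_pred != l)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f)
}

# Small window set with arbitrary geometry (for split/bookkeeping tests that
# do not care about signal content).
toy_window_set <- function(n_datasets = 2, n_subjects = 3, per_subject = 10,
                           len = 8, seed = 1) {
  set.seed(seed)
  parts <- list()
  for (d in seq_len(n_datasets)) for (s in seq_len(n_subjects)) {
    n <- per_subject
    vals <- array(rnorm(n * len * 4), c(n, len, 4))
    meta <- data.frame(
      window_id = sprintf("D%d.S%d.w%03d", d, s, seq_len(n)),
      dataset = sprintf("D%d", d), subject = sprintf("D%d.S%d", d, s),
      label = rep(canonical_activities(), length.out = n),
      stringsAsFactors = FALSE)
    parts[[length(parts) + 1]] <- window_set(vals, meta)
  }
  ws_bind(parts)
}

# Tiny harmonized benchmark for integration tests.
small_benchmark_ws <- function(seed = 7, subjects = 2, duration = 30,
                               sigma_dataset = 0.7) {
  bench <- make_benchmark(
    benchmark_config(duration_per_activity = duration,
                     subjects_per_dataset = subjects,
                     sigma_dataset = sigma_dataset),
    seed = seed)
  harmonize_recordings(bench)
}

# Separable 2-class feature problem for optimizer sanity checks.
separable_features <- function(n_per = 30, p = 6, gap = 6, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p, -gap / 2), n_per),
             matrix(rnorm(n_per * p, gap / 2), n_per))
  list(features = X,
       labels = rep(c("sit", "walk"), each = n_per),
       classes = c("sit", "walk"))
}
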