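# Handcrafted per-channel features: 48 scalar functionals in three families
# (statistical, temporal, high-level spectral), evaluated on each of the four
# window channels for a 192-dimensional representation per window.
# Per-coefficient features (raw FFT bins, eCDF values, histogram bins) and
# wavelet/audio features (MFCC, LPCC) are deliberately not part of the set;
# only high-level summaries of the FFT are.

feature_names_statistical <- c(
  "mean", "median", "sd", "var", "skewness", "kurtosis", "min", "max",
  "range", "iqr", "rms", "mean_abs_dev", "median_abs_dev", "q25", "q75",
  "crest_factor")

feature_names_temporal <- c(
  "zero_cross_rate", "mean_cross_rate", "mean_abs_diff", "mean_diff",
  "median_abs_diff", "median_diff", "sum_abs_diff", "abs_energy",
  "area_under_curve", "autocorr_lag1", "slope", "peak_count",
  "signal_entropy", "temporal_centroid", "signal_distance",
  "positive_turning_count")

feature_names_spectral <- c(
  "spectral_centroid", "spectral_spread", "spectral_skewness",
  "spectral_kurtosis", "spectral_entropy", "spectral_rolloff_85",
  "spectral_rollon_05", "median_frequency", "max_frequency",
  "dominant_frequency", "max_power", "total_power", "spectral_slope",
  "spectral_decrease", "band_share_low", "band_share_high")

#' Build the handcrafted feature registry
#'
#' The registry is the ordered contract for the handcrafted representation:
#' exactly 48 per-channel scalar functionals (16 statistical, 16 temporal,
#' 16 high-level spectral), so that a 4-channel window yields 192 features.
#' The ordering is fixed, and a configuration that does not produce exactly
#' 48 entries is rejected rather than silently changing the representation
#' width.
#'
#' @param families Feature families to include; anything other than the
#'   full default set violates the 48-feature contract and errors.
#' @return data.frame with columns `name` and `family`, 48 rows.
#' @export
build_registry <- function(families = c("statistical", "temporal", "spectral")) {
  sets <- list(statistical = feature_names_statistical,
               temporal = feature_names_temporal,
               spectral = feature_names_spectral)
  unknown <- setdiff(families, names(sets))
  if (length(unknown)) stop_cfg("unknown families: %s", paste(unknown, collapse = ", "))
  reg <- do.call(rbind, lapply(families, function(f) {
    data.frame(name = sets[[f]], family = f, stringsAsFactors = FALSE)
  }))
  if (nrow(reg) != 48) {
    stop_cfg("registry has %d entries; the handcrafted contract requires 48",
             nrow(reg))
  }
  reg
}

# All 48 functionals for one channel of one window. Degenerate inputs
# (constant or all-zero signals) take defined finite values: moment ratios,
# entropies and spectral summaries of a powerless spectrum are 0.
channel_features <- function(x, rate = 50) {
  n <- length(x)
  zero_guard <- function(v, default = 0) if (!is.finite(v)) default else v

  mu <- mean(x); med <- stats::median(x)
  s <- stats::sd(x); rms <- sqrt(mean(x^2))
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  stat_f <- c(
    mean = mu, median = med, sd = s, var = s^2,
    skewness = zero_guard(e1071::skewness(x)),
    kurtosis = zero_guard(e1071::kurtosis(x)),
    min = min(x), max = max(x), range = max(x) - min(x), iqr = q[2] - q[1],
    rms = rms, mean_abs_dev = mean(abs(x - mu)),
    median_abs_dev = stats::median(abs(x - med)), q25 = q[1], q75 = q[2],
    crest_factor = if (rms > 0) max(abs(x)) / rms else 0)

  dx <- diff(x)
  sgn <- x >= mu
  sgn0 <- x >= 0
  tt <- (seq_len(n) - 1) / rate
  ac1 <- if (s > 0) zero_guard(stats::cor(x[-n], x[-1])) else 0
  slope <- if (stats::var(tt) > 0) stats::cov(tt, x) / stats::var(tt) else 0
  peaks <- if (n >= 3) sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) else 0
  ent <- {
    if (max(x) == min(x)) 0 else {
      h <- tabulate(cut(x, breaks = 10, labels = FALSE), 10)
      p <- h[h > 0] / n
      -sum(p * log(p)) / log(10)
    }
  }
  absx <- abs(x)
  turn <- if (n >= 3) sum(dx[-length(dx)] > 0 & dx[-1] <= 0) else 0
  temp_f <- c(
    zero_cross_rate = sum(diff(sgn0) != 0) / (n - 1),
    mean_cross_rate = sum(diff(sgn) != 0) / (n - 1),
    mean_abs_diff = mean(abs(dx)), mean_diff = mean(dx),
    median_abs_diff = stats::median(abs(dx)), median_diff = stats::median(dx),
    sum_abs_diff = sum(abs(dx)), abs_energy = sum(x^2),
    area_under_curve = sum((x[-1] + x[-n]) / 2) / rate,
    autocorr_lag1 = ac1, slope = slope, peak_count = peaks,
    signal_entropy = ent,
    temporal_centroid = if (sum(absx) > 0) sum(tt * absx) / sum(absx) else 0,
    signal_distance = sum(sqrt(1 + dx^2)),
    positive_turning_count = turn)

  # one-sided power spectrum
  p_full <- Mod(stats::fft(x))^2 / n
  half <- seq_len(floor(n / 2) + 1)
  P <- p_full[half]
  f <- (half - 1) * rate / n
  tot <- sum(P)
  if (tot <= 0) {
    spec_f <- stats::setNames(numeric(16), feature_names_spectral)
  } else {
    cen <- sum(f * P) / tot
    spr <- sqrt(sum((f - cen)^2 * P) / tot)
    sk <- if (spr > 0) sum((f - cen)^3 * P) / tot / spr^3 else 0
    ku <- if (spr > 0) sum((f - cen)^4 * P) / tot / spr^4 else 0
    pp <- P[P > 0] / tot
    sent <- if (length(pp) > 1) -sum(pp * log(pp)) / log(length(P)) else 0
    cum <- cumsum(P) / tot
    roll <- function(q) f[which(cum >= q)[1]]
    Pnd <- P[-1]; fnd <- f[-1]
    dom <- if (max(Pnd) > 0) fnd[which.max(Pnd)] else 0
    sl <- if (stats::var(f) > 0) stats::cov(f, P) / stats::var(f) else 0
    dec_den <- sum(Pnd)
    dec <- if (dec_den > 0) sum((Pnd - P[1]) / (half[-1] - 1)) / dec_den else 0
    spec_f <- c(
      spectral_centroid = cen, spectral_spread = spr, spectral_skewness = sk,
      spectral_kurtosis = ku, spectral_entropy = sent,
      spectral_rolloff_85 = roll(0.85), spectral_rollon_05 = roll(0.05),
      median_frequency = roll(0.5), max_frequency = roll(0.95),
      dominant_frequency = dom, max_power = max(Pnd), total_power = tot,
      spectral_slope = sl, spectral_decrease = dec,
      band_share_low = sum(P[f >= 0.5 & f <= 3]) / tot,
      band_share_high = sum(P[f > 3 & f <= 10]) / tot)
  }
  out <- c(stat_f, temp_f, spec_f)
  names(out) <- c(feature_names_statistical, feature_names_temporal,
                  feature_names_spectral)
  out
}

#' Extract handcrafted features from a window set
#'
#' Evaluates the 48 registry functionals on each channel of each window,
#' channel-major (all 48 for x, then y, z, magnitude), yielding a
#' `[n_windows x 192]` representation matrix. Extraction is a pure
#' function of the window values: identical windows give bit-identical
#' rows, and degenerate (constant) windows yield finite features.
#'
#' @param ws A `window_set` (windows `[250 x 4]`).
#' @param registry Output of [build_registry()].
#' @param rate Sampling rate in Hz underlying the windows.
#' @return Numeric matrix `[n x 192]` with named columns
#'   (`<channel>_<feature>`) and attribute `source = "handcrafted"`.
#' @export
extract_features <- function(ws, registry = build_registry(), rate = 50) {
  stopifnot(inherits(ws, "window_set"))
  d <- dim(ws$values)
  if (length(d) != 3 || d[3] != 4) stop_cfg("expected [n x len x 4] windows")
  channels <- c("x", "y", "z", "mag")
  n <- d[1]
  out <- matrix(NA_real_, n, 48 * 4)
  colnames(out) <- as.vector(vapply(channels, function(ch) {
    paste(ch, registry$name, sep = "_")
  }, character(48)))
  for (i in seq_len(n)) {
    row <- numeric(0)
    for (c_ in 1:4) {
      feats <- channel_features(ws$values[i, , c_], rate = rate)
      row <- c(row, unname(feats[registry$name]))
    }
    out[i, ] <- row
  }
  if (!all(is.finite(out))) stop_cfg("non-finite feature values produced")
  attr(out, "source") <- "handcrafted"
  out
}

#' Train-set Z-score scaler
#'
#' `fit_scaler` computes per-column mean and population standard deviation
#' (1/n denominator) on the training representation only; `apply_scaler`
#' standardizes any representation with those same train statistics, so
#' no test-set information leaks into the scaling. Columns constant on the
#' train set (sd = 0) map to 0.
#'
#' @param train Numeric matrix (training rows only).
#' @return `fit_scaler`: an object of class `zscaler` with `mean` and `sd`
#'   vectors.
#' @export
fit_scaler <- function(train) {
  train <- as.matrix(train)
  m <- colMeans(train)
  sd_pop <- sqrt(colMeans(sweep(train, 2, m)^2))
  structure(list(mean = m, sd = sd_pop), class = "zscaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `zscaler`.
#' @param x Matrix to transform (same number of columns as the train set).
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "zscaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$mean)) stop_cfg("scaler/input dimension mismatch")
  out <- sweep(x, 2, scaler$mean)
  nz <- scaler$sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, scaler$sd[nz], `/`)
  out[, !nz] <- 0
  src <- attr(x, "source")
  if (!is.null(src)) attr(out, "source") <- src
  out
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "zscaler"))
  x <- as.matrix(x)
  out <- sweep(x, 2, scaler$sd, `*`)
  sweep(out, 2, scaler$mean, `+`)
}

#' Write / read a representation matrix and scaler as delimited text
#'
#' @param x Representation matrix with column names.
#' @param path File path.
#' @return Reader returns the matrix (with `source` attribute if stored).
#' @export
write_representation <- function(x, path) {
  dt <- data.table::as.data.table(as.matrix(x))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_representation
#' @export
read_representation <- function(path) {
  as.matrix(data.table::fread(path, sep = "\t", data.table = FALSE))
}

#' @rdname write_representation
#' @param scaler A `zscaler`.
#' @export
write_scaler <- function(scaler, path) {
  dt <- data.table::data.table(rbind(mean = scaler$mean, sd = scaler$sd),
                               keep.rownames = "stat")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_representation
#' @export
read_scaler <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  vals <- as.matrix(dt[-1])
  structure(list(mean = stats::setNames(vals[1, ], colnames(vals)),
                 sd = stats::setNames(vals[2, ], colnames(vals))),
            class = "zscaler")
}
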