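#' Window-set container
#'
#' A harmonized corpus of fixed-length windows. `values` is an
#' `[n_windows x 250 x 4]` array (5 s at 50 Hz; channels x, y, z,
#' magnitude); `meta` is a data.frame with one row per window:
#' `window_id`, `dataset`, `subject`, `label`.
#'
#' @param values Numeric array `[n, 250, 4]`.
#' @param meta data.frame with columns `window_id`, `dataset`, `subject`,
#'   `label`; `window_id` must be unique.
#' @return An object of class `window_set`.
#' @export
window_set <- function(values, meta) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  need <- c("window_id", "dataset", "subject", "label")
  if (!all(need %in% names(meta))) {
    stop_cfg("meta must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(meta) != dim(values)[1]) stop_cfg("values/meta row mismatch")
  if (anyDuplicated(meta$window_id)) stop_cfg("duplicated window_id")
  bad <- setdiff(unique(meta$label), canonical_activities())
  if (length(bad)) stop_cfg("non-canonical labels: %s", paste(bad, collapse = ", "))
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows [%d x %d], %d dataset(s), %d subject(s)\n",
              n_windows(x), dim(x$values)[2], dim(x$values)[3],
              length(unique(x$meta$dataset)), length(unique(x$meta$subject))))
  print(table(x$meta$dataset, x$meta$label))
  invisible(x)
}

#' @rdname window_set
#' @param ws A `window_set`.
#' @export
n_windows <- function(ws) dim(ws$values)[1]

#' Subset a window set by window identifiers or row indices
#'
#' @param ws A `window_set`.
#' @param ids Character `window_id`s or integer row indices.
#' @return A `window_set` with the selected windows, in the given order.
#' @export
ws_subset <- function(ws, ids) {
  idx <- if (is.character(ids)) match(ids, ws$meta$window_id) else ids
  if (anyNA(idx)) stop_cfg("unknown window ids")
  window_set(ws$values[idx, , , drop = FALSE], ws$meta[idx, ])
}

#' Combine several window sets into one
#'
#' @param ... `window_set` objects (or a single list of them).
#' @return A `window_set` holding all windows; ids must stay unique.
#' @export
ws_bind <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "window_set")) {
    parts <- parts[[1]]
  }
  parts <- Filter(function(p) !is.null(p) && n_windows(p) > 0, parts)
  if (!length(parts)) stop_cfg("nothing to bind")
  vals <- do.call(rbind, lapply(parts, function(p) {
    matrix(p$values, nrow = dim(p$values)[1])
  }))
  d <- dim(parts[[1]]$values)
  window_set(array(vals, c(nrow(vals), d[2], d[3])),
             do.call(rbind, lapply(parts, `[[`, "meta")))
}

#' Resample a recording to a common rate
#'
#' Linear interpolation of every channel on a uniform time grid at
#' `target_rate`; per-sample labels are carried over by nearest-time
#' assignment. A recording already at the target rate is returned
#' unchanged.
#'
#' @param rec A `har_recording`.
#' @param target_rate Target rate in Hz (default 50).
#' @return A `har_recording` at `target_rate` with
#'   `round(n * target_rate / rate)` samples.
#' @export
resample_recording <- function(rec, target_rate = 50) {
  stopifnot(inherits(rec, "har_recording"))
  n <- nrow(rec$samples)
  if (n == 0) stop_cfg("cannot resample an empty recording")
  if (rec$rate == target_rate) return(rec)
  n_out <- round(n * target_rate / rec$rate)
  t_old <- (seq_len(n) - 1) / rec$rate
  t_new <- (seq_len(n_out) - 1) / target_rate
  out <- apply(rec$samples, 2, function(ch) {
    stats::approx(t_old, ch, xout = t_new, rule = 2)$y
  })
  out <- matrix(out, nrow = n_out, dimnames = list(NULL, colnames(rec$samples)))
  nearest <- pmin(pmax(round(t_new * rec$rate) + 1, 1), n)
  new_recording(out, target_rate, rec$labels[nearest],
                rec$subject_id, rec$dataset_id)
}

#' Append the magnitude channel
#'
#' Adds a fourth channel, the per-sample Euclidean norm of the x, y, z
#' axes. The magnitude is invariant to device orientation, which is what
#' makes it valuable under dataset-level shift; the original axes are
#' retained alongside it.
#'
#' @param rec A 3-channel `har_recording`.
#' @return A 4-channel `har_recording` (channels x, y, z, mag).
#' @export
add_magnitude <- function(rec) {
  stopifnot(inherits(rec, "har_recording"))
  if (ncol(rec$samples) != 3) stop_cfg("expected a 3-channel recording")
  mag <- sqrt(rowSums(rec$samples^2))
  samples <- cbind(rec$samples, mag = mag)
  new_recording(samples, rec$rate, rec$labels, rec$subject_id, rec$dataset_id)
}

#' Map raw activity labels onto the canonical vocabulary
#'
#' `mapping` is a named character vector `raw -> canonical`; map a raw
#' label to `NA` to drop its samples (they are removed before windowing).
#' Canonical labels absent from `mapping` pass through unchanged. Any
#' other unmapped label is an error naming the label, so silent label
#' leakage is impossible.
#'
#' @param rec A `har_recording`.
#' @param mapping Named character vector, e.g.
#'   `c(upstairs = "stairs", downstairs = "stairs", biking = NA)`.
#' @return A `har_recording` with canonical labels only.
#' @export
map_labels <- function(rec, mapping = NULL) {
  stopifnot(inherits(rec, "har_recording"))
  labs <- rec$labels
  raw <- unique(labs)
  full <- stats::setNames(as.character(raw), raw)
  if (!is.null(mapping)) full[names(mapping)[names(mapping) %in% raw]] <-
    mapping[names(mapping) %in% raw]
  unmapped <- raw[!(full[raw] %in% canonical_activities() | is.na(full[raw]))]
  if (length(unmapped)) {
    stop_cfg("unmapped label(s): %s", paste(unmapped, collapse = ", "))
  }
  new_labs <- unname(full[labs])
  keep <- !is.na(new_labs)
  new_recording(rec$samples[keep, , drop = FALSE], rec$rate, new_labs[keep],
                rec$subject_id, rec$dataset_id)
}

#' Cut a recording into fixed-length single-label windows
#'
#' Windows are cut without overlap within each maximal run of constant
#' label: a window never spans a label change (such windows are
#' discarded), and remainder samples shorter than one window are dropped.
#' The recording must already be harmonized (50 Hz, 4 channels,
#' canonical labels).
#'
#' @param rec A harmonized `har_recording`.
#' @param window_seconds Window length in seconds (default 5).
#' @param overlap Fractional overlap; only 0 is supported.
#' @return A `window_set` (possibly empty).
#' @export
windowize <- function(rec, window_seconds = 5, overlap = 0) {
  stopifnot(inherits(rec, "har_recording"))
  if (overlap != 0) stop_cfg("only non-overlapping windows are supported")
  if (rec$rate != 50) stop_cfg("windowize expects a 50 Hz recording")
  if (ncol(rec$samples) != 4) stop_cfg("windowize expects 4 channels (x,y,z,mag)")
  bad <- setdiff(unique(rec$labels), canonical_activities())
  if (length(bad)) stop_cfg("non-canonical labels: %s", paste(bad, collapse = ", "))
  wlen <- round(window_seconds * rec$rate)
  runs <- rle(rec$labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  vals <- list(); labs <- character(0)
  for (i in seq_along(runs$lengths)) {
    k <- runs$lengths[i] %/% wlen
    if (k == 0) next
    for (j in seq_len(k)) {
      a <- starts[i] + (j - 1) * wlen
      vals[[length(vals) + 1]] <- rec$samples[a:(a + wlen - 1), , drop = FALSE]
      labs <- c(labs, runs$values[i])
    }
  }
  nw <- length(vals)
  arr <- array(0, c(nw, wlen, 4))
  for (i in seq_len(nw)) arr[i, , ] <- vals[[i]]
  meta <- data.frame(
    window_id = if (nw) sprintf("%s.%s.w%04d", rec$dataset_id, rec$subject_id,
                                seq_len(nw)) else character(0),
    dataset = rep(rec$dataset_id, nw), subject = rep(rec$subject_id, nw),
    label = labs, stringsAsFactors = FALSE)
  window_set(arr, meta)
}

#' Randomly subsample a window set
#'
#' Uniform sampling without replacement of `round(fraction * n)` windows,
#' used to rein in datasets that dominate a corpus by sheer window count.
#'
#' @param ws A `window_set`.
#' @param fraction Fraction in (0, 1]; 1 is the identity.
#' @param seed Integer seed for a reproducible draw.
#' @return A `window_set`.
#' @export
subsample_windows <- function(ws, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop_cfg("fraction must be in (0, 1]")
  if (fraction == 1) return(ws)
  n <- n_windows(ws)
  with_seed(seed, ws_subset(ws, sort(sample.int(n, round(fraction * n)))))
}

#' Harmonize a collection of recordings into one window set
#'
#' The full homogenization pipeline applied per recording: resample to
#' 50 Hz, append the magnitude channel (skipped for recordings that
#' already carry 4 channels), map labels to the canonical vocabulary,
#' cut 5-second single-label windows, then optionally subsample
#' individual datasets. Applying the pipeline to an already-harmonized
#' corpus reproduces it exactly.
#'
#' @param recordings A `har_benchmark` or list of `har_recording`s.
#' @param mapping Optional raw-label mapping passed to [map_labels()].
#' @param target_rate Common rate, Hz.
#' @param dataset_fractions Optional named vector of per-dataset window
#'   fractions for [subsample_windows()] (e.g. `c(RealWorld = 1/3)`).
#' @param seed Seed for the subsampling draws.
#' @return A `window_set` covering all recordings, with window ids made
#'   unique across recordings.
#' @export
harmonize_recordings <- function(recordings, mapping = NULL, target_rate = 50,
                                 dataset_fractions = NULL, seed = NULL) {
  if (inherits(recordings, "har_benchmark")) recordings <- recordings$recordings
  parts <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    rec <- resample_recording(rec, target_rate)
    if (ncol(rec$samples) == 3) rec <- add_magnitude(rec)
    rec <- map_labels(rec, mapping)
    ws <- windowize(rec)
    if (n_windows(ws) > 0) {
      ws$meta$window_id <- sprintf("r%03d.%s", i, ws$meta$window_id)
    }
    parts[[i]] <- ws
  }
  out <- ws_bind(parts)
  if (!is.null(dataset_fractions)) {
    keep <- lapply(unique(out$meta$dataset), function(d) {
      sub <- ws_subset(out, which(out$meta$dataset == d))
      f <- dataset_fractions[d]
      if (!is.na(f)) sub <- subsample_windows(sub, f, seed = seed)
      sub
    })
    out <- ws_bind(keep)
  }
  out
}

#' Write / read a window set as delimited text
#'
#' Flat table, one row per window: `window_id`, `dataset`, `subject`,
#' `label`, then 1000 values (250 samples x 4 channels, channel-major:
#' all of x, then y, z, magnitude). A compact index file
#' (`<path>.idx`, metadata only) is written alongside. The round trip is
#' lossless to full double precision.
#'
#' @param ws A `window_set`.
#' @param path Output file path.
#' @return `write_window_set` returns `path` invisibly;
#'   `read_window_set` returns the `window_set`.
#' @export
write_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  d <- dim(ws$values)
  flat <- matrix(ws$values, nrow = d[1])  # column order: sample-major per channel
  colnames(flat) <- as.vector(outer(sprintf("s%03d", seq_len(d[2])),
                                    c("x", "y", "z", "mag")[seq_len(d[3])],
                                    function(s, c) paste(c, s, sep = "_")))
  dt <- data.table::data.table(ws$meta, flat)
  data.table::fwrite(dt, path, sep = "\t")
  data.table::fwrite(data.table::as.data.table(ws$meta),
                     paste0(path, ".idx"), sep = "\t")
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  meta_cols <- c("window_id", "dataset", "subject", "label")
  vals <- as.matrix(dt[setdiff(names(dt), meta_cols)])
  n_ch <- length(unique(sub("_s[0-9]+$", "", colnames(vals))))
  window_set(array(vals, c(nrow(vals), ncol(vals) / n_ch, n_ch)),
             dt[meta_cols])
}
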