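#' Activity signal model
#'
#' Describes the waveform family used to synthesize one activity class.
#' Periodic activities (walk, run, stairs) are quasi-sinusoidal: a fundamental
#' at `base_frequency` plus a weaker second harmonic along the body-vertical
#' axis, smaller lateral components, and (for stairs) strong slow amplitude
#' modulation. Static activities (sit, stand) are the gravity vector projected
#' on `gravity_axis_weights` plus tremor noise of scale `noise_floor`.
#'
#' @param activity One of `canonical_activities()`.
#' @param base_frequency Fundamental stride frequency in Hz. Must be positive
#'   for walk/run/stairs and zero for sit/stand.
#' @param base_amplitude Oscillation amplitude scale in m/s^2.
#' @param gravity_axis_weights Unit 3-vector giving the body-vertical axis.
#' @param noise_floor Standard deviation (m/s^2) of the activity's intrinsic
#'   tremor noise (distinct from device noise, which lives in
#'   [domain_params()]).
#' @param am_depth Relative depth of slow amplitude modulation (stairs use a
#'   deep modulation to mimic the alternating step/landing cadence).
#' @param impulse_weight Relative weight of a phase-locked heel-strike
#'   impulse train superposed on the vertical oscillation: a sharply
#'   decaying burst at every stride onset.
#' @param lateral_phase Phase offset (radians) of the primary lateral
#'   oscillation relative to the vertical one. Per-channel summary
#'   features are blind to cross-channel timing, so a class pair that
#'   differs mainly in this phase relation is separable from the raw
#'   multi-channel waveform but not from channel-wise statistics — the
#'   kind of subtlety that gives representation learners in-distribution
#'   headroom, and that sensor rotation destroys out of distribution.
#'
#' @return An object of class `activity_model`.
#' @seealso [default_activity_models()], [generate_recording()]
#' @export
activity_model <- function(activity, base_frequency, base_amplitude,
                           gravity_axis_weights = c(0, 0, 1),
                           noise_floor = 0, am_depth = 0,
                           impulse_weight = 0, lateral_phase = 0) {
  if (!activity %in% canonical_activities()) {
    stop_cfg("unknown activity '%s'; expected one of: %s", activity,
             paste(canonical_activities(), collapse = ", "))
  }
  static <- activity %in% c("sit", "stand")
  if (static && base_frequency != 0) {
    stop_cfg("static activity '%s' must have base_frequency = 0", activity)
  }
  if (!static && base_frequency <= 0) {
    stop_cfg("periodic activity '%s' must have base_frequency > 0", activity)
  }
  w <- as.numeric(gravity_axis_weights)
  if (length(w) != 3 || abs(sqrt(sum(w^2)) - 1) > 1e-8) {
    stop_cfg("gravity_axis_weights must be a unit 3-vector")
  }
  structure(list(activity = activity, base_frequency = base_frequency,
                 base_amplitude = base_amplitude, gravity_axis_weights = w,
                 noise_floor = noise_floor, am_depth = am_depth,
                 impulse_weight = impulse_weight,
                 lateral_phase = lateral_phase),
            class = "activity_model")
}

#' Default activity models for the five canonical classes
#'
#' Parameter choices aim for classes that are separable but not trivially
#' so. Walk (2 Hz) and stairs (1.75 Hz) are channel-wise near twins:
#' identical amplitude, overlapping cadence ranges once inter-subject
#' variation is applied, and only weak asymmetries in modulation depth
#' and footfall impulses. Their strongest difference is the
#' lateral-to-vertical phase relation (+90 vs -90 degrees): a
#' gait-geometry cue that channel-wise summary features cannot see but a
#' multi-channel network can learn — and that sensor rotation destroys,
#' while the weak asymmetries survive any rotation via the magnitude
#' channel. Run is fast and large-amplitude with strong
#' footfall impulses; sit is a tilted gravity vector with faint tremor;
#' stand is upright with stronger postural sway (the two share the
#' 9.81 m/s^2 magnitude and differ in tremor and gravity direction).
#'
#' @return Named list of [activity_model()] objects.
#' @export
default_activity_models <- function() {
  list(
    walk   = activity_model("walk",   2.0, 3.2, c(0, 0, 1), noise_floor = 0.30,
                            am_depth = 0.30, impulse_weight = 0.35,
                            lateral_phase = pi / 2),
    run    = activity_model("run",    2.8, 8.0, c(0, 0, 1), noise_floor = 0.50,
                            impulse_weight = 0.5, lateral_phase = pi / 2),
    stairs = activity_model("stairs", 1.75, 3.2, c(0, 0, 1), noise_floor = 0.30,
                            am_depth = 0.55, impulse_weight = 0.15,
                            lateral_phase = -pi / 2),
    sit    = activity_model("sit",    0, 0, c(0, 0.5, sqrt(3) / 2),
                            noise_floor = 0.03),
    stand  = activity_model("stand",  0, 0, c(0, 0, 1), noise_floor = 0.08)
  )
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

# Random rotation: uniform random axis, angle ~ N(0, angle_sd). angle_sd = 0
# gives the identity exactly.
random_rotation <- function(angle_sd) {
  if (angle_sd == 0) return(diag(3))
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::rnorm(1, 0, angle_sd))
}

#' Domain parameters: which dataset/subject/device produced a recording
#'
#' Encodes the three nested domain levels of a multi-dataset accelerometer
#' corpus: the dataset (sensor orientation/position convention, calibration
#' offset, native sampling rate), the subject (gait frequency and amplitude
#' scaling), and the device (measurement noise).
#'
#' @param dataset_id,subject_id Identifiers.
#' @param native_rate Sampling rate in Hz; must be at least 50 Hz up to a
#'   5% tolerance (datasets sampled much below 50 Hz are excluded from the
#'   benchmark to avoid oversampling).
#' @param orientation 3x3 rotation from body frame to sensor frame.
#' @param device_noise_sd Per-axis white measurement noise sd, m/s^2.
#' @param calibration_offset 3-vector additive bias, m/s^2.
#' @param subject_freq_scale,subject_amp_scale Dimensionless multipliers on
#'   the activity model's base frequency and amplitude.
#'
#' @return An object of class `domain_params`.
#' @export
domain_params <- function(dataset_id, subject_id, native_rate = 50,
                          orientation = diag(3), device_noise_sd = 0,
                          calibration_offset = c(0, 0, 0),
                          subject_freq_scale = 1, subject_amp_scale = 1) {
  R <- as.matrix(orientation)
  if (!all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8 ||
      abs(det(R) - 1) > 1e-8) {
    stop_cfg("orientation must be a proper rotation (orthonormal, det +1)")
  }
  if (native_rate < 50 * (1 - 0.05)) {
    stop_cfg("native_rate %.1f Hz is below the 50 Hz (within 5%%) benchmark floor",
             native_rate)
  }
  structure(list(dataset_id = dataset_id, subject_id = subject_id,
                 native_rate = native_rate, orientation = R,
                 device_noise_sd = device_noise_sd,
                 calibration_offset = as.numeric(calibration_offset),
                 subject_freq_scale = subject_freq_scale,
                 subject_amp_scale = subject_amp_scale),
            class = "domain_params")
}

new_recording <- function(samples, rate, labels, subject_id, dataset_id) {
  stopifnot(nrow(samples) == length(labels))
  structure(list(samples = samples, rate = rate, labels = labels,
                 subject_id = subject_id, dataset_id = dataset_id),
            class = "har_recording")
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("<har_recording> %s/%s: %d samples x %d ch @ %g Hz, labels: %s\n",
              x$dataset_id, x$subject_id, nrow(x$samples), ncol(x$samples),
              x$rate, paste(unique(x$labels), collapse = ",")))
  invisible(x)
}

#' Synthesize one labelled accelerometer recording
#'
#' Generates `duration` seconds of triaxial acceleration for a single
#' activity performed by a single (subject, device, dataset) domain. The
#' body-frame signal (gravity plus activity waveform plus tremor) is rotated
#' into the sensor frame by the domain's orientation, then the calibration
#' offset and white device noise are added. All randomness (phases, tremor,
#' device noise) is fixed by `seed`.
#'
#' @param model An [activity_model()].
#' @param domain A [domain_params()].
#' @param duration Length in seconds (> 0).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A `har_recording`: samples `[n x 3]` in m/s^2 at the domain's
#'   native rate, constant per-sample label.
#' @export
generate_recording <- function(model, domain, duration, seed = NULL) {
  stopifnot(inherits(model, "activity_model"), inherits(domain, "domain_params"))
  if (duration <= 0) stop_cfg("duration must be positive")
  with_seed(seed, {
    rate <- domain$native_rate
    n <- round(duration * rate)
    t <- (seq_len(n) - 1) / rate
    w <- model$gravity_axis_weights
    # orthonormal complement of the vertical axis: lateral directions
    ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u1 <- ref - sum(ref * w) * w; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(w[2] * u1[3] - w[3] * u1[2],
            w[3] * u1[1] - w[1] * u1[3],
            w[1] * u1[2] - w[2] * u1[1])
    g <- 9.81
    body <- tcrossprod(rep(1, n), g * w)  # gravity baseline
    if (model$base_frequency > 0) {
      f <- model$base_frequency * domain$subject_freq_scale
      A <- model$base_amplitude * domain$subject_amp_scale
      ph <- stats::runif(5, 0, 2 * pi)
      am <- 1 + model$am_depth * sin(2 * pi * 0.25 * t + ph[5])
      vert <- am * (A * sin(2 * pi * f * t + ph[1]) +
                      0.35 * A * sin(2 * pi * 2 * f * t + ph[2]))
      if (model$impulse_weight > 0) {
        # heel-strike burst at every stride onset: a sharply decaying
        # oscillation locked to the stride phase
        phase <- (f * t + ph[1] / (2 * pi)) %% 1
        burst <- exp(-phase / 0.08) * sin(2 * pi * phase / 0.16)
        vert <- vert + model$impulse_weight * A * am * burst
      }
      # primary lateral component phase-locked to the vertical oscillation
      lat1 <- 0.30 * A * sin(2 * pi * f * t + ph[1] + model$lateral_phase)
      lat2 <- 0.20 * A * sin(pi * f * t + ph[4])
      body <- body + tcrossprod(vert, w) + tcrossprod(lat1, u1) +
        tcrossprod(lat2, u2)
    }
    if (model$noise_floor > 0) {
      body <- body + matrix(stats::rnorm(3 * n, 0, model$noise_floor), n, 3)
    }
    sensor <- body %*% t(domain$orientation)
    sensor <- sweep(sensor, 2, domain$calibration_offset, `+`)
    if (domain$device_noise_sd > 0) {
      sensor <- sensor + matrix(stats::rnorm(3 * n, 0, domain$device_noise_sd),
                                n, 3)
    }
    colnames(sensor) <- c("x", "y", "z")
    new_recording(sensor, rate, rep(model$activity, n),
                  domain$subject_id, domain$dataset_id)
  })
}

#' Benchmark configuration
#'
#' Describes a synthetic multi-dataset corpus: how many datasets and
#' subjects, how long each subject performs each activity, and the three
#' shift magnitudes. `sigma_dataset` scales the dataset-level orientation
#' rotation (radians) and calibration offset; `sigma_subject` scales the
#' log-normal subject gait variation and a small subject-level orientation
#' jitter; `sigma_device` sets the device measurement-noise scale (m/s^2).
#' Setting a sigma to zero removes that shift level entirely.
#'
#' The defaults are the package's reference study conditions: 3 datasets of
#' 8 subjects, 120 s per activity per subject (24 five-second windows), with
#' mild subject variation, moderate device noise, and strong dataset-level
#' orientation/offset shift — the regime in which held-out-dataset transfer
#' is genuinely out-of-distribution.
#'
#' @param n_datasets,subjects_per_dataset Corpus dimensions.
#' @param duration_per_activity Seconds of each activity per subject.
#' @param sigma_subject,sigma_device,sigma_dataset Shift magnitudes.
#' @param native_rates Pool of native sampling rates (Hz) datasets draw from.
#' @param activity_models Named list of [activity_model()]s.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(n_datasets = 3, subjects_per_dataset = 8,
                             duration_per_activity = 120,
                             sigma_subject = 0.12, sigma_device = 0.3,
                             sigma_dataset = 0.7,
                             native_rates = c(50, 100, 200),
                             activity_models = default_activity_models()) {
  if (n_datasets < 2) stop_cfg("need at least 2 datasets (held-out-dataset splits)")
  if (subjects_per_dataset < 2) {
    stop_cfg("need at least 2 subjects per dataset (held-out-user split)")
  }
  structure(list(n_datasets = n_datasets,
                 subjects_per_dataset = subjects_per_dataset,
                 duration_per_activity = duration_per_activity,
                 sigma_subject = sigma_subject, sigma_device = sigma_device,
                 sigma_dataset = sigma_dataset, native_rates = native_rates,
                 activity_models = activity_models),
            class = "benchmark_config")
}

#' Generate a multi-dataset accelerometer benchmark
#'
#' Draws dataset-level domains (orientation, offset, native rate), then
#' subject-level domains within each dataset (gait scales, small orientation
#' jitter, device noise), then one recording per (subject, activity).
#' Subjects within a dataset share the dataset's orientation/offset draw, so
#' between-dataset shift grows with `sigma_dataset` while within-dataset
#' heterogeneity is governed by `sigma_subject` and `sigma_device`.
#'
#' @param config A [benchmark_config()].
#' @param seed Integer master seed; the same (config, seed) pair always
#'   reproduces the identical corpus.
#' @return A `har_benchmark`: list with `recordings` (list of
#'   `har_recording`), `config`, and `dataset_ids`.
#' @export
make_benchmark <- function(config = benchmark_config(), seed = 1) {
  stopifnot(inherits(config, "benchmark_config"))
  with_seed(seed, {
    recs <- list()
    dataset_ids <- sprintf("D%d", seq_len(config$n_datasets))
    for (d in dataset_ids) {
      R_d <- random_rotation(config$sigma_dataset)
      off_d <- stats::rnorm(3, 0, 0.3 * config$sigma_dataset)
      rate_d <- if (length(config$native_rates) == 1) config$native_rates else
        sample(config$native_rates, 1)
      for (s in seq_len(config$subjects_per_dataset)) {
        sid <- sprintf("%s_S%02d", d, s)
        R_s <- R_d %*% random_rotation(0.5 * config$sigma_subject)
        dom <- domain_params(
          dataset_id = d, subject_id = sid, native_rate = rate_d,
          orientation = R_s,
          device_noise_sd = config$sigma_device * stats::runif(1, 0.7, 1.3),
          calibration_offset = off_d,
          subject_freq_scale = exp(stats::rnorm(1, 0, config$sigma_subject)),
          subject_amp_scale = exp(stats::rnorm(1, 0, config$sigma_subject)))
        for (am in config$activity_models) {
          rec_seed <- sample.int(.Machine$integer.max - 1L, 1)
          recs[[length(recs) + 1]] <- generate_recording(
            am, dom, config$duration_per_activity, seed = rec_seed)
        }
      }
    }
    structure(list(recordings = recs, config = config,
                   dataset_ids = dataset_ids),
              class = "har_benchmark")
  })
}

#' @export
print.har_benchmark <- function(x, ...) {
  cat(sprintf("<har_benchmark> %d datasets, %d recordings\n",
              length(x$dataset_ids), length(x$recordings)))
  invisible(x)
}

#' Write / read a single recording as plain text
#'
#' One file per recording: `#`-prefixed header lines (dataset, subject,
#' rate) followed by whitespace-separated columns `t ax ay az label`
#' (plus `amag` when a magnitude channel is present).
#'
#' @param rec A `har_recording`.
#' @param path Output file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the reconstructed `har_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "har_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dataset: %s", rec$dataset_id),
               sprintf("# subject: %s", rec$subject_id),
               sprintf("# rate: %.10g", rec$rate)), con)
  n <- nrow(rec$samples)
  df <- data.frame(t = (seq_len(n) - 1) / rec$rate, rec$samples,
                   label = rec$labels)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 3)
  get_field <- function(key) sub(sprintf("^# %s: ", key), "", grep(
    sprintf("^# %s:", key), hdr, value = TRUE))
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  chan <- setdiff(names(df), c("t", "label"))
  samples <- as.matrix(df[chan])
  colnames(samples) <- chan
  new_recording(samples, as.numeric(get_field("rate")),
                as.character(df$label), get_field("subject"),
                get_field("dataset"))
}

#' Write / read a benchmark corpus as a directory of text files
#'
#' Writes one file per recording under `dir/recordings/` plus a YAML
#' manifest (`manifest.yaml`) listing files and the generating
#' configuration, so a corpus on disk is self-describing.
#'
#' @param bench A `har_benchmark`.
#' @param dir Directory (created if needed).
#' @return `write_benchmark` returns `dir` invisibly; `read_benchmark`
#'   returns the `har_benchmark`.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "har_benchmark"))
  rdir <- file.path(dir, "recordings")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(bench$recordings))
  for (i in seq_along(bench$recordings)) {
    r <- bench$recordings[[i]]
    files[i] <- sprintf("recordings/%s_%s_%03d.txt", r$dataset_id,
                        r$subject_id, i)
    write_recording(r, file.path(dir, files[i]))
  }
  cfg <- bench$config
  manifest <- list(
    dataset_ids = bench$dataset_ids,
    files = files,
    config = list(n_datasets = cfg$n_datasets,
                  subjects_per_dataset = cfg$subjects_per_dataset,
                  duration_per_activity = cfg$duration_per_activity,
                  sigma_subject = cfg$sigma_subject,
                  sigma_device = cfg$sigma_device,
                  sigma_dataset = cfg$sigma_dataset,
                  native_rates = cfg$native_rates))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  recs <- lapply(manifest$files, function(f) read_recording(file.path(dir, f)))
  cfg <- manifest$config
  config <- benchmark_config(
    n_datasets = cfg$n_datasets,
    subjects_per_dataset = cfg$subjects_per_dataset,
    duration_per_activity = cfg$duration_per_activity,
    sigma_subject = cfg$sigma_subject, sigma_device = cfg$sigma_device,
    sigma_dataset = cfg$sigma_dataset,
    native_rates = unlist(cfg$native_rates))
  structure(list(recordings = recs, config = config,
                 dataset_ids = unlist(manifest$dataset_ids)),
            class = "har_benchmark")
}
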