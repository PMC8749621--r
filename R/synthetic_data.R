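#' Configuration of the synthetic record generator
#'
#' The generator emulates the capture protocol used for training data: ~32 s
#' records sampled at 32 Hz, with the wearer motionless for a few seconds at
#' the head and tail (the clean windows), movement bursts in the middle
#' segment coupled into the PPG channel, and additive sensor noise.
#'
#' @param duration record length in seconds (default 32).
#' @param sampling_rate samples per second (default 32).
#' @param hr_start,hr_end heart rate (bpm) at the start/end of the record;
#'   the instantaneous rate moves linearly between them. Both in [40, 180].
#' @param clean_head,clean_tail movement-free seconds at head/tail
#'   (default 5 each).
#' @param artifact_gain nonnegative scale of the motion artifact coupled
#'   into the PPG channel (default 1).
#' @param noise_sd standard deviation of the additive Gaussian sensor noise
#'   on every channel (default 0.02).
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration = 32, sampling_rate = 32,
                         hr_start = 70, hr_end = 72,
                         clean_head = 5, clean_tail = 5,
                         artifact_gain = 1, noise_sd = 0.02, seed = 1L) {
  if (clean_head + clean_tail >= duration)
    stop("clean_head + clean_tail must be < duration")
  if (hr_start < 40 || hr_start > 180 || hr_end < 40 || hr_end > 180)
    stop("heart rates must lie in [40, 180] bpm")
  if (artifact_gain < 0) stop("artifact_gain must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 hr_start = hr_start, hr_end = hr_end,
                 clean_head = clean_head, clean_tail = clean_tail,
                 artifact_gain = artifact_gain, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Ground-truth peak times for a synthetic record
#'
#' The instantaneous heart rate moves linearly from `hr_start` to `hr_end`
#' over the record; peak times are the (exact, closed-form) crossings of the
#' integrated beat phase at half-integer offsets, so the first peak falls
#' half a beat into the record. Window A ends at `clean_head`; Window B
#' starts at `duration - clean_tail`.
#'
#' @param config a [synth_config()].
#' @return a [peak_annotation()] with >= 2 peaks inside each clean window.
#' @export
generate_true_peaks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dur <- config$duration
  a <- (config$hr_end - config$hr_start) / (120 * dur)  # phase = a t^2 + b t
  b <- config$hr_start / 60
  phase_at_end <- a * dur^2 + b * dur
  k <- seq(0.5, phase_at_end, by = 1)
  times <- if (abs(a) < 1e-12) k / b else (-b + sqrt(b^2 + 4 * a * k)) / (2 * a)
  times <- times[times <= dur]
  wa <- config$clean_head
  wb <- dur - config$clean_tail
  if (sum(times <= wa) < 2L || sum(times >= wb) < 2L)
    stop("configuration yields fewer than 2 peaks in a clean window")
  peak_annotation(times, window_a_end = wa, window_b_start = wb)
}

# Tukey-style envelope: 1 inside [lo, hi] with raised-cosine ramps of `ramp`
# seconds just inside the boundaries, exactly 0 outside.
motion_envelope <- function(t, lo, hi, ramp = 1) {
  env <- numeric(length(t))
  inside <- t > lo & t < hi
  env[inside] <- 1
  up <- t > lo & t < lo + ramp
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - lo) / ramp))
  down <- t > hi - ramp & t < hi
  env[down] <- 0.5 * (1 - cos(pi * (hi - t[down]) / ramp))
  env
}

#' Generate a synthetic record with known ground truth
#'
#' The clean pulse is a bottom-flattened piecewise cosine with maxima exactly
#' at the true peak times (the same waveform family [build_reference()]
#' produces, so target recovery can be tested exactly). Each accelerometer
#' axis carries a burst of 2–5 random sinusoids in 0.5–5 Hz — the
#' walking/arm-swing band that overlaps the heart-rate band — enveloped to
#' the middle segment, plus sensor noise everywhere. The motion artifact
#' added to the PPG is a deterministic function of those burst components:
#' a linear mix plus an amplitude modulation of the pulse by their rectified
#' mean, scaled by `artifact_gain`. Identical seeds give identical records.
#'
#' The clean pulse is stored in the record's `target` field.
#'
#' @param config a [synth_config()].
#' @return list with elements `record` (a [signal_record()] whose `target`
#'   holds the clean pulse) and `annotation` (the true
#'   [peak_annotation()]).
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ann <- generate_true_peaks(config)
  n <- round(config$duration * config$sampling_rate)
  t <- (seq_len(n) - 1) / config$sampling_rate
  clean <- synthesize_target(ann$peak_times, n, config$sampling_rate, G = 0.3)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  env <- motion_envelope(t, config$clean_head,
                         config$duration - config$clean_tail)
  bursts <- lapply(1:3, function(axis) {
    m <- sample(2:5, 1)
    freq <- stats::runif(m, 0.5, 5)
    amp <- stats::runif(m, 0.2, 1)
    ph <- stats::runif(m, 0, 2 * pi)
    raw <- colSums(amp * sin(outer(2 * pi * freq, t) + ph))
    mx <- max(abs(raw))
    env * (if (mx > 0) raw / mx else raw)
  })
  noise <- lapply(1:4, function(i) stats::rnorm(n, 0, config$noise_sd))

  mix <- 0.5 * bursts[[1]] + 0.3 * bursts[[2]] + 0.2 * bursts[[3]]
  rect <- (abs(bursts[[1]]) + abs(bursts[[2]]) + abs(bursts[[3]])) / 3
  artifact <- config$artifact_gain * (0.6 * mix + 0.4 * clean * rect)

  record <- signal_record(
    ppg = clean + artifact + noise[[1]],
    acc_x = bursts[[1]] + noise[[2]],
    acc_y = bursts[[2]] + noise[[3]],
    acc_z = bursts[[3]] + noise[[4]],
    sampling_rate = config$sampling_rate,
    target = clean,
    record_id = sprintf("synth-%d", config$seed))
  list(record = record, annotation = ann)
}

#' Generate a corpus of synthetic records
#'
#' Per-record heart rates are drawn uniformly in [55, 95] bpm with a gentle
#' within-record drift of up to ±2 bpm, emulating resting captures from
#' different wearers; record seeds derive deterministically from `seed`.
#'
#' @param n_records number of records.
#' @param seed master integer seed.
#' @param config template [synth_config()]; its heart rates are redrawn per
#'   record, the remaining fields are kept.
#' @return list of `list(record, annotation, config)` entries.
#' @export
generate_corpus <- function(n_records, seed = 1L, config = synth_config()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  hr0 <- stats::runif(n_records, 55, 95)
  drift <- stats::runif(n_records, -2, 2)
  seeds <- sample.int(2^30, n_records)
  lapply(seq_len(n_records), function(i) {
    cfg <- config
    cfg$hr_start <- hr0[i]
    cfg$hr_end <- hr0[i] + drift[i]
    cfg$seed <- seeds[i]
    out <- generate_record(cfg)
    out$record$record_id <- sprintf("synth-%03d", i)
    out$config <- cfg
    out
  })
}
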