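#' Inter-peak periods of the clean windows
#'
#' `T_A` is the interval between the last two peaks inside Time Window A,
#' `T_B` the interval between the first two peaks inside Time Window B, and
#' `T_M` their arithmetic mean — the working estimate of the beat period
#' across the motion-corrupted gap between the windows.
#'
#' @param annotation a [peak_annotation()] with both window boundaries set.
#' @return list with elements `T_A`, `T_B`, `T_M`, and the anchor times
#'   `t_A` (last peak in Window A) and `t_B` (last peak in Window B).
#' @export
window_periods <- function(annotation) {
  stopifnot(inherits(annotation, "peak_annotation"))
  if (is.na(annotation$window_a_end) || is.na(annotation$window_b_start))
    stop("annotation must carry both clean-window boundaries")
  pk <- annotation$peak_times
  a <- pk[pk <= annotation$window_a_end]
  b <- pk[pk >= annotation$window_b_start]
  if (length(a) < 2L) stop("fewer than 2 peaks in Time Window A")
  if (length(b) < 2L) stop("fewer than 2 peaks in Time Window B")
  T_A <- a[length(a)] - a[length(a) - 1L]
  T_B <- b[2L] - b[1L]
  list(T_A = T_A, T_B = T_B, T_M = (T_A + T_B) / 2,
       t_A = a[length(a)], t_B = b[length(b)])
}

round_half_up <- function(x) floor(x + 0.5)

#' Validate the gap between the clean windows
#'
#' The number of beat intervals spanning the gap is `n = (t_B - t_A) / T_M`.
#' The linear-interval extrapolation is considered usable when `n` is within
#' 0.5 of an integer, with half-up rounding; the boundary case counts as
#' valid.
#'
#' @param t_A time of the last peak in Time Window A (s).
#' @param t_B time of the last peak in Time Window B (s).
#' @param T_M mean clean-window beat period (s).
#' @return list with `n` (real), `n_round` (integer) and `valid` (logical).
#' @export
check_gap <- function(t_A, t_B, T_M) {
  if (!is.finite(T_M) || T_M <= 0) stop("T_M must be positive")
  if (t_B <= t_A) stop("t_B must exceed t_A")
  n <- (t_B - t_A) / T_M
  n_round <- as.integer(round_half_up(n))
  list(n = n, n_round = n_round, valid = abs(n - n_round) <= 0.5)
}

#' Linearly interpolated beat intervals across the gap
#'
#' Produces `n_round` intervals `T_i` changing linearly in `i` so that they
#' start near `T_A` and sum exactly to `t_B - t_A`:
#' `T_i = T_A + 2 i ((t_B - t_A)/n_round - T_A) / (n_round + 1)`.
#' Their cumulative sums added to `t_A` give `n_round - 1` interior peak
#' times and land exactly on `t_B`.
#'
#' @param T_A last clean beat period of Window A (s).
#' @param t_A,t_B anchor peak times (s).
#' @param n_round integer number of intervals, >= 1.
#' @return list with `intervals` (length `n_round`) and `inserted_peaks`
#'   (length `n_round - 1`).
#' @export
interpolate_intervals <- function(T_A, t_A, t_B, n_round) {
  if (n_round < 1L) stop("n_round must be >= 1")
  i <- seq_len(n_round)
  intervals <- T_A + 2 * i * ((t_B - t_A) / n_round - T_A) / (n_round + 1)
  peaks <- t_A + cumsum(intervals)
  list(intervals = intervals,
       inserted_peaks = if (n_round > 1L) peaks[seq_len(n_round - 1L)]
                        else numeric(0))
}

#' Bottom-flattening of an ideal waveform
#'
#' Real PPG pulses are asymmetric: the trough is shallower than the crest.
#' A pure cosine through the peaks is therefore corrected by keeping
#' non-negative values and scaling negative values by `G` (default 0.3):
#' `s -> s` for `s >= 0`, `s -> G s` for `s < 0`. The map is continuous at 0
#' and monotone for any `G` in (0, 1].
#'
#' @param s numeric vector.
#' @param G flattening gain in (0, 1].
#' @return the flattened vector.
#' @export
flatten_bottom <- function(s, G = 0.3) {
  stopifnot(G > 0, G <= 1)
  ifelse(s < 0, G * s, s)
}

#' Synthesize the ideal target waveform through a peak train
#'
#' Builds a piecewise cosine whose maxima (+1) fall exactly on the given
#' peak times, with one full period between consecutive peaks; before the
#' first and after the last peak the adjacent segment's period is extended.
#' The cosine is then bottom-flattened with [flatten_bottom()] and, by
#' default, min–max normalized to \eqn{[-1, 1]} on the sampled grid.
#'
#' @param peaks strictly increasing peak times (s); at least 2.
#' @param length number of output samples.
#' @param sampling_rate samples per second.
#' @param G flattening gain, default 0.3.
#' @param normalize map the result to `[-1, 1]` (default TRUE).
#' @return numeric vector of `length` samples.
#' @export
synthesize_target <- function(peaks, length, sampling_rate, G = 0.3,
                              normalize = TRUE) {
  if (base::length(peaks) < 2L) stop("need at least 2 peaks")
  if (any(diff(peaks) <= 0)) stop("peaks must be strictly increasing")
  t <- (seq_len(length) - 1) / sampling_rate
  k <- findInterval(t, peaks)
  k <- pmin(pmax(k, 1L), base::length(peaks) - 1L)  # extend edge periods
  period <- peaks[k + 1L] - peaks[k]
  s <- cospi(2 * (t - peaks[k]) / period)
  s <- flatten_bottom(s, G)
  if (normalize) {
    mn <- min(s); mx <- max(s)
    if (mx > mn) s <- 2 * (s - mn) / (mx - mn) - 1
  }
  s
}

#' Build the reference target waveform for a record
#'
#' Composes [window_periods()], [check_gap()], [interpolate_intervals()] and
#' [synthesize_target()]: the detected peaks of the clean windows anchor a
#' linear extrapolation of beat intervals across the motion-corrupted gap,
#' and an ideal bottom-flattened cosine through the resulting full peak train
#' becomes the record's training target. If the gap check fails the record
#' is flagged rejected (`record$rejected`, excluded from training) and no
#' target is attached.
#'
#' @param record a valid `signal_record`.
#' @param annotation a `peak_annotation` with window boundaries.
#' @param G bottom-flattening gain, default 0.3.
#' @return the record with `target` populated (or `rejected = TRUE`), with
#'   attribute `"gap"` holding the [check_gap()] result.
#' @export
build_reference <- function(record, annotation, G = 0.3) {
  validate_record(record)
  wp <- window_periods(annotation)
  gap <- check_gap(wp$t_A, wp$t_B, wp$T_M)
  if (!gap$valid) {
    record$rejected <- TRUE
    attr(record, "gap") <- gap
    return(record)
  }
  ip <- interpolate_intervals(wp$T_A, wp$t_A, wp$t_B, gap$n_round)
  pk <- annotation$peak_times
  full <- c(pk[pk <= wp$t_A], ip$inserted_peaks, wp$t_B)
  record$target <- synthesize_target(full, length(record$ppg),
                                     record$sampling_rate, G = G)
  attr(record, "gap") <- gap
  record
}
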