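#' Zero-phase Butterworth band-pass filter
#'
#' Designs a maximally-flat-magnitude (Butterworth) band-pass of the given
#' overall order and applies it twice — once forwards, once backwards — so
#' phase distortion cancels and peak positions are preserved. The
#' twice-applied magnitude response is exactly the square of the single-pass
#' response. The default band 0.5–4 Hz covers 30–240 bpm.
#'
#' @param x numeric signal.
#' @param sampling_rate samples per second.
#' @param low_hz,high_hz band edges; `0 < low_hz < high_hz < sampling_rate/2`.
#' @param order overall filter order (even; default 8).
#' @param forward_backward apply the filter in both directions (default
#'   TRUE); FALSE gives the causal single pass.
#' @return the filtered signal (same length).
#' @export
zero_phase_bandpass <- function(x, sampling_rate, low_hz = 0.5, high_hz = 4,
                                order = 8L, forward_backward = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < sampling_rate / 2))
    stop("need 0 < low_hz < high_hz < sampling_rate/2")
  if (order %% 2L != 0L) stop("order must be even for a band-pass design")
  bf <- signal::butter(order / 2L, c(low_hz, high_hz) / (sampling_rate / 2),
                       type = "pass")
  # point-reflection padding tames the start-up/tail transients of the IIR
  # passes near the record edges; the pad is cropped off afterwards
  n <- length(x)
  npad <- min(n - 1L,
              max(3L * (2L * order + 1L),
                  as.integer(round(2 * sampling_rate / low_hz))))
  xp <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- as.numeric(signal::filter(bf, xp))
  if (forward_backward)
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[npad + seq_len(n)]
}

#' Detect peaks in a conditioned PPG signal
#'
#' A simple time-domain detector: strict local maxima exceeding
#' `rel_threshold` times a running amplitude estimate (local max of the
#' rectified signal over a centered ~1.5 s half-window), thinned greedily by
#' amplitude so that kept peaks are separated by at least the refractory
#' period (default 0.25 s, a 240 bpm ceiling). Times are at sample
#' resolution. Intended to run on the band-pass-filtered signal.
#'
#' @param x filtered numeric signal.
#' @param sampling_rate samples per second.
#' @param refractory minimum peak separation in seconds (default 0.25).
#' @param rel_threshold fraction of the running amplitude a peak must exceed
#'   (default 0.3).
#' @return a [peak_annotation()] (possibly empty, windows `NA`).
#' @export
detect_peaks <- function(x, sampling_rate, refractory = 0.25,
                         rel_threshold = 0.3) {
  n <- length(x)
  if (n < 3L) return(peak_annotation(numeric(0)))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(peak_annotation(numeric(0)))
  hw <- as.integer(round(1.5 * sampling_rate))
  env <- vapply(cand, function(i)
    max(abs(x[max(1L, i - hw):min(n, i + hw)])), numeric(1))
  cand <- cand[x[cand] > rel_threshold * env]
  if (!length(cand)) return(peak_annotation(numeric(0)))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- refractory * sampling_rate
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= min_gap))
      kept <- c(kept, i)
  peak_annotation(sort((kept - 1L) / sampling_rate))
}

#' Heart rate inside a time window
#'
#' 60 divided by the mean (or median) inter-peak interval among the peaks
#' falling in `[t0, t1)`; undefined (`NA`) with fewer than 2 peaks.
#'
#' @param peaks a `peak_annotation` or numeric vector of peak times.
#' @param t0,t1 window bounds in seconds, `t1 > t0`.
#' @param method `"mean"` (default) or `"median"` interval.
#' @return heart rate in bpm, or `NA`.
#' @export
hr_in_window <- function(peaks, t0, t1, method = c("mean", "median")) {
  method <- match.arg(method)
  if (t1 <= t0) stop("t1 must exceed t0")
  pt <- if (inherits(peaks, "peak_annotation")) peaks$peak_times else peaks
  pt <- pt[pt >= t0 & pt < t1]
  if (length(pt) < 2L) return(NA_real_)
  iv <- diff(pt)
  60 / if (method == "mean") mean(iv) else stats::median(iv)
}

#' Sliding-window heart-rate MAE
#'
#' The standard evaluation protocol: heart rate is estimated in windows of
#' `window_length` seconds slid by `shift` seconds (window starts `0, shift,
#' 2 shift, ...` while the window still fits in the record), for both the
#' estimated and the ground-truth peak trains; the score is the mean
#' absolute error in bpm over the windows where both are defined.
#'
#' @param est,truth `peak_annotation`s (or numeric peak-time vectors).
#' @param duration record duration in seconds.
#' @param window_length window length in seconds (default 8).
#' @param shift window shift in seconds (default 2).
#' @param method interval summary passed to [hr_in_window()].
#' @return an object of class `hr_evaluation`: list with `per_window`
#'   (data.frame of `t0`, `hr_estimate`, `hr_truth`), `mae`, `n_windows`,
#'   `n_defined`, `window_length`, `shift`.
#' @export
evaluate_mae <- function(est, truth, duration, window_length = 8, shift = 2,
                         method = "mean") {
  if (window_length > duration)
    stop("window_length exceeds the record duration")
  starts <- seq(0, duration - window_length, by = shift)
  hr_e <- vapply(starts, function(t0)
    hr_in_window(est, t0, t0 + window_length, method), numeric(1))
  hr_t <- vapply(starts, function(t0)
    hr_in_window(truth, t0, t0 + window_length, method), numeric(1))
  ok <- !is.na(hr_e) & !is.na(hr_t)
  if (!any(ok)) warning("no window has both estimate and truth defined")
  structure(list(per_window = data.frame(t0 = starts, hr_estimate = hr_e,
                                         hr_truth = hr_t),
                 mae = if (any(ok)) mean(abs(hr_e[ok] - hr_t[ok])) else NA_real_,
                 n_windows = length(starts), n_defined = sum(ok),
                 window_length = window_length, shift = shift),
            class = "hr_evaluation")
}

#' @export
print.hr_evaluation <- function(x, ...) {
  cat(sprintf("<hr_evaluation: MAE %.3f bpm over %d/%d defined windows (%g s / %g s)>\n",
              x$mae, x$n_defined, x$n_windows, x$window_length, x$shift))
  invisible(x)
}

#' Corpus aggregate of per-record MAEs
#'
#' @param evaluations list of `hr_evaluation` objects (one per record).
#' @return list with `mae_mean`, `mae_sd`, `n_records`.
#' @export
summarize_evaluations <- function(evaluations) {
  maes <- vapply(evaluations, function(e) e$mae, numeric(1))
  maes <- maes[!is.na(maes)]
  list(mae_mean = mean(maes), mae_sd = stats::sd(maes),
       n_records = length(maes))
}

#' Filter, detect and score one PPG channel
#'
#' Convenience composition of the evaluation stage: band-pass filter the
#' signal, detect peaks, and score the sliding-window heart-rate MAE
#' against the ground-truth peak train.
#'
#' @param x numeric PPG signal (raw or conditioned).
#' @param sampling_rate samples per second.
#' @param truth ground-truth `peak_annotation`.
#' @param ... passed to [evaluate_mae()].
#' @return an `hr_evaluation`.
#' @export
evaluate_ppg_hr <- function(x, sampling_rate, truth, ...) {
  filt <- zero_phase_bandpass(x, sampling_rate)
  est <- detect_peaks(filt, sampling_rate)
  evaluate_mae(est, truth, duration = length(x) / sampling_rate, ...)
}
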