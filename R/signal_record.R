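#' Multichannel wearable-sensor record
#'
#' A `signal_record` holds one uniformly sampled capture from a wrist-worn
#' device: the photoplethysmography (PPG) channel plus the three accelerometer
#' axes, optionally accompanied by a clean target PPG waveform used for
#' supervised training.
#'
#' @param ppg numeric vector, raw PPG channel.
#' @param acc_x,acc_y,acc_z numeric vectors, accelerometer axes (same length
#'   as `ppg`; units arbitrary, typically normalized).
#' @param sampling_rate samples per second, default 32.
#' @param target optional numeric vector, clean reference PPG (same length).
#' @param record_id character identifier.
#' @param norm_params optional named list of per-channel `c(offset, scale)`
#'   pairs written by [normalize_record()].
#'
#' @return An object of class `signal_record`.
#' @seealso [read_record()], [normalize_record()]
#' @export
signal_record <- function(ppg, acc_x, acc_y, acc_z, sampling_rate = 32,
                          target = NULL, record_id = "record",
                          norm_params = NULL) {
  rec <- structure(
    list(ppg = as.numeric(ppg), acc_x = as.numeric(acc_x),
         acc_y = as.numeric(acc_y), acc_z = as.numeric(acc_z),
         target = if (is.null(target)) NULL else as.numeric(target),
         sampling_rate = sampling_rate, record_id = as.character(record_id),
         norm_params = norm_params, rejected = FALSE),
    class = "signal_record")
  validate_record(rec)
  rec
}

#' Channels present in a record
#' @param record a `signal_record`.
#' @return character vector of channel names (includes `"target"` when set).
#' @export
record_channels <- function(record) {
  ch <- c("ppg", "acc_x", "acc_y", "acc_z")
  if (!is.null(record$target)) ch <- c(ch, "target")
  ch
}

#' Validate a signal record
#'
#' Checks the structural invariants: all present channels share one length of
#' at least 2, and the sampling rate is positive.
#'
#' @param record a `signal_record`.
#' @return the record, invisibly. Errors on violation.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  lens <- vapply(record_channels(record), function(ch) length(record[[ch]]),
                 integer(1))
  if (length(unique(lens)) != 1L)
    stop("signal_record channels have differing lengths: ",
         paste(sprintf("%s=%d", names(lens), lens), collapse = ", "))
  if (lens[[1]] < 2L)
    stop("signal_record channels must have length >= 2, got ", lens[[1]])
  if (!is.numeric(record$sampling_rate) || record$sampling_rate <= 0)
    stop("sampling_rate must be positive")
  for (ch in record_channels(record))
    if (anyNA(record[[ch]])) stop("channel '", ch, "' contains NA")
  invisible(record)
}

#' @export
print.signal_record <- function(x, ...) {
  n <- length(x$ppg)
  cat(sprintf("<signal_record '%s': %d samples @ %g Hz (%.1f s)%s%s%s>\n",
              x$record_id, n, x$sampling_rate, n / x$sampling_rate,
              if (!is.null(x$target)) ", with target" else "",
              if (!is.null(x$norm_params)) ", normalized" else "",
              if (isTRUE(x$rejected)) ", REJECTED" else ""))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$ppg)

#' Ordered peak annotation with clean-window boundaries
#'
#' Peak times of a PPG record together with the boundaries of the two
#' movement-free intervals: Time Window A at the head of the record (ends at
#' `window_a_end`) and Time Window B at the tail (starts at
#' `window_b_start`). The windows anchor the interval extrapolation used to
#' rebuild the target waveform through the motion-corrupted middle segment.
#' Peak trains produced by a detector carry `NA` windows; window invariants
#' are only enforced when both boundaries are given.
#'
#' @param peak_times strictly increasing numeric vector, seconds.
#' @param window_a_end,window_b_start window boundaries in seconds, or `NA`.
#' @return An object of class `peak_annotation`.
#' @export
peak_annotation <- function(peak_times, window_a_end = NA_real_,
                            window_b_start = NA_real_) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) > 1 && any(diff(peak_times) <= 0))
    stop("peak_times must be strictly increasing")
  ann <- structure(list(peak_times = peak_times,
                        window_a_end = as.numeric(window_a_end),
                        window_b_start = as.numeric(window_b_start)),
                   class = "peak_annotation")
  if (!is.na(ann$window_a_end) && !is.na(ann$window_b_start)) {
    if (ann$window_a_end >= ann$window_b_start)
      stop("window_a_end must be < window_b_start")
    if (sum(peak_times <= ann$window_a_end) < 2L)
      stop("need >= 2 peaks in Time Window A")
    if (sum(peak_times >= ann$window_b_start) < 2L)
      stop("need >= 2 peaks in Time Window B")
  }
  ann
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("<peak_annotation: %d peaks%s>\n", length(x$peak_times),
              if (!is.na(x$window_a_end))
                sprintf(", window A ends %.2f s, window B starts %.2f s",
                        x$window_a_end, x$window_b_start) else ""))
  invisible(x)
}

record_csv_columns <- c("t", "ppg", "acc_x", "acc_y", "acc_z")

#' Read a record from CSV
#'
#' The dialect is a plain CSV with header `t,ppg,acc_x,acc_y,acc_z[,target]`,
#' one row per sample, `t` in seconds ascending at a fixed step. The sampling
#' rate is recovered from the time column.
#'
#' @param path path to the CSV file.
#' @param record_id identifier; defaults to the file name without extension.
#' @return a validated [signal_record()].
#' @export
read_record <- function(path, record_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = ",", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) != 1L)
    stop("ragged CSV '", path, "': line ",
         which(nf != nf[1])[1], " has ", nf[which(nf != nf[1])[1]],
         " fields, expected ", nf[1])
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)
  if (length(cols) < 5L || !identical(cols[1:5], record_csv_columns))
    stop("malformed header in '", path, "': expected '",
         paste(record_csv_columns, collapse = ","), "[,target]', got '",
         paste(cols, collapse = ","), "'")
  extra <- setdiff(cols, c(record_csv_columns, "target"))
  if (length(extra))
    stop("unexpected columns in '", path, "': ", paste(extra, collapse = ", "))
  dt <- diff(df$t)
  if (any(dt <= 0))
    stop("non-monotone time column in '", path, "' at line ",
         which(dt <= 0)[1] + 2L)  # +1 header, +1 diff offset
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("time column in '", path, "' is not a fixed step")
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(path))
  signal_record(ppg = df$ppg, acc_x = df$acc_x, acc_y = df$acc_y,
                acc_z = df$acc_z, sampling_rate = 1 / stats::median(dt),
                target = if ("target" %in% cols) df$target else NULL,
                record_id = record_id)
}

#' Write a record to CSV
#'
#' Inverse of [read_record()]: round-tripping reproduces the record to
#' numeric round-off.
#'
#' @param record a valid `signal_record`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  validate_record(record)
  n <- length(record$ppg)
  df <- data.frame(t = (seq_len(n) - 1) / record$sampling_rate,
                   ppg = record$ppg, acc_x = record$acc_x,
                   acc_y = record$acc_y, acc_z = record$acc_z)
  if (!is.null(record$target)) df$target <- record$target
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write peak annotations
#'
#' Annotations travel as a CSV with a single `peak_time` column plus a JSON
#' sidecar (same path with extension `.windows.json`) holding the keys
#' `window_a_end` and `window_b_start`.
#'
#' @param path path of the peak CSV.
#' @param annotation a `peak_annotation`.
#' @return `read_annotation` returns a [peak_annotation()];
#'   `write_annotation` returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), "peak_time"))
    stop("annotation CSV must have the single column 'peak_time'")
  side <- annotation_sidecar_path(path)
  wa <- NA_real_; wb <- NA_real_
  if (file.exists(side)) {
    w <- jsonlite::read_json(side, simplifyVector = TRUE)
    wa <- as.numeric(w$window_a_end); wb <- as.numeric(w$window_b_start)
  }
  peak_annotation(df$peak_time, wa, wb)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  utils::write.csv(data.frame(peak_time = annotation$peak_times), path,
                   row.names = FALSE, quote = FALSE)
  if (!is.na(annotation$window_a_end))
    jsonlite::write_json(list(window_a_end = annotation$window_a_end,
                              window_b_start = annotation$window_b_start),
                         annotation_sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

annotation_sidecar_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".windows.json")

#' Normalize a record channel-wise to [-1, 1]
#'
#' Each channel (including the target, when present) is mapped affinely so
#' its minimum becomes -1 and its maximum +1. The per-channel
#' `(offset, scale)` with `x' = (x - offset) / scale` is stored in
#' `norm_params`, making the mapping invertible via [denormalize_record()].
#' A constant channel maps to all zeros with its scale recorded as 0.
#' Applying the function twice is a no-op (up to round-off) on channels that
#' already span the full range.
#'
#' @param record a valid `signal_record`.
#' @return the normalized record.
#' @export
normalize_record <- function(record) {
  validate_record(record)
  params <- list()
  for (ch in record_channels(record)) {
    x <- record[[ch]]
    mn <- min(x); mx <- max(x)
    offset <- (mn + mx) / 2
    scale <- (mx - mn) / 2
    record[[ch]] <- if (scale == 0) rep(0, length(x)) else (x - offset) / scale
    params[[ch]] <- c(offset = offset, scale = scale)
  }
  record$norm_params <- params
  record
}

#' @rdname normalize_record
#' @export
denormalize_record <- function(record) {
  if (is.null(record$norm_params)) stop("record carries no norm_params")
  for (ch in record_channels(record)) {
    p <- record$norm_params[[ch]]
    if (is.null(p)) next
    record[[ch]] <- record[[ch]] * p[["scale"]] + p[["offset"]]
  }
  record$norm_params <- NULL
  record
}

is_normalized <- function(record) {
  all(vapply(record_channels(record), function(ch) {
    r <- range(record[[ch]])
    r[1] >= -1 - 1e-9 && r[2] <= 1 + 1e-9
  }, logical(1)))
}
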