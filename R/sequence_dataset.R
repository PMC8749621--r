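#' Segmented training sequences
#'
#' A `sequence_dataset` is the 3-D training array cut from normalized
#' records: `num_sequences x L x 4` with the features in the fixed order
#' `ppg, acc_x, acc_y, acc_z`, paired with one scalar target per sequence.
#' Each sequence takes every `S`-th sample and predicts the clean PPG value
#' at its own last (most recent) sample — the causal alignment a real-time
#' conditioner needs. Provenance (`record_id`, end-sample index) is kept per
#' sequence so evaluation losses can be averaged per signal.
#'
#' @name sequence_dataset
NULL

dataset_features <- c("ppg", "acc_x", "acc_y", "acc_z")

new_sequence_dataset <- function(sequences, targets, L, S, hop, provenance) {
  structure(list(sequences = sequences, targets = targets,
                 L = as.integer(L), S = as.integer(S), hop = as.integer(hop),
                 feature_names = dataset_features, provenance = provenance),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("<sequence_dataset: %d sequences, L=%d, S=%d, hop=%d, %d records>\n",
              nrow(x$sequences), x$L, x$S, x$hop,
              length(unique(x$provenance$record_id))))
  invisible(x)
}

#' Number of sequences a record yields
#'
#' Closed form for the hop-stepped count of admissible end samples: a
#' sequence of `L` samples strided by `S` spans `(L-1)*S + 1` samples, so
#' `floor((len - 1 - (L-1)*S) / hop) + 1` sequences fit (0 when the record is
#' shorter than one span).
#'
#' @param len record length in samples.
#' @param L sequence length (timesteps).
#' @param S inter-sample stride in samples.
#' @param hop step between consecutive end samples.
#' @return integer count.
#' @export
n_sequences <- function(len, L, S, hop = 1L) {
  span <- (L - 1L) * S + 1L
  if (len < span) return(0L)
  as.integer((len - span) %/% hop + 1L)
}

#' Segment a normalized record into training sequences
#'
#' For each admissible end sample `e` (the first is `(L-1)*S + 1`, then
#' stepped by `hop`), the sequence takes the samples at
#' `e - (L-1)S, e - (L-2)S, ..., e` from the four input channels; the paired
#' target is the record's target at `e`. Sequences are time-ordered.
#'
#' @param record a normalized `signal_record` with a target.
#' @param L sequence length in timesteps.
#' @param S inter-sample stride in samples.
#' @param hop step between consecutive sequences (default 1).
#' @return a `sequence_dataset`; empty (with a warning) when the record is
#'   shorter than one span.
#' @export
segment_record <- function(record, L, S, hop = 1L) {
  validate_record(record)
  if (is.null(record$target)) stop("record has no target")
  if (!is_normalized(record))
    stop("record must be normalized (all channels within [-1, 1])")
  L <- as.integer(L); S <- as.integer(S); hop <- as.integer(hop)
  stopifnot(L >= 1L, S >= 1L, hop >= 1L)
  len <- length(record$ppg)
  m <- n_sequences(len, L, S, hop)
  if (m == 0L) {
    warning(sprintf("record '%s' (%d samples) shorter than one span (%d); empty dataset",
                    record$record_id, len, (L - 1L) * S + 1L))
    return(new_sequence_dataset(
      array(numeric(0), dim = c(0L, L, 4L),
            dimnames = list(NULL, NULL, dataset_features)),
      numeric(0), L, S, hop,
      data.frame(record_id = character(0), end_index = integer(0))))
  }
  ends <- seq.int((L - 1L) * S + 1L, len, by = hop)
  idx <- outer(ends, rev(seq_len(L) - 1L) * S, `-`)  # m x L sample indices
  arr <- array(NA_real_, dim = c(m, L, 4L),
               dimnames = list(NULL, NULL, dataset_features))
  for (f in seq_along(dataset_features))
    arr[, , f] <- record[[dataset_features[f]]][idx]
  new_sequence_dataset(arr, record$target[ends], L, S, hop,
                       data.frame(record_id = record$record_id,
                                  end_index = ends))
}

#' Merge sequence datasets
#'
#' Concatenates datasets cut with identical `L` and `S` (typically one per
#' record), preserving provenance.
#'
#' @param parts list of `sequence_dataset` objects.
#' @return one `sequence_dataset`.
#' @export
merge_datasets <- function(parts) {
  stopifnot(length(parts) >= 1L)
  L <- parts[[1]]$L; S <- parts[[1]]$S
  for (p in parts)
    if (p$L != L || p$S != S)
      stop("cannot merge datasets with differing L or S")
  if (length(parts) == 1L) return(parts[[1]])
  m <- sum(vapply(parts, function(p) nrow(p$sequences), integer(1)))
  arr <- array(NA_real_, dim = c(m, L, 4L),
               dimnames = list(NULL, NULL, dataset_features))
  at <- 0L
  for (p in parts) {
    k <- nrow(p$sequences)
    if (k > 0L) arr[at + seq_len(k), , ] <- p$sequences
    at <- at + k
  }
  hops <- unique(vapply(parts, `[[`, integer(1), "hop"))
  new_sequence_dataset(arr,
                       unlist(lapply(parts, `[[`, "targets")),
                       L, S, if (length(hops) == 1L) hops else NA_integer_,
                       do.call(rbind, lapply(parts, `[[`, "provenance")))
}

#' Split records into training and evaluation sets
#'
#' Deterministic seeded shuffle at the record level (never at the sequence
#' level, which would leak information between the sets).
#'
#' @param records a list (of records, or of anything record-shaped).
#' @param n_train number of training records; must be < `length(records)`.
#' @param seed integer seed.
#' @return list with elements `train` and `eval`.
#' @export
split_train_eval <- function(records, n_train, seed = 1L) {
  if (n_train >= length(records))
    stop("n_train must be smaller than the number of records")
  if (n_train < 1L) stop("n_train must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  perm <- sample.int(length(records))
  list(train = records[perm[seq_len(n_train)]],
       eval = records[perm[(n_train + 1L):length(records)]])
}
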