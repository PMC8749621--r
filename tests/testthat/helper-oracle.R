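# Scalar-arithmetic reference implementation of one LSTM cell step,
# instrumented to count every basic operation (add, subtract, multiply,
# divide, exp). Sigmoid is evaluated literally as 1/(1 + e^-x) (one negation
# counted as a subtract, one exp, one add, one divide); tanh literally as
# (e^x - e^-x)/(e^x + e^-x) (one negation, two exp, one subtract, one add,
# one divide). Weight layout matches the package: column blocks ordered
# (input, forget, candidate, output).
lstm_scalar_step <- function(Wx, Wh, b, x, h_prev, c_prev) {
  d <- length(x); h <- length(h_prev)
  counts <- c(add = 0, subtract = 0, multiply = 0, divide = 0, exp = 0)
  bump <- function(op, k = 1) counts[op] <<- counts[op] + k
  sig <- function(v) {
    bump("subtract"); bump("exp"); bump("add"); bump("divide")
    1 / (1 + exp(-v))
  }
  th <- function(v) {
    bump("subtract"); bump("exp", 2); bump("subtract"); bump("add")
    bump("divide")
    (exp(v) - exp(-v)) / (exp(v) + exp(-v))
  }
  # pre-activation of one gate block (columns cols): W'x + U'h + b
  pre <- function(cols) {
    vapply(cols, function(ci) {
      acc_x <- Wx[1, ci] * x[1]; bump("multiply")
      for (j in seq_len(d)[-1]) {
        acc_x <- acc_x + Wx[j, ci] * x[j]; bump("multiply"); bump("add")
      }
      acc_h <- Wh[1, ci] * h_prev[1]; bump("multiply")
      for (j in seq_len(h)[-1]) {
        acc_h <- acc_h + Wh[j, ci] * h_prev[j]; bump("multiply"); bump("add")
      }
      z <- acc_x + acc_h; bump("add")
      z <- z + b[ci]; bump("add")
      z
    }, numeric(1))
  }
  zi <- pre(seq_len(h))
  zf <- pre(h + seq_len(h))
  zg <- pre(2 * h + seq_len(h))
  zo <- pre(3 * h + seq_len(h))
  I <- vapply(zi, sig, numeric(1))
  F <- vapply(zf, sig, numeric(1))
  G <- vapply(zg, th, numeric(1))
  O <- vapply(zo, sig, numeric(1))
  C <- numeric(h); H <- numeric(h)
  for (i in seq_len(h)) {
    C[i] <- F[i] * c_prev[i] + I[i] * G[i]
    bump("multiply", 2); bump("add")
    tc <- th(C[i])
    H[i] <- O[i] * tc; bump("multiply")
  }
  list(counts = counts, I = I, F = F, G = G, O = O, C = C, H = H)
}

# Brute-force enumerator of admissible sequence end samples.
enumerate_ends <- function(len, L, S, hop) {
  ends <- integer(0)
  e <- (L - 1L) * S + 1L
  while (e <= len) {
    ends <- c(ends, e)
    e <- e + hop
  }
  ends
}

# A small valid record with distinct channel contents.
toy_record <- function(n = 64, fs = 32, with_target = TRUE) {
  t <- (seq_len(n) - 1) / fs
  signal_record(ppg = sin(2 * pi * t), acc_x = cos(2 * pi * 0.7 * t),
                acc_y = 0.5 * sin(2 * pi * 1.3 * t + 1),
                acc_z = seq(-1, 1, length.out = n),
                sampling_rate = fs,
                target = if (with_target) 0.8 * sin(2 * pi * t) else NULL,
                record_id = "toy")
}

# Normalized synthetic records (record + annotation) ready for segmentation.
prep_synth <- function(entries) {
  lapply(entries, function(e) {
    e$record <- normalize_record(e$record)
    e
  })
}
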