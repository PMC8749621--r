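#' Hyperparameter configuration of the conditioning network
#'
#' The conditioning network takes sequences of `L` timesteps of the 4
#' features (ppg, acc_x, acc_y, acc_z), strided by `S` samples, through
#' `N_l` recurrent long short-term memory layers of `N_h` cells each, and a
#' final linear fully connected unit producing one predicted clean-PPG value
#' per sequence.
#'
#' @param L sequence length in timesteps.
#' @param S inter-sample stride in samples (affects data preparation, not
#'   the network itself).
#' @param N_h cells per hidden layer.
#' @param N_l number of hidden recurrent layers, 1 or 2.
#' @param epochs training epochs (default 60).
#' @param seed integer seed driving weight initialization and batch
#'   shuffling.
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param grid_mode when TRUE, additionally restricts `L`, `S` and `N_h` to
#'   the grid-search value lists (see [grid_variants()]).
#' @return an object of class `lstm_config`.
#' @export
lstm_config <- function(L, S, N_h = 8L, N_l = 1L, epochs = 60L, seed = 1L,
                        batch_size = 32L, learning_rate = 1e-3,
                        grid_mode = FALSE) {
  L <- as.integer(L); S <- as.integer(S)
  N_h <- as.integer(N_h); N_l <- as.integer(N_l)
  stopifnot(L >= 1L, S >= 1L, N_h >= 1L, epochs >= 0L, batch_size >= 1L,
            learning_rate > 0)
  if (!N_l %in% c(1L, 2L))
    stop("N_l must be 1 or 2 (deeper stacks showed no benefit)")
  if (grid_mode) {
    if (!L %in% grid_values$L) stop("grid mode: L must be one of ",
                                    paste(grid_values$L, collapse = ", "))
    if (!S %in% grid_values$S) stop("grid mode: S must be one of ",
                                    paste(grid_values$S, collapse = ", "))
    if (!N_h %in% grid_values$N_h) stop("grid mode: N_h must be one of ",
                                        paste(grid_values$N_h, collapse = ", "))
  }
  structure(list(L = L, S = S, N_h = N_h, N_l = N_l,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer = "adam", loss = "mae"),
            class = "lstm_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform matrix, column blocks ordered (input, forget, candidate,
# output) for the gate kernels.
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_weights <- function(config) {
  h <- config$N_h
  layers <- lapply(seq_len(config$N_l), function(l) {
    d <- if (l == 1L) 4L else h
    b <- numeric(4L * h)
    b[h + seq_len(h)] <- 1            # forget-gate bias starts open
    list(Wx = glorot(d, 4L * h), Wh = glorot(h, 4L * h), b = b)
  })
  list(layers = layers,
       dense = list(w = as.numeric(glorot(h, 1L)), b = 0))
}

#' Construct a (possibly untrained) conditioning network
#'
#' Initializes the network weights from the configuration's seed: Glorot
#' uniform kernels, zero biases with the forget-gate bias set to 1. Use
#' [lstm_train()] (or the one-call [ppg_lstm()]) to fit it.
#'
#' @param config an [lstm_config()].
#' @return an object of class `ppg_lstm` with empty training history.
#' @export
lstm_init <- function(config) {
  stopifnot(inherits(config, "lstm_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  structure(list(config = config, weights = init_weights(config),
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      eval_loss = numeric(0)),
                 eval_loss_best = NA_real_, trained = FALSE,
                 feature_names = dataset_features),
            class = "ppg_lstm")
}

#' Number of trainable parameters
#'
#' For one layer of `h` cells on `d` inputs: `4 (h d + h^2 + h)` gate
#' parameters; the linear output adds `h + 1`.
#'
#' @param object a `ppg_lstm` model.
#' @return integer parameter count.
#' @export
n_params <- function(object) {
  stopifnot(inherits(object, "ppg_lstm"))
  sum(vapply(object$weights$layers, function(ly)
    length(ly$Wx) + length(ly$Wh) + length(ly$b), numeric(1))) +
    length(object$weights$dense$w) + 1L
}

# Batched forward pass. X: array B x L x 4. Returns predictions and, when
# cache = TRUE, the per-layer per-timestep quantities needed by BPTT.
lstm_forward <- function(weights, X, cache = FALSE) {
  B <- dim(X)[1]; L <- dim(X)[2]
  n_layers <- length(weights$layers)
  caches <- if (cache) vector("list", n_layers)
  # inputs to the current layer, list of B x d matrices per timestep
  inputs <- lapply(seq_len(L), function(t) matrix(X[, t, ], nrow = B))
  for (l in seq_len(n_layers)) {
    ly <- weights$layers[[l]]
    h <- ncol(ly$Wh)/4L
    H <- matrix(0, B, h); C <- matrix(0, B, h)
    steps <- if (cache) vector("list", L)
    outs <- vector("list", L)
    for (t in seq_len(L)) {
      Z <- inputs[[t]] %*% ly$Wx + H %*% ly$Wh
      Z <- Z + rep(ly$b, each = B)
      I <- sigmoid(Z[, seq_len(h), drop = FALSE])
      F <- sigmoid(Z[, h + seq_len(h), drop = FALSE])
      G <- tanh(Z[, 2L * h + seq_len(h), drop = FALSE])
      O <- sigmoid(Z[, 3L * h + seq_len(h), drop = FALSE])
      C_prev <- C
      C <- F * C + I * G
      Ct <- tanh(C)
      H_prev <- H
      H <- O * Ct
      if (cache)
        steps[[t]] <- list(x = inputs[[t]], I = I, F = F, G = G, O = O,
                           C_prev = C_prev, Ct = Ct, H_prev = H_prev)
      outs[[t]] <- H
    }
    if (cache) caches[[l]] <- steps
    inputs <- outs
  }
  H_last <- inputs[[L]]
  pred <- as.numeric(H_last %*% weights$dense$w) + weights$dense$b
  list(pred = pred, H_last = H_last, caches = caches)
}

# Backpropagation through time. dy: gradient of the loss w.r.t. each
# prediction. Returns gradients with the same shape as the weights.
lstm_backward <- function(weights, fwd, dy) {
  n_layers <- length(weights$layers)
  L <- length(fwd$caches[[1]])
  B <- length(dy)
  grads <- list(layers = vector("list", n_layers),
                dense = list(w = as.numeric(t(fwd$H_last) %*% dy),
                             b = sum(dy)))
  # gradient flowing into each layer's hidden output at each timestep
  dH_in <- vector("list", L)
  dH_in[[L]] <- outer(dy, weights$dense$w)
  for (l in rev(seq_len(n_layers))) {
    ly <- weights$layers[[l]]
    steps <- fwd$caches[[l]]
    h <- ncol(ly$Wh)/4L
    gWx <- matrix(0, nrow(ly$Wx), 4L * h)
    gWh <- matrix(0, h, 4L * h)
    gb <- numeric(4L * h)
    dH_rec <- matrix(0, B, h); dC <- matrix(0, B, h)
    dX <- if (l > 1L) vector("list", L)
    for (t in rev(seq_len(L))) {
      st <- steps[[t]]
      dH <- dH_rec
      if (!is.null(dH_in[[t]])) dH <- dH + dH_in[[t]]
      dO <- dH * st$Ct
      dC <- dC + dH * st$O * (1 - st$Ct^2)
      dF <- dC * st$C_prev
      dI <- dC * st$G
      dG <- dC * st$I
      dZ <- cbind(dI * st$I * (1 - st$I),
                  dF * st$F * (1 - st$F),
                  dG * (1 - st$G^2),
                  dO * st$O * (1 - st$O))
      gWx <- gWx + crossprod(st$x, dZ)
      gWh <- gWh + crossprod(st$H_prev, dZ)
      gb <- gb + colSums(dZ)
      dH_rec <- dZ %*% t(ly$Wh)
      dC <- dC * st$F
      if (l > 1L) dX[[t]] <- dZ %*% t(ly$Wx)
    }
    grads$layers[[l]] <- list(Wx = gWx, Wh = gWh, b = gb)
    if (l > 1L) dH_in <- dX
  }
  grads
}

adam_init <- function(weights) {
  zero_like <- function(w) rapply(w, function(x) x * 0, how = "replace")
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  for (l in seq_along(weights$layers)) {
    for (nm in c("Wx", "Wh", "b")) {
      r <- upd(weights$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      weights$layers[[l]][[nm]] <- r$w
      state$m$layers[[l]][[nm]] <- r$m
      state$v$layers[[l]][[nm]] <- r$v
    }
  }
  for (nm in c("w", "b")) {
    r <- upd(weights$dense[[nm]], grads$dense[[nm]],
             state$m$dense[[nm]], state$v$dense[[nm]])
    weights$dense[[nm]] <- r$w
    state$m$dense[[nm]] <- r$m
    state$v$dense[[nm]] <- r$v
  }
  list(weights = weights, state = state)
}

# Mean absolute error per record (provenance groups), then averaged across
# records — the per-signal evaluation average.
per_signal_mae <- function(pred, ds) {
  err <- abs(pred - ds$targets)
  mean(tapply(err, ds$provenance$record_id, mean))
}

predict_dataset <- function(weights, ds, chunk = 4096L) {
  m <- nrow(ds$sequences)
  if (m == 0L) return(numeric(0))
  out <- numeric(m)
  at <- 1L
  while (at <= m) {
    hi <- min(at + chunk - 1L, m)
    out[at:hi] <- lstm_forward(weights,
                               ds$sequences[at:hi, , , drop = FALSE])$pred
    at <- hi + 1L
  }
  out
}

#' Train the conditioning network
#'
#' Minibatch training with the Adam optimizer on the mean-absolute-error
#' loss. After every epoch the evaluation loss is computed as the
#' per-signal average of the per-sequence absolute errors over the
#' evaluation set; the weights achieving the best (lowest) evaluation loss
#' are the ones retained in the returned model. With `epochs = 0` the model
#' is returned untrained with an empty history. Training is deterministic
#' for a fixed seed and data (single-threaded execution).
#'
#' @param model a `ppg_lstm` from [lstm_init()].
#' @param train_ds training `sequence_dataset` (same `L` as the model).
#' @param eval_ds optional evaluation `sequence_dataset`; when absent the
#'   training loss is used for best-weight tracking.
#' @param epochs override of `model$config$epochs`.
#' @param verbose print per-epoch losses.
#' @return the trained `ppg_lstm` with `history` and `eval_loss_best` set.
#' @export
lstm_train <- function(model, train_ds, eval_ds = NULL,
                       epochs = model$config$epochs, verbose = FALSE) {
  stopifnot(inherits(model, "ppg_lstm"), inherits(train_ds, "sequence_dataset"))
  cfg <- model$config
  if (train_ds$L != cfg$L)
    stop("dataset L (", train_ds$L, ") differs from model L (", cfg$L, ")")
  m <- nrow(train_ds$sequences)
  if (m == 0L) stop("empty training dataset")
  if (!is.null(eval_ds) && nrow(eval_ds$sequences) == 0L)
    stop("empty evaluation dataset")
  if (epochs == 0L) return(model)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed + 1L)

  weights <- model$weights
  state <- adam_init(weights)
  best <- Inf; best_weights <- weights
  hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                     eval_loss = NA_real_)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(m)
    total <- 0
    at <- 1L
    while (at <= m) {
      idx <- perm[at:min(at + cfg$batch_size - 1L, m)]
      X <- train_ds$sequences[idx, , , drop = FALSE]
      y <- train_ds$targets[idx]
      fwd <- lstm_forward(weights, X, cache = TRUE)
      res <- fwd$pred - y
      total <- total + sum(abs(res))
      dy <- sign(res) / length(idx)
      grads <- lstm_backward(weights, fwd, dy)
      st <- adam_step(weights, grads, state, cfg$learning_rate)
      weights <- st$weights; state <- st$state
      at <- at + cfg$batch_size
    }
    hist$train_loss[ep] <- total / m
    score <- if (!is.null(eval_ds))
      per_signal_mae(predict_dataset(weights, eval_ds), eval_ds)
    else hist$train_loss[ep]
    if (!is.null(eval_ds)) hist$eval_loss[ep] <- score
    if (score < best) { best <- score; best_weights <- weights }
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  eval %s", ep,
                      hist$train_loss[ep],
                      if (!is.null(eval_ds)) sprintf("%.5f", score) else "-"))
  }
  model$weights <- best_weights
  model$history <- hist
  model$eval_loss_best <- if (!is.null(eval_ds)) best else NA_real_
  model$trained <- TRUE
  model
}

#' Fit a PPG conditioning network
#'
#' One-call interface: initializes the network from `config` and trains it
#' on `train_ds`, tracking the per-signal evaluation loss on `eval_ds`.
#'
#' @param train_ds training `sequence_dataset`.
#' @param eval_ds optional evaluation `sequence_dataset`.
#' @param config an [lstm_config()]; its `L` must match the datasets.
#' @param verbose print per-epoch losses.
#' @return a fitted `ppg_lstm` model.
#' @export
ppg_lstm <- function(train_ds, eval_ds = NULL, config, verbose = FALSE) {
  lstm_train(lstm_init(config), train_ds, eval_ds, verbose = verbose)
}

#' Condition a record with a trained network
#'
#' Runs hop-1 segmentation over the (normalized) record and predicts one
#' clean-PPG value per end sample, yielding a conditioned PPG of the same
#' length as the input. The first `(L-1)*S` samples, which lack a full
#' history, are served by left-padding the record with its first sample's
#' values. Predictions are clipped to `[-1, 1]`.
#'
#' @param model a `ppg_lstm`.
#' @param record a normalized `signal_record`.
#' @return the record with its `ppg` channel replaced by the conditioned
#'   signal.
#' @export
condition_signal <- function(model, record) {
  stopifnot(inherits(model, "ppg_lstm"))
  validate_record(record)
  if (!is_normalized(record))
    stop("record must be normalized before conditioning")
  cfg <- model$config
  span <- (cfg$L - 1L) * cfg$S
  n <- length(record$ppg)
  if (n < 1L) stop("record shorter than one span")
  padded <- record
  for (ch in c("ppg", "acc_x", "acc_y", "acc_z"))
    padded[[ch]] <- c(rep(record[[ch]][1], span), record[[ch]])
  padded$target <- c(rep(if (is.null(record$target)) 0 else record$target[1],
                         span),
                     if (is.null(record$target)) numeric(n) else record$target)
  ds <- segment_record(padded, cfg$L, cfg$S, hop = 1L)
  pred <- predict_dataset(model$weights, ds)
  record$ppg <- pmin(1, pmax(-1, pred))
  record
}

#' @export
predict.ppg_lstm <- function(object, newdata, ...) {
  if (inherits(newdata, "sequence_dataset")) {
    if (newdata$L != object$config$L)
      stop("dataset L differs from model L")
    predict_dataset(object$weights, newdata)
  } else if (inherits(newdata, "signal_record")) {
    condition_signal(object, newdata)
  } else stop("newdata must be a sequence_dataset or a signal_record")
}

#' @export
print.ppg_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ppg_lstm: L=%d S=%d N_h=%d N_l=%d, %d parameters, %s%s>\n",
              cfg$L, cfg$S, cfg$N_h, cfg$N_l, n_params(x),
              if (x$trained) sprintf("trained %d epochs", nrow(x$history))
              else "untrained",
              if (!is.na(x$eval_loss_best))
                sprintf(", best eval MAE %.4f", x$eval_loss_best) else ""))
  invisible(x)
}

#' @export
summary.ppg_lstm <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("Training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ppg_lstm <- function(object, ...) object$weights

#' @export
plot.ppg_lstm <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("model has no training history")
  ylim <- range(c(h$train_loss, h$eval_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", ylim = ylim,
                 xlab = "epoch", ylab = "MAE loss", ...)
  if (any(!is.na(h$eval_loss))) {
    graphics::lines(h$epoch, h$eval_loss, lty = 2)
    graphics::legend("topright", c("train", "eval"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Save / load a fitted model
#'
#' The weights and history are serialized with `saveRDS`; the configuration
#' is additionally written to a JSON sidecar (`<path>.json`) for inspection.
#'
#' @param model a `ppg_lstm`.
#' @param path destination path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ppg_lstm"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ppg_lstm"))
  model
}
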