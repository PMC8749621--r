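test_that("parameter count matches the closed form", {
  m <- lstm_init(lstm_config(L = 4, S = 1, N_h = 4, N_l = 1))
  expect_equal(n_params(m), 4 * (4 * 4 + 4^2 + 4) + 4 + 1)   # 149
  m2 <- lstm_init(lstm_config(L = 4, S = 1, N_h = 8, N_l = 2))
  # second layer consumes the first layer's hidden width
  expect_equal(nrow(m2$weights$layers[[2]]$Wx), 8)
  expect_equal(n_params(m2),
               4 * (8 * 4 + 64 + 8) + 4 * (8 * 8 + 64 + 8) + 8 + 1)
})

test_that("configurations outside the supported ranges are rejected", {
  expect_error(lstm_config(L = 4, S = 1, N_l = 3), "N_l")
  expect_error(lstm_config(L = 5, S = 1, grid_mode = TRUE), "grid mode: L")
  expect_error(lstm_config(L = 4, S = 3, grid_mode = TRUE), "grid mode: S")
  expect_error(lstm_config(L = 4, S = 1, N_h = 5, grid_mode = TRUE),
               "grid mode: N_h")
  expect_s3_class(lstm_config(L = 4, S = 1, N_h = 32, grid_mode = TRUE),
                  "lstm_config")
})

test_that("the cell recurrence matches a scalar reference implementation", {
  set.seed(20)
  for (h in c(1L, 3L)) {
    cfg <- lstm_config(L = 3, S = 1, N_h = h, N_l = 1, seed = 20)
    w <- lstm_init(cfg)$weights$layers[[1]]
    X <- array(rnorm(1 * 3 * 4), c(1, 3, 4))
    fwd <- ppgcond:::lstm_forward(list(layers = list(w),
                                       dense = list(w = rep(0, h), b = 0)),
                                  X, cache = TRUE)
    h_prev <- numeric(h); c_prev <- numeric(h)
    for (t in 1:3) {
      ref <- lstm_scalar_step(w$Wx, w$Wh, w$b, X[1, t, ], h_prev, c_prev)
      st <- fwd$caches[[1]][[t]]
      expect_equal(as.numeric(st$I), ref$I, tolerance = 1e-12)
      expect_equal(as.numeric(st$F), ref$F, tolerance = 1e-12)
      expect_equal(as.numeric(st$G), ref$G, tolerance = 1e-12)
      expect_equal(as.numeric(st$O), ref$O, tolerance = 1e-12)
      expect_equal(as.numeric(st$O * st$Ct), ref$H, tolerance = 1e-12)
      # gate and state codomains
      expect_true(all(ref$I > 0 & ref$I < 1))
      expect_true(all(ref$F > 0 & ref$F < 1))
      expect_true(all(ref$O > 0 & ref$O < 1))
      expect_true(all(abs(ref$G) < 1))
      expect_true(all(abs(ref$H) < 1))
      h_prev <- ref$H; c_prev <- ref$C
    }
  }
})

test_that("backpropagation matches finite differences", {
  cfg <- lstm_config(L = 3, S = 1, N_h = 4, N_l = 2, seed = 9)
  m <- lstm_init(cfg); w <- m$weights
  set.seed(1)
  X <- array(rnorm(4 * 3 * 4), c(4, 3, 4)); y <- rnorm(4)
  loss <- function(w) mean(abs(ppgcond:::lstm_forward(w, X)$pred - y))
  fwd <- ppgcond:::lstm_forward(w, X, cache = TRUE)
  g <- ppgcond:::lstm_backward(w, fwd, sign(fwd$pred - y) / 4)
  eps <- 1e-6; worst <- 0
  probe <- function(path_set, path_get) {
    wp <- path_set(eps); wm <- path_set(-eps)
    abs((loss(wp) - loss(wm)) / (2 * eps) - path_get())
  }
  set.seed(2)
  for (l in 1:2) for (nm in c("Wx", "Wh", "b")) {
    W <- w$layers[[l]][[nm]]
    for (k in sample(length(W), min(5L, length(W)))) {
      worst <- max(worst, probe(function(e) {
        w2 <- w; w2$layers[[l]][[nm]][k] <- W[k] + e; w2
      }, function() g$layers[[l]][[nm]][k]))
    }
  }
  for (k in seq_along(w$dense$w))
    worst <- max(worst, probe(function(e) {
      w2 <- w; w2$dense$w[k] <- w$dense$w[k] + e; w2
    }, function() g$dense$w[k]))
  expect_lt(worst, 1e-6)
})

test_that("the network learns the pass-through identity task", {
  corpus <- prep_synth(generate_corpus(3, seed = 14,
                                       synth_config(artifact_gain = 0)))
  recs <- lapply(corpus, function(e) {
    e$record$target <- e$record$ppg    # target is the ppg feature itself
    e$record
  })
  ds <- merge_datasets(lapply(recs, segment_record, L = 4L, S = 2L))
  cfg <- lstm_config(L = 4, S = 2, N_h = 8, N_l = 1, epochs = 10, seed = 3)
  fit <- ppg_lstm(ds, ds, cfg)
  expect_lt(fit$eval_loss_best, 0.05)
  expect_equal(fit$eval_loss_best, min(fit$history$eval_loss))
  expect_lte(nrow(fit$history), 60)
})

test_that("training is deterministic and epochs = 0 is a no-op", {
  rec <- normalize_record(generate_record(synth_config(seed = 6))$record)
  ds <- segment_record(rec, 4, 2)
  cfg <- lstm_config(L = 4, S = 2, N_h = 4, epochs = 3, seed = 5)
  f1 <- ppg_lstm(ds, ds, cfg)
  f2 <- ppg_lstm(ds, ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  m0 <- lstm_train(lstm_init(cfg), ds, ds, epochs = 0)
  expect_false(m0$trained)
  expect_equal(nrow(m0$history), 0)
  expect_error(lstm_train(lstm_init(lstm_config(L = 8, S = 2)), ds), "L")
})

test_that("conditioning returns a full-length signal in [-1, 1]", {
  rec <- normalize_record(generate_record(synth_config(seed = 16))$record)
  untrained <- lstm_init(lstm_config(L = 4, S = 2, N_h = 4, seed = 1))
  cond <- condition_signal(untrained, rec)
  expect_length(cond$ppg, length(rec$ppg))
  expect_true(all(is.finite(cond$ppg)))
  expect_true(all(abs(cond$ppg) <= 1))
  # record of exactly one span
  span_rec <- rec
  for (ch in record_channels(rec)) span_rec[[ch]] <- rec[[ch]][1:7]
  cond7 <- condition_signal(untrained, span_rec)   # (L-1)*S + 1 = 7
  expect_length(cond7$ppg, 7)
  # predict() dispatches on both input types
  expect_equal(predict(untrained, span_rec)$ppg, cond7$ppg)
  ds <- segment_record(rec, 4, 2)
  expect_length(predict(untrained, ds), nrow(ds$sequences))
})

test_that("conditioning reduces error to target on held-out records", {
  corpus <- prep_synth(generate_corpus(12, seed = 21))
  sp <- split_train_eval(corpus, n_train = 8, seed = 21)
  tr <- merge_datasets(lapply(sp$train,
                              function(e) segment_record(e$record, 4, 2)))
  ev <- merge_datasets(lapply(sp$eval,
                              function(e) segment_record(e$record, 4, 2)))
  fit <- ppg_lstm(tr, ev, lstm_config(L = 4, S = 2, N_h = 8, N_l = 1,
                                      epochs = 8, seed = 2))
  mse <- vapply(sp$eval, function(e) {
    cond <- condition_signal(fit, e$record)
    c(raw = mean((e$record$ppg - e$record$target)^2),
      cond = mean((cond$ppg - e$record$target)^2))
  }, numeric(2))
  expect_lt(mean(mse["cond", ]), mean(mse["raw", ]))
})

test_that("grid enumeration is the Cartesian product of the value lists", {
  expect_equal(nrow(grid_variants()), 240)
  expect_equal(nrow(grid_variants(L = 4, S = 1)), 8)
  expect_equal(nrow(grid_variants(L = integer(0))), 0)
  set.seed(8)
  for (k in 1:5) {
    L <- sample(grid_values$L, sample(1:5, 1))
    S <- sample(grid_values$S, sample(1:6, 1))
    N_l <- sample(grid_values$N_l, sample(1:2, 1))
    N_h <- sample(grid_values$N_h, sample(1:4, 1))
    g <- grid_variants(L, S, N_l, N_h)
    # oracle: explicit nested loops
    cnt <- 0L
    for (a in L) for (b in S) for (c in N_l) for (d in N_h) cnt <- cnt + 1L
    expect_equal(nrow(g), cnt)
    expect_false(anyDuplicated(g) > 0)
  }
})

test_that("the grid runner trains each variant and joins the cost model", {
  corpus <- prep_synth(generate_corpus(3, seed = 33,
                                       synth_config(duration = 16,
                                                    clean_head = 3,
                                                    clean_tail = 3)))
  recs <- lapply(corpus, `[[`, "record")
  res <- run_grid(recs[1:2], recs[3], grid_variants(L = 4, S = c(1, 2),
                                                    N_l = 1, N_h = 4),
                  epochs = 1, seed = 1)
  expect_equal(nrow(res), 2)
  expect_true(all(is.finite(res$eval_loss_best)))
  expect_true(all(res$n_params == 4 * (4 * 4 + 16 + 4) + 4 + 1))
  expect_equal(res$relative_cost,
               vapply(seq_len(2), function(i)
                 variant_cost(lstm_config(L = res$L[i], S = res$S[i],
                                          N_h = res$N_h[i], N_l = res$N_l[i])),
                 numeric(1)))
  expect_equal(nrow(run_grid(recs[1:2], recs[3],
                             grid_variants(L = integer(0)))), 0)
})

test_that("models round-trip through save/load", {
  rec <- normalize_record(generate_record(synth_config(seed = 6))$record)
  ds <- segment_record(rec, 4, 2)
  fit <- ppg_lstm(ds, ds, lstm_config(L = 4, S = 2, N_h = 4, epochs = 1))
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, p)
  expect_true(file.exists(paste0(p, ".json")))
  back <- load_model(p)
  expect_identical(back$weights, fit$weights)
  expect_equal(predict(back, ds), predict(fit, ds))
})
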