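test_that("sigmoid and tanh costs are literal operation counts", {
  expect_equal(sigma_cost(), 20)
  expect_equal(tanh_cost(), 36)
  ones <- cost_table(1, 1, 1, 1, 1)
  expect_equal(sigma_cost(ones), 4)
  expect_equal(tanh_cost(ones), 6)
  expect_equal(sigma_cost(cost_table(exp = 30)), 35)
  expect_equal(tanh_cost(cost_table(exp = 0)), 6)
  expect_error(cost_table(add = 0), "unit")
  expect_error(cost_table(divide = -1), "nonnegative")
})

test_that("the step-cost formula matches the instrumented scalar oracle", {
  set.seed(55)
  tabs <- list(default_cost_table(),
               cost_table(add = 2, subtract = 0.5, multiply = 3,
                          divide = 7, exp = 11))
  for (d in c(1L, 2L, 4L, 8L)) for (h in c(1L, 2L, 4L, 8L)) {
    Wx <- matrix(rnorm(d * 4 * h), d)
    Wh <- matrix(rnorm(h * 4 * h), h)
    b <- rnorm(4 * h)
    ref <- lstm_scalar_step(Wx, Wh, b, rnorm(d), rnorm(h), rnorm(h))
    br <- lstm_step_cost(d, h)
    # raw counts: the oracle counts sigma/tanh internals as basic operations
    expect_identical(unname(ref$counts["multiply"]), as.numeric(br$multiply))
    expect_identical(unname(ref$counts["add"]),
                     as.numeric(br$add + br$sigma_count + br$tanh_count))
    expect_identical(unname(ref$counts["subtract"]),
                     as.numeric(br$sigma_count + 2 * br$tanh_count))
    expect_identical(unname(ref$counts["divide"]),
                     as.numeric(br$sigma_count + br$tanh_count))
    expect_identical(unname(ref$counts["exp"]),
                     as.numeric(br$sigma_count + 2 * br$tanh_count))
    for (tab in tabs) {
      oracle_total <- sum(unlist(tab)[c("add", "subtract", "multiply",
                                        "divide", "exp")] *
                            ref$counts[c("add", "subtract", "multiply",
                                         "divide", "exp")])
      expect_equal(lstm_step_cost(d, h, tab)$total_relative_cost,
                   oracle_total, tolerance = 1e-12)
    }
  }
})

test_that("step cost scales with the dominant h*d terms", {
  big_d <- 512L
  c1 <- lstm_step_cost(big_d, 2L)$total_relative_cost
  c2 <- lstm_step_cost(big_d, 4L)$total_relative_cost
  expect_equal(c2 / c1, 2, tolerance = 0.05)
  only_mul <- cost_table(add = 1e-12, subtract = 0, multiply = 1.2,
                         divide = 0, exp = 0)
  h <- 3L; d <- 5L
  expect_equal(lstm_step_cost(d, h, only_mul)$total_relative_cost,
               1.2 * (4 * h * (d + h) + 3 * h), tolerance = 1e-6)
})

test_that("variant cost is monotone in L, N_h, N_l and independent of S", {
  cost <- function(L = 4, S = 1, N_h = 4, N_l = 1)
    variant_cost(lstm_config(L = L, S = S, N_h = N_h, N_l = N_l))
  expect_true(all(diff(vapply(c(4, 8, 16, 24, 32),
                              function(L) cost(L = L), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(4, 8, 16, 32),
                              function(nh) cost(N_h = nh), numeric(1))) > 0))
  expect_gt(cost(N_l = 2), cost(N_l = 1))
  expect_equal(cost(S = 1), cost(S = 16))
})

test_that("cost is linear in the cost-table entries", {
  cfg <- lstm_config(L = 8, S = 2, N_h = 8, N_l = 2)
  t1 <- cost_table(1, 2, 3, 4, 5)
  t2 <- cost_table(0.5, 1, 1.5, 2, 2.5)
  tsum <- cost_table(1.5, 3, 4.5, 6, 7.5)
  expect_equal(variant_cost(cfg, tsum),
               variant_cost(cfg, t1) + variant_cost(cfg, t2),
               tolerance = 1e-9)
  tdbl <- cost_table(2, 4, 6, 8, 10)
  expect_equal(variant_cost(cfg, tdbl), 2 * variant_cost(cfg, t1),
               tolerance = 1e-9)
})

test_that("the exact per-layer mode sums true layer widths", {
  cfg1 <- lstm_config(L = 4, S = 1, N_h = 8, N_l = 1)
  tab <- default_cost_table()
  expect_equal(variant_cost(cfg1, tab, exact_layers = TRUE),
               4 * lstm_step_cost(4, 8, tab)$total_relative_cost +
                 8 * (tab$multiply + tab$add))
  cfg2 <- lstm_config(L = 4, S = 1, N_h = 8, N_l = 2)
  expect_equal(variant_cost(cfg2, tab, exact_layers = TRUE),
               4 * (lstm_step_cost(4, 8, tab)$total_relative_cost +
                    lstm_step_cost(8, 8, tab)$total_relative_cost) +
                 8 * (tab$multiply + tab$add))
  # paper-mode single-bank convention differs from the exact count
  expect_false(isTRUE(all.equal(variant_cost(cfg2, tab),
                                variant_cost(cfg2, tab, exact_layers = TRUE))))
})
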