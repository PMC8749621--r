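#' Relative costs of the basic arithmetic operations
#'
#' Unitless costs of the basic operations normalized to the cost of
#' addition, measured once on an Arm-based embedded platform and shipped as
#' constants: add 1, subtract 1, multiply 1.2, divide 3, exp 15.
#'
#' @param add,subtract,multiply,divide,exp positive relative costs.
#' @return an object of class `cost_table`.
#' @export
cost_table <- function(add = 1, subtract = 1, multiply = 1.2, divide = 3,
                       exp = 15) {
  tab <- list(add = add, subtract = subtract, multiply = multiply,
              divide = divide, exp = exp)
  if (any(vapply(tab, function(v) !is.numeric(v) || v < 0, logical(1))))
    stop("all costs must be nonnegative numbers")
  if (tab$add <= 0) stop("add is the unit cost and must be positive")
  structure(tab, class = "cost_table")
}

#' @rdname cost_table
#' @export
default_cost_table <- function() cost_table()

#' Cost of one sigmoid evaluation
#'
#' Literal operation count of `1 / (1 + e^-x)`: one negation (a subtract),
#' one exp, one add, one divide.
#'
#' @param table a [cost_table()].
#' @return relative cost (20 with the default table).
#' @export
sigma_cost <- function(table = default_cost_table()) {
  table$subtract + table$exp + table$add + table$divide
}

#' Cost of one tanh evaluation
#'
#' Literal operation count of `(e^x - e^-x) / (e^x + e^-x)`: one negation
#' (a subtract), two exp, one subtract, one add, one divide.
#'
#' @param table a [cost_table()].
#' @return relative cost (36 with the default table).
#' @export
tanh_cost <- function(table = default_cost_table()) {
  2 * table$exp + 2 * table$subtract + table$add + table$divide
}

#' Operation counts and cost of one LSTM timestep
#'
#' Per timestep, each of the four gate pre-activations costs a `h x d` and a
#' `h x h` matrix–vector product plus bias add: `h(d + h)` multiplies and
#' `h(d + h)` adds per gate. Activations: `3h` sigmoids and `h` tanh for the
#' gates and candidate, the cell-state update adds `2h` multiplies and `h`
#' adds, and the hidden-state output another `h` tanh and `h` multiplies.
#'
#' @param d input feature width.
#' @param h number of hidden cells.
#' @param table a [cost_table()].
#' @return an object of class `cost_breakdown`: counts (`multiply`, `add`,
#'   `sigma_count`, `tanh_count`), `d`, `h` and `total_relative_cost`.
#' @export
lstm_step_cost <- function(d, h, table = default_cost_table()) {
  stopifnot(d >= 1, h >= 1)
  multiply <- 4 * h * (d + h) + 3 * h
  add <- 4 * h * (d + h) + h
  sigma_count <- 3 * h
  tanh_count <- 2 * h
  structure(list(d = d, h = h, multiply = multiply, add = add,
                 sigma_count = sigma_count, tanh_count = tanh_count,
                 total_relative_cost =
                   table$multiply * multiply + table$add * add +
                   sigma_count * sigma_cost(table) +
                   tanh_count * tanh_cost(table)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown d=%d h=%d: %d mul, %d add, %d sigma, %d tanh -> %.1f>\n",
              x$d, x$h, x$multiply, x$add, x$sigma_count, x$tanh_count,
              x$total_relative_cost))
  invisible(x)
}

#' Relative inference cost of a network variant
#'
#' Default convention: effective feature width `d = 4 L` and effective
#' hidden size `h = N_h * N_l`, with `L` timesteps of [lstm_step_cost()]
#' plus the linear output (`h` multiplies and `h` adds). This single-bank
#' approximation of multi-layer stacks is the convention used on the cost
#' axis of variant-ranking plots. `exact_layers = TRUE` instead sums the
#' true per-layer costs (layer 1 sees `d = 4`, deeper layers `d = N_h`) —
#' a stricter count, not the default convention.
#'
#' @param config an [lstm_config()].
#' @param table a [cost_table()].
#' @param exact_layers use the exact per-layer count (default FALSE).
#' @return total relative cost (unit: cost of one addition).
#' @export
variant_cost <- function(config, table = default_cost_table(),
                         exact_layers = FALSE) {
  stopifnot(inherits(config, "lstm_config"))
  L <- config$L
  if (exact_layers) {
    step_total <- 0
    for (l in seq_len(config$N_l)) {
      d_l <- if (l == 1L) 4L else config$N_h
      step_total <- step_total +
        lstm_step_cost(d_l, config$N_h, table)$total_relative_cost
    }
    h_out <- config$N_h
    L * step_total + h_out * (table$multiply + table$add)
  } else {
    h <- config$N_h * config$N_l
    L * lstm_step_cost(4L * L, h, table)$total_relative_cost +
      h * (table$multiply + table$add)
  }
}
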