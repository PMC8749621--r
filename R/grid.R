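#' Hyperparameter value lists for the grid search
#'
#' The value lists explored when ranking network variants: sequence length
#' `L` in {4, 8, 16, 24, 32}, inter-sample stride `S` in
#' {1, 2, 4, 8, 10, 16}, layers `N_l` in {1, 2}, cells `N_h` in
#' {4, 8, 16, 32} — a Cartesian product of 240 variants.
#'
#' @export
grid_values <- list(L = c(4L, 8L, 16L, 24L, 32L),
                    S = c(1L, 2L, 4L, 8L, 10L, 16L),
                    N_l = c(1L, 2L),
                    N_h = c(4L, 8L, 16L, 32L))

#' Enumerate network variants
#'
#' Cartesian product of the hyperparameter value lists, one row per variant.
#'
#' @param L,S,N_l,N_h value vectors; defaults are [grid_values].
#' @return data.frame with columns `L`, `S`, `N_l`, `N_h` (possibly 0 rows).
#' @export
grid_variants <- function(L = grid_values$L, S = grid_values$S,
                          N_l = grid_values$N_l, N_h = grid_values$N_h) {
  if (!length(L) || !length(S) || !length(N_l) || !length(N_h))
    return(data.frame(L = integer(0), S = integer(0),
                      N_l = integer(0), N_h = integer(0)))
  g <- expand.grid(N_h = N_h, N_l = N_l, S = S, L = L,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("L", "S", "N_l", "N_h")]
}

#' Train and rank network variants
#'
#' For every variant, segments the training and evaluation records with its
#' `(L, S)`, trains the network, and records the best evaluation loss
#' together with the analytic relative inference cost — the table behind
#' loss-versus-cost trade-off plots.
#'
#' @param train_records,eval_records lists of normalized `signal_record`s
#'   with targets.
#' @param variants data.frame from [grid_variants()].
#' @param epochs training epochs per variant (reduce for screening runs).
#' @param seed integer seed shared by all variants.
#' @param hop segmentation hop (default 1).
#' @param cost_table a [cost_table()] for the cost column.
#' @param verbose print progress.
#' @return `variants` with added columns `n_params`, `eval_loss_best`,
#'   `relative_cost`.
#' @export
run_grid <- function(train_records, eval_records, variants = grid_variants(),
                     epochs = 60L, seed = 1L, hop = 1L,
                     cost_table = default_cost_table(), verbose = FALSE) {
  variants <- cbind(variants, n_params = rep(NA_integer_, nrow(variants)),
                    eval_loss_best = rep(NA_real_, nrow(variants)),
                    relative_cost = rep(NA_real_, nrow(variants)))
  if (!nrow(variants)) return(variants)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    cfg <- lstm_config(L = v$L, S = v$S, N_h = v$N_h, N_l = v$N_l,
                       epochs = epochs, seed = seed)
    tr <- merge_datasets(lapply(train_records, segment_record,
                                L = v$L, S = v$S, hop = hop))
    ev <- merge_datasets(lapply(eval_records, segment_record,
                                L = v$L, S = v$S, hop = hop))
    fit <- ppg_lstm(tr, ev, cfg)
    variants$n_params[i] <- n_params(fit)
    variants$eval_loss_best[i] <- fit$eval_loss_best
    variants$relative_cost[i] <- variant_cost(cfg, cost_table)
    if (verbose)
      message(sprintf("[%d/%d] L=%d S=%d N_l=%d N_h=%d  eval %.5f  cost %.0f",
                      i, nrow(variants), v$L, v$S, v$N_l, v$N_h,
                      variants$eval_loss_best[i], variants$relative_cost[i]))
  }
  variants
}
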