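#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the interpolating-exponent calibration table
#'
#' @param x A `cpr_calibration` from [calibrate_interpolating_exponent()].
#' @param ... Unused.
#' @return Tibble with one row per candidate exponent.
#' @export
tidy.cpr_calibration <- function(x, ...) x$table

#' @rdname tidy.cpr_calibration
#' @export
glance.cpr_calibration <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, log_best_k = log(x$best_k),
                 best_mean_surplus = max(x$table$mean_surplus),
                 n_candidates = nrow(x$table), n_episodes = x$n_episodes)
}

#' Tidy a lagged offer regression
#'
#' @param x A `cpr_lagfit` from [lagged_offer_regression()].
#' @param ... Unused.
#' @return Tibble of per-lag median weights.
#' @export
tidy.cpr_lagfit <- function(x, ...) x$median

#' @rdname tidy.cpr_lagfit
#' @export
glance.cpr_lagfit <- function(x, ...) {
  peak <- x$median$lag[which.max(abs(x$median$weight))]
  tibble::tibble(n_trials = x$n_trials, skipped = x$skipped,
                 dominant_lag = peak,
                 dominant_weight = x$median$weight[x$median$lag == peak])
}

#' Glance at a behavioural-clone fit
#'
#' @param x A `bc_fit` from [train_bc()].
#' @param ... Unused.
#' @return One-row tibble with the update count, first/final loss and the
#'   uniform-policy reference `ln N`.
#' @export
glance.bc_fit <- function(x, ...) {
  lt <- x$loss_trace$loss[x$loss_trace$loss > 0]
  tibble::tibble(updates = x$hyper$updates, n_checkpoints = length(x$checkpoints),
                 first_loss = lt[1], final_loss = utils::tail(lt, 1),
                 ln_n_bins = log(x$hyper$n_bins))
}

#' Tidy and glance at a mechanism training run
#'
#' @param x A `mech_fit` from [train_mechanism()].
#' @param ... Unused.
#' @return `tidy()`: tibble of checkpoints and their evaluation surplus;
#'   `glance()`: one-row summary with initial/best evaluation surplus.
#' @export
tidy.mech_fit <- function(x, ...) {
  tibble::tibble(
    step = vapply(x$checkpoints, `[[`, integer(1), "step"),
    eval_surplus = vapply(x$checkpoints, `[[`, numeric(1), "eval_surplus"))
}

#' @rdname tidy.mech_fit
#' @export
glance.mech_fit <- function(x, ...) {
  ev <- vapply(x$checkpoints, `[[`, numeric(1), "eval_surplus")
  tibble::tibble(updates = x$train_config$updates,
                 init_surplus = ev[1], best_surplus = max(ev),
                 best_step = x$checkpoints[[max(which(ev >= max(ev) - 1e-12))]]$step)
}
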