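# Diagnostic figures: pool/offer dynamics, surplus vs Gini, offer equality
# vs pool size, exclusion durations, lag profiles, calibration curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot pool and per-player dynamics of an episode
#'
#' Top panel: pool size and per-trial total surplus; lower panels: offers
#' (solid) and reciprocations (dashed) per player.
#'
#' @param object An `episode_log`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episode_log <- function(object, ...) {
  tab <- as_tibble(object)
  pool <- dplyr::summarise(dplyr::group_by(tab, .data$trial),
                           pool = .data$pool_before[1],
                           surplus = sum(.data$surplus))
  long <- tidyr::pivot_longer(tab, c("offer", "contribution"),
                              names_to = "series", values_to = "amount")
  top <- ggplot2::ggplot(pool, ggplot2::aes(.data$trial)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pool), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$surplus), colour = "firebrick") +
    ggplot2::labs(y = "pool (blue) / surplus (red)", x = NULL,
                  title = sprintf("mechanism: %s", object$mechanism_id)) +
    ggplot2::theme_minimal()
  bottom <- ggplot2::ggplot(long, ggplot2::aes(.data$trial, .data$amount,
                                               linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~player, nrow = 1) +
    ggplot2::scale_linetype_manual(values = c(offer = "solid",
                                              contribution = "dashed")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
  patchwork::wrap_plots(top, bottom, ncol = 1, heights = c(1, 1.4))
}

#' Surplus vs Gini scatter per mechanism
#'
#' Each small point is a game; the large point is the condition mean.
#'
#' @param metrics Tibble from [metrics_table()] (one or more mechanisms).
#' @return A ggplot object.
#' @export
plot_surplus_gini <- function(metrics) {
  means <- dplyr::summarise(dplyr::group_by(metrics, .data$mechanism),
                            total_surplus = mean(.data$total_surplus),
                            surplus_gini = mean(.data$surplus_gini))
  ggplot2::ggplot(metrics, ggplot2::aes(.data$surplus_gini, .data$total_surplus,
                                        colour = .data$mechanism)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = means, size = 4) +
    ggplot2::labs(x = "Gini of player surplus", y = "total surplus") +
    ggplot2::theme_minimal()
}

#' Offer Gini vs pool size
#'
#' @param per_trial Tibble from [offer_gini_by_pool()].
#' @return A ggplot object.
#' @export
plot_offer_gini_by_pool <- function(per_trial) {
  by_game <- dplyr::summarise(dplyr::group_by(per_trial, .data$game),
                              pool = mean(.data$pool),
                              offer_gini = mean(.data$offer_gini))
  ggplot2::ggplot(per_trial, ggplot2::aes(.data$pool, .data$offer_gini)) +
    ggplot2::geom_point(colour = "grey60", alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = by_game, colour = "darkorange", size = 2) +
    ggplot2::labs(x = "pool size", y = "offer Gini") +
    ggplot2::theme_minimal()
}

#' Exclusion durations vs start trial
#'
#' Points on the diagonal are exclusions lasting to the end of the episode
#' (the player was never reincluded).
#'
#' @param events Tibble from [exclusion_events()] (optionally several games
#'   bound together).
#' @param horizon Episode length, for the diagonal reference line.
#' @return A ggplot object.
#' @export
plot_exclusions <- function(events, horizon = 40) {
  ggplot2::ggplot(events, ggplot2::aes(.data$start_trial, .data$duration)) +
    ggplot2::geom_abline(intercept = horizon + 1, slope = -1,
                         linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "trial exclusion starts", y = "duration (rounds)") +
    ggplot2::theme_minimal()
}

#' Lag-profile plot of a lagged offer regression
#'
#' Grey points are per-trial weights; the line is the per-lag median.
#'
#' @param object A `cpr_lagfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpr_lagfit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_trial, -"trial",
                              names_to = "lag", values_to = "weight")
  long$lag <- as.integer(sub("lag", "", long$lag))
  ggplot2::ggplot(long, ggplot2::aes(.data$lag, .data$weight)) +
    ggplot2::geom_point(colour = "grey60", alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = object$median, colour = "black") +
    ggplot2::geom_point(data = object$median, colour = "black", size = 2) +
    ggplot2::labs(x = "lag of reciprocation relative to offer (trials)",
                  y = "regression weight") +
    ggplot2::theme_minimal()
}

#' Calibration curve of the interpolating exponent
#'
#' @param object A `cpr_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpr_calibration <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$log_k, .data$mean_surplus)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$best_k), colour = "darkorange") +
    ggplot2::labs(x = "log k", y = "mean total surplus") +
    ggplot2::theme_minimal()
}
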