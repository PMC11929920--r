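# Descriptive analysis of gameplay: surplus, Gini, inclusivity, depletion,
# exclusion events and lagged offer regressions.

#' Gini coefficient
#'
#' Mean absolute pairwise difference divided by twice the mean, computed via
#' the sorted-values identity in O(n log n). Defined as 0 for constant and
#' for all-zero inputs (after a total collapse in welfare nobody gets
#' anything, which is perfectly equal).
#'
#' @param x Non-negative numeric vector.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' gini(c(1, 0, 0, 0))  # 0.75
#' @export
gini <- function(x) {
  if (any(x < 0)) stop("gini requires non-negative values", call. = FALSE)
  n <- length(x)
  s <- sum(x)
  if (n < 2L || s == 0) return(0)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs) / (n * s)) - (n + 1) / n
}

#' Per-episode metrics
#'
#' Computes the figures' per-game quantities: total and per-player surplus,
#' the Gini of aggregate player surplus, mean active players (players
#' receiving an offer of at least one unit per round), the trial on which
#' the pool drops below one unit (or the horizon if it never does), whether
#' the game was sustained (pool at least one unit on the last trial), and
#' the per-trial offer Gini paired with pool size.
#'
#' @param log An `episode_log`.
#' @param threshold Offer/pool unit threshold (defaults to the config's).
#' @return A `cpr_metrics` list; `as_tibble()` gives the one-row game
#'   summary and `$per_trial` the trial-level offer-Gini table.
#' @export
episode_metrics <- function(log, threshold = NULL) {
  cfg <- log$config
  if (is.null(threshold)) threshold <- cfg$offer_unit_threshold
  T_len <- episode_length(log)
  s <- episode_surpluses(log)
  per_player <- colSums(s)
  active <- rowSums(log$offers >= threshold)
  below <- which(log$pool_after < threshold)
  depletion_trial <- if (length(below)) below[1] else T_len
  per_trial <- tibble::tibble(
    trial = seq_len(T_len),
    pool = log$pool_before,
    offer_gini = vapply(seq_len(T_len), function(t) gini(log$offers[t, ]),
                        numeric(1))
  )
  structure(list(
    mechanism_id = log$mechanism_id,
    game = log$game_index,
    total_surplus = sum(s),
    per_player_surplus = per_player,
    surplus_gini = gini(per_player),
    active_players = mean(active),
    depletion_trial = depletion_trial,
    sustained = log$pool_after[T_len] >= threshold,
    horizon = T_len,
    per_trial = per_trial
  ), class = "cpr_metrics")
}

#' @export
print.cpr_metrics <- function(x, ...) {
  cat(sprintf("<cpr_metrics> %s game %d: surplus %.1f, Gini %.3f, active %.2f, %s\n",
              x$mechanism_id, x$game, x$total_surplus, x$surplus_gini,
              x$active_players,
              if (x$sustained) "sustained" else sprintf("depleted at trial %d", x$depletion_trial)))
  invisible(x)
}

#' @export
as_tibble.cpr_metrics <- function(x, ...) {
  tibble::tibble(
    mechanism = x$mechanism_id, game = x$game,
    total_surplus = x$total_surplus, surplus_gini = x$surplus_gini,
    active_players = x$active_players, depletion_trial = x$depletion_trial,
    sustained = x$sustained, horizon = x$horizon
  )
}

#' Metrics table for a set of episode logs
#'
#' @param logs List of `episode_log`s.
#' @param threshold Unit threshold, see [episode_metrics()].
#' @return Tibble with one row per game.
#' @export
metrics_table <- function(logs, threshold = NULL) {
  dplyr::bind_rows(lapply(logs, function(l)
    as_tibble(episode_metrics(l, threshold))))
}

#' Exclusion events in an episode
#'
#' An exclusion starts on a trial where a player who received at least
#' `threshold` units on the previous trial gets an offer below it, and lasts
#' for the run of consecutive sub-threshold offers. Events running to the
#' final trial are flagged as never reincluded.
#'
#' @param log An `episode_log`.
#' @param threshold Offer unit threshold.
#' @return Tibble with `player`, `start_trial` (1-based), `duration`,
#'   `reincluded`.
#' @export
exclusion_events <- function(log, threshold = 1) {
  T_len <- episode_length(log)
  out <- list()
  for (i in seq_len(log$config$p)) {
    inc <- log$offers[, i] >= threshold
    t <- 2L
    while (t <= T_len) {
      if (!inc[t] && inc[t - 1L]) {
        dur <- 0L
        while (t + dur <= T_len && !inc[t + dur]) dur <- dur + 1L
        out[[length(out) + 1L]] <- tibble::tibble(
          player = i, start_trial = t, duration = dur,
          reincluded = (t + dur) <= T_len)
        t <- t + dur
      } else t <- t + 1L
    }
  }
  if (!length(out))
    return(tibble::tibble(player = integer(), start_trial = integer(),
                          duration = integer(), reincluded = logical()))
  dplyr::bind_rows(out)
}

#' Lagged offer regressions
#'
#' For each trial `t` with all lags available, fits an ordinary least
#' squares regression (pooling players and games within the set of logs) of
#' the offer at `t` on the focal player's reciprocations at lags -4..+4,
#' then reports the median weight per lag across trials. A proportional
#' mechanism concentrates its mass at lag -1 (the current offer is set by
#' the previous reciprocation); a mechanism that elicits reciprocation
#' shifts mass toward lag 0 and beyond. Zero-variance regressors get a
#' zero weight; trials whose design is otherwise singular are skipped and
#' counted.
#'
#' @param logs List of `episode_log`s (one condition).
#' @param lags Integer lags of reciprocation relative to the offer trial.
#' @return A `cpr_lagfit` with `per_trial` (tibble of trial x lag weights)
#'   and `median` (tibble of per-lag medians); has [tidy()]/[glance()]
#'   methods.
#' @export
lagged_offer_regression <- function(logs, lags = -4:4) {
  stopifnot(length(logs) >= 1)
  T_len <- min(vapply(logs, episode_length, integer(1)))
  lo <- max(1L - min(lags), 1L)
  hi <- T_len - max(lags)
  if (hi < lo) stop("episodes too short for the requested lags", call. = FALSE)
  rows <- list()
  skipped <- 0L
  for (t in seq(lo, hi)) {
    y <- unlist(lapply(logs, function(l) l$offers[t, ]))
    X <- sapply(lags, function(k)
      unlist(lapply(logs, function(l) l$contributions[t + k, ])))
    X <- matrix(X, ncol = length(lags))
    keep <- apply(X, 2L, function(col) stats::sd(col) > 1e-12)
    beta <- rep(0, length(lags))
    if (any(keep)) {
      fit <- tryCatch(
        stats::lm.fit(cbind(1, X[, keep, drop = FALSE]), y),
        error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) {
        coefs <- fit$coefficients
        if (is.null(coefs)) { skipped <- skipped + 1L; next }
        coefs[is.na(coefs)] <- 0
        beta[keep] <- coefs[-1L]
      } else {
        beta[keep] <- fit$coefficients[-1L]
      }
    }
    rows[[length(rows) + 1L]] <- c(trial = t, stats::setNames(beta, paste0("lag", lags)))
  }
  if (!length(rows)) stop("no usable trials for the lag regression", call. = FALSE)
  per_trial <- tibble::as_tibble(do.call(rbind, rows))
  med <- tibble::tibble(
    lag = lags,
    weight = unname(vapply(paste0("lag", lags), function(nm)
      stats::median(per_trial[[nm]]), numeric(1)))
  )
  structure(list(per_trial = per_trial, median = med,
                 lags = lags, n_trials = nrow(per_trial),
                 skipped = skipped),
            class = "cpr_lagfit")
}

#' @export
print.cpr_lagfit <- function(x, ...) {
  peak <- x$median$lag[which.max(abs(x$median$weight))]
  cat(sprintf("<cpr_lagfit> %d trials (%d skipped); dominant lag %+d (median weight %.3f)\n",
              x$n_trials, x$skipped, peak,
              x$median$weight[x$median$lag == peak]))
  invisible(x)
}

#' Summarise a condition (set of games under one mechanism)
#'
#' Per-game metrics plus condition-level means (overall and split into
#' sustained vs depleted games) and the Pearson correlation between surplus
#' and Gini within each subset (reported as `NA` when undefined, e.g. with
#' fewer than three games or zero variance).
#'
#' @param metrics Tibble from [metrics_table()], or a list of logs.
#' @return A list with `per_game`, `means` (tibble with one row per subset:
#'   all/sustained/depleted) including `cor_surplus_gini`.
#' @export
summarize_condition <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- metrics_table(metrics)
  stopifnot(nrow(metrics) >= 1)
  one <- function(df, label) {
    if (!nrow(df))
      return(tibble::tibble(subset = label, n_games = 0L,
                            mean_surplus = NA_real_, mean_gini = NA_real_,
                            mean_active = NA_real_, mean_depletion = NA_real_,
                            cor_surplus_gini = NA_real_))
    cc <- if (nrow(df) >= 3 && stats::sd(df$total_surplus) > 1e-12 &&
              stats::sd(df$surplus_gini) > 1e-12)
      stats::cor(df$total_surplus, df$surplus_gini) else NA_real_
    tibble::tibble(
      subset = label, n_games = nrow(df),
      mean_surplus = mean(df$total_surplus),
      mean_gini = mean(df$surplus_gini),
      mean_active = mean(df$active_players),
      mean_depletion = mean(df$depletion_trial),
      cor_surplus_gini = cc)
  }
  means <- dplyr::bind_rows(
    one(metrics, "all"),
    one(metrics[metrics$sustained, , drop = FALSE], "sustained"),
    one(metrics[!metrics$sustained, , drop = FALSE], "depleted"))
  list(per_game = metrics, means = means)
}

#' Per-trial offer Gini vs pool size for a set of logs
#'
#' @param logs List of `episode_log`s.
#' @return Tibble with `game`, `trial`, `pool`, `offer_gini`.
#' @export
offer_gini_by_pool <- function(logs) {
  dplyr::bind_rows(lapply(logs, function(l) {
    m <- episode_metrics(l)
    dplyr::mutate(m$per_trial, game = l$game_index, .before = 1L)
  }))
}
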