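#' Game configuration for the iterated common-pool trust game
#'
#' Defines the static parameters of the game: the number of players `p`, the
#' initial/maximum pool `R0` (the carrying capacity), the growth factor `r`
#' applied to reciprocations, and the termination rule. Contributions are
#' multiplied by `1 + r` when returned to the pool, and the pool is capped at
#' `R0` after every round.
#'
#' Two termination rules are supported: a fixed horizon of `horizon` rounds,
#' or a geometric rule (`min_rounds`, `end_prob`) under which the game lasts
#' at least `min_rounds` rounds and then ends with probability `end_prob`
#' after each additional round.
#'
#' @param p Number of players (>= 1; >= 2 for a non-degenerate game).
#' @param R0 Initial and maximum pool size, in resource units (> 0).
#' @param r Growth factor applied to contributions (> -1).
#' @param horizon Fixed episode length in rounds; ignored when `min_rounds`
#'   and `end_prob` are both supplied.
#' @param min_rounds,end_prob Geometric termination: minimum number of rounds,
#'   and the per-round end probability after the minimum (0 < end_prob <= 1).
#' @param n_consecutive_games Number of consecutive games in a session.
#' @param offer_unit_threshold Offers below this many resource units count as
#'   exclusion/no allocation; the receiving player is forced to contribute 0.
#' @param integer_contributions If `TRUE`, contributions are restricted to
#'   whole units (mimicking a slider incremented in integers).
#' @param truncate_on_depletion If `TRUE`, an episode stops once the pool
#'   falls below `offer_unit_threshold`; by default the episode runs to its
#'   sampled length with all-zero allocations after depletion.
#' @param normalizer Normalisation constant for neural-network observations
#'   (defaults to `R0`).
#' @return A `cpr_config` object (a named list).
#' @examples
#' cfg <- game_config()            # p = 4, R0 = 200, r = 0.4, 40 rounds
#' cfg_geom <- game_config(min_rounds = 25, end_prob = 0.2)
#' @export
game_config <- function(p = 4L, R0 = 200, r = 0.4, horizon = 40L,
                        min_rounds = NULL, end_prob = NULL,
                        n_consecutive_games = 1L,
                        offer_unit_threshold = 1,
                        integer_contributions = FALSE,
                        truncate_on_depletion = FALSE,
                        normalizer = R0) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("invalid configuration: p must be >= 1", call. = FALSE)
  if (!is.finite(R0) || R0 <= 0) stop("invalid configuration: R0 must be > 0", call. = FALSE)
  if (!is.finite(r) || r <= -1) stop("invalid configuration: r must be > -1", call. = FALSE)
  geometric <- !is.null(min_rounds) && !is.null(end_prob)
  if (geometric) {
    if (end_prob <= 0 || end_prob > 1)
      stop("invalid configuration: end_prob must be in (0, 1]", call. = FALSE)
    if (min_rounds < 1) stop("invalid configuration: min_rounds must be >= 1", call. = FALSE)
  } else {
    horizon <- as.integer(horizon)
    if (is.na(horizon) || horizon < 1L)
      stop("invalid configuration: horizon must be >= 1", call. = FALSE)
  }
  structure(list(
    p = p, R0 = R0, r = r,
    horizon = if (geometric) NA_integer_ else horizon,
    min_rounds = if (geometric) as.integer(min_rounds) else NULL,
    end_prob = if (geometric) end_prob else NULL,
    geometric = geometric,
    n_consecutive_games = as.integer(n_consecutive_games),
    offer_unit_threshold = offer_unit_threshold,
    integer_contributions = isTRUE(integer_contributions),
    truncate_on_depletion = isTRUE(truncate_on_depletion),
    normalizer = normalizer
  ), class = "cpr_config")
}

#' @export
print.cpr_config <- function(x, ...) {
  term <- if (x$geometric) {
    sprintf("geometric (min %d rounds, end prob %.3g)", x$min_rounds, x$end_prob)
  } else {
    sprintf("fixed horizon %d rounds", x$horizon)
  }
  cat(sprintf("<cpr_config> p = %d, R0 = %g, r = %g, %s\n", x$p, x$R0, x$r, term))
  invisible(x)
}

#' Initial game state
#'
#' The pool is initialised to its maximum value `R0`; previous offers and
#' contributions are zero.
#'
#' @param config A [game_config()] object.
#' @return A `cpr_state` list with fields `t` (0-based round index), `R`
#'   (current pool), `prev_offers`, `prev_contributions`, `depleted_at`.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "cpr_config"))
  structure(list(
    t = 0L,
    R = config$R0,
    prev_offers = rep(0, config$p),
    prev_contributions = rep(0, config$p),
    depleted_at = NA_integer_
  ), class = "cpr_state")
}

validate_round_inputs <- function(state, offers, contributions, config) {
  p <- config$p
  if (length(offers) != p) stop("offers must have length p", call. = FALSE)
  if (length(contributions) != p) stop("contributions must have length p", call. = FALSE)
  tol <- 1e-9 * max(1, state$R)
  neg <- which(offers < -tol)
  if (length(neg))
    stop(sprintf("negative offer for player %d", neg[1]), call. = FALSE)
  if (sum(offers) > state$R + tol)
    stop(sprintf("offers sum to %.6g, exceeding the pool (%.6g)",
                 sum(offers), state$R), call. = FALSE)
  bad <- which(contributions < -tol | contributions > offers + tol)
  if (length(bad))
    stop(sprintf("contribution outside [0, offer] for player %d", bad[1]),
         call. = FALSE)
  if (config$integer_contributions) {
    nonint <- which(abs(contributions - round(contributions)) > 1e-9)
    if (length(nonint))
      stop(sprintf("non-integer contribution for player %d", nonint[1]),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply one round of offers and contributions
#'
#' Implements the pool update
#' `R' = min(R0, R - sum(e) + (1 + r) * sum(c))`: the pool is depleted by the
#' allocation and replenished, with interest, by the reciprocations, then
#' capped at the carrying capacity `R0`. Each player's surplus for the round
#' is `e_i - c_i`.
#'
#' @param state A `cpr_state`.
#' @param offers Numeric vector of length `p`, non-negative, summing to at
#'   most `state$R`.
#' @param contributions Numeric vector of length `p` with
#'   `0 <= c_i <= offers_i`.
#' @param config A [game_config()].
#' @return A list with `state` (the updated `cpr_state`) and `record`, a
#'   one-row tibble holding the round's offers, contributions, surpluses,
#'   retained amount and pool before/after (vector fields as list-columns).
#' @examples
#' cfg <- game_config()
#' st <- init_state(cfg)
#' out <- apply_round(st, rep(50, 4), rep(50, 4) / 1.4, cfg)
#' out$state$R  # replenishment fixed point: stays at 200
#' @export
apply_round <- function(state, offers, contributions, config) {
  validate_round_inputs(state, offers, contributions, config)
  offers <- pmax(offers, 0)
  contributions <- pmin(pmax(contributions, 0), offers)
  R_before <- state$R
  retained <- max(R_before - sum(offers), 0)
  surpluses <- offers - contributions
  delta <- -sum(offers) + (1 + config$r) * sum(contributions)
  R_after <- min(config$R0, R_before + delta)
  R_after <- max(R_after, 0)
  depleted_at <- state$depleted_at
  if (is.na(depleted_at) && R_after < config$offer_unit_threshold)
    depleted_at <- state$t
  record <- tibble::tibble(
    t = state$t,
    pool_before = R_before,
    offers = list(offers),
    contributions = list(contributions),
    surpluses = list(surpluses),
    retained = retained,
    pool_after = R_after
  )
  state_new <- structure(list(
    t = state$t + 1L,
    R = R_after,
    prev_offers = offers,
    prev_contributions = contributions,
    depleted_at = depleted_at
  ), class = "cpr_state")
  list(state = state_new, record = record)
}

#' Sample an episode length
#'
#' Under the fixed rule the length is the configured horizon. Under the
#' geometric rule the game lasts `min_rounds` rounds plus a geometric number
#' of additional rounds, each survived with probability `1 - end_prob`
#' (expected length `min_rounds + (1 - end_prob) / end_prob`).
#'
#' @param config A [game_config()].
#' @return Integer episode length; draws from the current RNG stream when the
#'   rule is geometric.
#' @export
sample_episode_length <- function(config) {
  stopifnot(inherits(config, "cpr_config"))
  if (!config$geometric) return(config$horizon)
  config$min_rounds + stats::rgeom(1L, config$end_prob)
}

#' Run one episode of the game
#'
#' Each round proceeds: the mechanism allocates offers from the pool, players
#' choose contributions, then the pool is updated. A player whose offer is
#' below `offer_unit_threshold` keeps the whole amount and contributes 0.
#' After depletion the mechanism can only allocate what remains (eventually
#' all zeros); the episode still runs to its sampled length unless
#' `truncate_on_depletion` is set in the config.
#'
#' @param mechanism A mechanism policy, see [new_mechanism()].
#' @param players List of `p` player policies, see [new_player()].
#' @param config A [game_config()].
#' @param seed Optional integer seed; the episode is bitwise reproducible
#'   given the seed. The caller's RNG state is preserved.
#' @param game_index Game number within a consecutive-game session.
#' @param length Optional pre-sampled episode length (overrides the
#'   termination rule).
#' @return An `episode_log` object; see [as_tibble.episode_log()] for the
#'   tidy per-player-per-round view.
#' @examples
#' cfg <- game_config(horizon = 5)
#' log <- run_episode(mechanism_equal(), replicate(4, player_sustainer(),
#'   simplify = FALSE), cfg, seed = 1)
#' tail(episode_pool(log), 1)  # sustainers keep the pool at R0
#' @export
run_episode <- function(mechanism, players, config, seed = NULL,
                        game_index = 1L, length = NULL) {
  stopifnot(inherits(config, "cpr_config"))
  if (!inherits(mechanism, "cpr_mechanism")) stop("mechanism must be a cpr_mechanism", call. = FALSE)
  if (base::length(players) != config$p)
    stop(sprintf("need %d players, got %d", config$p, base::length(players)), call. = FALSE)
  if (!all(vapply(players, inherits, logical(1), "cpr_player")))
    stop("players must be cpr_player objects", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  T_len <- if (is.null(length)) sample_episode_length(config) else as.integer(length)

  mstate <- mechanism$reset(config)
  pstates <- lapply(seq_len(config$p), function(i) players[[i]]$reset(config, i))
  state <- init_state(config)
  p <- config$p
  offers_m <- matrix(0, T_len, p)
  contribs_m <- matrix(0, T_len, p)
  pool_before <- numeric(T_len)
  pool_after <- numeric(T_len)
  retained_v <- numeric(T_len)
  n_done <- 0L
  for (t in seq_len(T_len)) {
    act <- mechanism$act(mstate, state, config)
    mstate <- act$state
    offers <- pmax(act$offers, 0)
    # guard against floating overshoot of the pool
    s <- sum(offers)
    if (s > state$R && s > 0) offers <- offers * (state$R / s)
    contribs <- numeric(p)
    for (i in seq_len(p)) {
      res <- players[[i]]$act(pstates[[i]], offers, state$prev_contributions,
                              state$R, i, config)
      pstates[i] <- list(res$state)   # list-assign: state may be NULL
      ci <- res$contribution
      ei <- offers[i]
      if (ei < config$offer_unit_threshold) ci <- 0
      ci <- min(max(ci, 0), ei)
      if (config$integer_contributions) ci <- floor(ci + 1e-9)
      contribs[i] <- ci
    }
    step <- apply_round(state, offers, contribs, config)
    offers_m[t, ] <- offers
    contribs_m[t, ] <- contribs
    pool_before[t] <- state$R
    pool_after[t] <- step$state$R
    retained_v[t] <- step$record$retained
    state <- step$state
    n_done <- t
    if (config$truncate_on_depletion && state$R < config$offer_unit_threshold) break
  }
  idx <- seq_len(n_done)
  structure(list(
    config = config,
    mechanism_id = mechanism$id,
    player_ids = vapply(players, function(pl) pl$id, character(1)),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    game_index = as.integer(game_index),
    sampled_length = T_len,
    offers = offers_m[idx, , drop = FALSE],
    contributions = contribs_m[idx, , drop = FALSE],
    pool_before = pool_before[idx],
    pool_after = pool_after[idx],
    retained = retained_v[idx],
    depleted_at = state$depleted_at
  ), class = "episode_log")
}

#' Run a session of consecutive games
#'
#' Runs `n_consecutive_games` episodes with the same mechanism and players;
#' the pool and all per-episode memory reset between games.
#'
#' @inheritParams run_episode
#' @return A list of `episode_log`s with increasing `game_index`.
#' @export
run_session <- function(mechanism, players, config, seed = NULL) {
  n <- config$n_consecutive_games
  seeds <- if (is.null(seed)) rep(list(NULL), n) else as.list(seed + seq_len(n) - 1L)
  lapply(seq_len(n), function(g)
    run_episode(mechanism, players, config, seed = seeds[[g]], game_index = g))
}

#' Number of rounds in an episode log
#' @param log An `episode_log`.
#' @export
episode_length <- function(log) base::length(log$pool_before)

#' Pool trajectory of an episode (pool after each round)
#' @param log An `episode_log`.
#' @export
episode_pool <- function(log) log$pool_after

#' Per-round surplus matrix (rounds x players)
#' @param log An `episode_log`.
#' @export
episode_surpluses <- function(log) log$offers - log$contributions

#' @export
print.episode_log <- function(x, ...) {
  cat(sprintf("<episode_log> mechanism '%s', %d players, %d rounds, total surplus %.2f\n",
              x$mechanism_id, x$config$p, episode_length(x),
              sum(episode_surpluses(x))))
  invisible(x)
}

#' Tidy view of an episode log
#'
#' One row per player per round: `game`, `trial` (1-based), `player`, `offer`,
#' `contribution`, `surplus`, `pool_before`, `pool_after`, `retained`.
#'
#' @param x An `episode_log`.
#' @param ... Unused.
#' @export
as_tibble.episode_log <- function(x, ...) {
  T_len <- episode_length(x)
  p <- x$config$p
  s <- episode_surpluses(x)
  tibble::tibble(
    game = rep(x$game_index, T_len * p),
    trial = rep(seq_len(T_len), each = p),
    player = rep(seq_len(p), times = T_len),
    offer = as.vector(t(x$offers)),
    contribution = as.vector(t(x$contributions)),
    surplus = as.vector(t(s)),
    pool_before = rep(x$pool_before, each = p),
    pool_after = rep(x$pool_after, each = p),
    retained = rep(x$retained, each = p)
  )
}

#' Maximum sustainable keep fraction
#'
#' The largest fraction of an endowment that players can keep while allowing
#' full replenishment of the pool: if everyone contributes `e / (1 + r)`, the
#' returned amount `(1 + r) c` exactly restores what was allocated, so the
#' keep fraction `r / (1 + r)` is sustainable indefinitely.
#'
#' @param r Growth factor.
#' @return `r / (1 + r)`.
#' @examples
#' sustainable_keep_fraction(0.4)  # 0.2857..., i.e. about 29%
#' @export
sustainable_keep_fraction <- function(r = 0.4) r / (1 + r)
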