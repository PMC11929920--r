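#' Construct a mechanism policy
#'
#' A mechanism maps the game history to the round's allocation: a vector of
#' `p` non-negative offers plus the amount retained in the pool, with
#' `sum(offers) + retained == R`. State is threaded functionally: `reset()`
#' returns a fresh per-episode state and `act()` returns the offers together
#' with the updated state.
#'
#' @param id Character identifier, recorded in episode logs.
#' @param reset `function(config)` returning the initial mechanism state.
#' @param act `function(state, game_state, config)` returning
#'   `list(offers, retained, state)`.
#' @return A `cpr_mechanism` object.
#' @export
new_mechanism <- function(id, reset = function(config) NULL, act) {
  structure(list(id = id, reset = reset, act = act), class = "cpr_mechanism")
}

#' @export
print.cpr_mechanism <- function(x, ...) {
  cat(sprintf("<cpr_mechanism> %s\n", x$id)); invisible(x)
}

#' Weighted equal/proportional allocation
#'
#' The baseline family mixing an equal split and a proportional-to-previous-
#' contribution split, controlled by a mixing weight `w`:
#' `e_i = w * A / p + (1 - w) * A * c_prev_i / sum(c_prev)` where `A` is the
#' allocatable amount `(1 - residual_fraction) * R`. On the opening round the
#' allocation is always equal. When no player contributed on the previous
#' round the proportional component allocates nothing to anyone (the whole
#' group is excluded under `w = 0`).
#'
#' @param w Mixing weight in `[0, 1]`: 1 = equal, 0 = proportional.
#' @param residual_fraction Fraction of the pool left unallocated, in
#'   `[0, 0.4]`. Defaults to 0 (the full pool is allocated).
#' @param state A `cpr_state`.
#' @param config A [game_config()].
#' @return `list(offers, retained)`.
#' @examples
#' cfg <- game_config()
#' st <- init_state(cfg)
#' weighted_offers(1, 0, st, cfg)$offers        # equal opening: 50 each
#' @export
weighted_offers <- function(w, residual_fraction = 0, state, config) {
  stopifnot(w >= 0, w <= 1, residual_fraction >= 0, residual_fraction <= 0.4)
  R <- state$R
  A <- (1 - residual_fraction) * R
  p <- config$p
  if (state$t == 0L) {
    offers <- rep(A / p, p)
  } else {
    c_prev <- state$prev_contributions
    tot <- sum(c_prev)
    prop <- if (tot > 0) A * c_prev / tot else rep(0, p)
    offers <- w * A / p + (1 - w) * prop
  }
  list(offers = offers, retained = R - sum(offers))
}

#' Weighted baseline mechanisms
#'
#' [mechanism_weighted()] wraps [weighted_offers()] as a mechanism policy;
#' `mechanism_equal()`, `mechanism_mixed()` and `mechanism_proportional()` are
#' the named members at `w = 1`, `w = 0.5` and `w = 0`.
#'
#' @inheritParams weighted_offers
#' @return A `cpr_mechanism`.
#' @export
mechanism_weighted <- function(w, residual_fraction = 0) {
  force(w); force(residual_fraction)
  new_mechanism(
    id = sprintf("weighted(w=%g%s)", w,
                 if (residual_fraction > 0) sprintf(",res=%g", residual_fraction) else ""),
    act = function(state, game_state, config) {
      out <- weighted_offers(w, residual_fraction, game_state, config)
      list(offers = out$offers, retained = out$retained, state = state)
    })
}

#' @rdname mechanism_weighted
#' @export
mechanism_equal <- function() {
  m <- mechanism_weighted(1); m$id <- "equal"; m
}

#' @rdname mechanism_weighted
#' @export
mechanism_mixed <- function() {
  m <- mechanism_weighted(0.5); m$id <- "mixed"; m
}

#' @rdname mechanism_weighted
#' @export
mechanism_proportional <- function() {
  m <- mechanism_weighted(0); m$id <- "proportional"; m
}

#' Random Dirichlet offers
#'
#' Draws five proportions from a flat Dirichlet (concentration 1) on the
#' 5-simplex; the first four, multiplied by the pool, are the offers and the
#' fifth is the amount kept in the pool. For `p != 4` players, `p + 1`
#' proportions are drawn.
#'
#' @param state A `cpr_state`.
#' @param config A [game_config()].
#' @return `list(offers, retained)`; draws from the current RNG stream.
#' @export
random_offers <- function(state, config) {
  p <- config$p
  g <- stats::rgamma(p + 1L, shape = 1)
  w <- g / sum(g)
  list(offers = w[seq_len(p)] * state$R, retained = w[p + 1L] * state$R)
}

#' Random baseline mechanism
#' @return A `cpr_mechanism` drawing Dirichlet(1) allocations each round.
#' @export
mechanism_random <- function() {
  new_mechanism("random", act = function(state, game_state, config) {
    out <- random_offers(game_state, config)
    list(offers = out$offers, retained = out$retained, state = state)
  })
}

#' Pool-conditioned mixing weight
#'
#' The interpolating baseline sets the mixing weight as a power law of the
#' normalised pool, `w = (R / R0)^k`: allocation is egalitarian only when the
#' pool is near full, and close to proportional otherwise (for large `k`).
#'
#' @param k Exponent (> 0).
#' @param R Current pool size.
#' @param R0 Maximum pool size.
#' @return The mixing weight `w` in `[0, 1]`.
#' @examples
#' interpolating_weight(22, 200, 200)  # 1: equal at a full pool
#' interpolating_weight(22, 100, 200)  # 2^-22: essentially proportional
#' @export
interpolating_weight <- function(k, R, R0) {
  stopifnot(k > 0, R >= 0, R <= R0)
  (R / R0)^k
}

#' Interpolating baseline mechanism
#'
#' @param k Exponent of the pool-conditioned weight, see
#'   [interpolating_weight()].
#' @param residual_fraction Fraction of the pool left unallocated.
#' @return A `cpr_mechanism`.
#' @export
mechanism_interpolating <- function(k, residual_fraction = 0) {
  force(k); force(residual_fraction)
  new_mechanism(
    id = sprintf("interpolating(k=%g)", k),
    act = function(state, game_state, config) {
      w <- interpolating_weight(k, game_state$R, config$R0)
      out <- weighted_offers(w, residual_fraction, game_state, config)
      list(offers = out$offers, retained = out$retained, state = state)
    })
}

#' Default exponent grid for interpolating-baseline calibration
#'
#' 101 candidates `k = exp(g)` for `g` on a grid from -5 to 5 in steps of
#' 0.1 (so `log(k)` spans `[-5, 5]`; `exp(3.1)` is approximately 22).
#'
#' @return Numeric vector of 101 exponents.
#' @export
default_k_grid <- function() exp(seq(-5, 5, by = 0.1))

#' Calibrate the interpolating-baseline exponent
#'
#' Runs `n_episodes` simulated games per candidate exponent against player
#' sets sampled from a population and returns the exponent with the highest
#' mean total surplus. Ties break toward the larger (more proportional)
#' exponent.
#'
#' @param population A player population, see [population()]; each episode
#'   samples a fresh player set from it.
#' @param grid Candidate exponents; defaults to [default_k_grid()].
#' @param n_episodes Episodes per candidate.
#' @param config A [game_config()].
#' @param seed Integer seed; the same episode seeds are reused across
#'   candidates, so candidates are compared on matched player draws.
#' @return A list with `best_k`, and `table`: a tibble of `k`, `log_k`,
#'   `mean_surplus`, `sd_surplus` (class `cpr_calibration`; has [tidy()] and
#'   [glance()] methods).
#' @export
calibrate_interpolating_exponent <- function(population, grid = default_k_grid(),
                                             n_episodes = 20L, config = game_config(),
                                             seed = 1L) {
  stopifnot(length(grid) >= 1, all(grid > 0))
  ep_seeds <- seed + seq_len(n_episodes)
  per_k <- purrr::map(grid, function(k) {
    mech <- mechanism_interpolating(k)
    surplus <- vapply(ep_seeds, function(s) {
      players <- sample_players(population, config, seed = s)
      log <- run_episode(mech, players, config, seed = s)
      sum(episode_surpluses(log))
    }, numeric(1))
    c(mean = mean(surplus), sd = stats::sd(surplus))
  })
  tab <- tibble::tibble(
    k = grid,
    log_k = log(grid),
    mean_surplus = vapply(per_k, `[[`, numeric(1), "mean"),
    sd_surplus = vapply(per_k, `[[`, numeric(1), "sd")
  )
  best <- max(tab$k[tab$mean_surplus >= max(tab$mean_surplus) - 1e-9])
  structure(list(best_k = best, table = tab, n_episodes = n_episodes),
            class = "cpr_calibration")
}

#' @export
print.cpr_calibration <- function(x, ...) {
  cat(sprintf("<cpr_calibration> best k = %.4g (log k = %.3g) over %d candidates, %d episodes each\n",
              x$best_k, log(x$best_k), nrow(x$table), x$n_episodes))
  invisible(x)
}

#' Resolve a mechanism from a name and parameters
#'
#' Accepts the names used in run configs: `equal`, `mixed`, `proportional`,
#' `random`, `weighted` (with `w`, optional `residual_fraction`),
#' `interpolating` (with `k`).
#'
#' @param name Mechanism name.
#' @param ... Parameters passed to the mechanism constructor.
#' @return A `cpr_mechanism`.
#' @export
mechanism_by_name <- function(name, ...) {
  switch(name,
    equal = mechanism_equal(),
    mixed = mechanism_mixed(),
    proportional = mechanism_proportional(),
    random = mechanism_random(),
    weighted = mechanism_weighted(...),
    interpolating = mechanism_interpolating(...),
    stop(sprintf("unknown mechanism '%s'", name), call. = FALSE)
  )
}
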