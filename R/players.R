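#' Construct a player policy
#'
#' A player observes, each round, the offers made to everyone in the current
#' round, everyone's contributions from the previous round, and the current
#' pool size, and returns its own contribution (between 0 and its own offer;
#' forced to 0 when the offer is below one unit). Per-episode state is
#' threaded functionally like for mechanisms.
#'
#' @param id Character identifier.
#' @param reset `function(config, own_index)` returning initial state.
#' @param act `function(state, offers_all, prev_contribs_all, pool,
#'   own_index, config)` returning `list(contribution, state)`.
#' @return A `cpr_player` object.
#' @export
new_player <- function(id, reset = function(config, own_index) NULL, act) {
  structure(list(id = id, reset = reset, act = act), class = "cpr_player")
}

#' @export
print.cpr_player <- function(x, ...) {
  cat(sprintf("<cpr_player> %s\n", x$id)); invisible(x)
}

# Draw a reciprocation fraction around `mean_frac` with truncated-normal
# noise; noise is on the fraction (not the amount) so contract bounds hold.
noisy_fraction <- function(mean_frac, noise_sd) {
  if (noise_sd <= 0) return(mean_frac)
  min(max(stats::rnorm(1L, mean_frac, noise_sd), 0), 1)
}

#' Sustainer archetype
#'
#' Always reciprocates the optimal sustainable fraction `1 / (1 + r)` of its
#' offer, so that the returned amount `(1 + r) c` exactly replaces the offer.
#' With `noise_sd > 0` the fraction is perturbed by truncated Gaussian noise
#' each round.
#'
#' @param noise_sd Standard deviation of the per-round fraction noise.
#' @return A `cpr_player`.
#' @export
player_sustainer <- function(noise_sd = 0) {
  force(noise_sd)
  new_player(
    id = if (noise_sd > 0) sprintf("sustainer(sd=%g)", noise_sd) else "sustainer",
    act = function(state, offers_all, prev_contribs_all, pool, own_index, config) {
      f <- noisy_fraction(1 / (1 + config$r), noise_sd)
      list(contribution = offers_all[own_index] * f, state = state)
    })
}

#' Free-rider archetype
#'
#' Reciprocates `base_fraction` of its offer (0 by default: pure defection).
#' With `cooperate_rounds > 0` it plays as a sustainer for that many opening
#' rounds before switching to defection, which lets fixture data contain a
#' defection event at a controlled time.
#'
#' @param base_fraction Fraction reciprocated once defecting, in `[0, 1]`.
#' @param cooperate_rounds Number of opening rounds played sustainably.
#' @return A `cpr_player`.
#' @export
player_free_rider <- function(base_fraction = 0, cooperate_rounds = 0L) {
  force(base_fraction); force(cooperate_rounds)
  new_player(
    id = sprintf("free_rider(f=%g%s)", base_fraction,
                 if (cooperate_rounds > 0) sprintf(",coop=%d", cooperate_rounds) else ""),
    reset = function(config, own_index) list(t = 0L),
    act = function(state, offers_all, prev_contribs_all, pool, own_index, config) {
      f <- if (state$t < cooperate_rounds) 1 / (1 + config$r) else base_fraction
      list(contribution = offers_all[own_index] * f,
           state = list(t = state$t + 1L))
    })
}

# Others' reciprocation fractions from the previous round, counting only
# co-players whose previous offer was at least one unit (a forced zero under
# the sub-unit rule carries no behavioural signal).
others_fractions <- function(prev_offers, prev_contribs, own_index, threshold) {
  idx <- setdiff(seq_along(prev_offers), own_index)
  idx <- idx[prev_offers[idx] >= threshold]
  if (!length(idx)) return(NULL)
  prev_contribs[idx] / prev_offers[idx]
}

#' Conditional-cooperator archetype
#'
#' Reciprocates its offer times the mean of the other players' reciprocation
#' fractions observed on the previous round (clipped to `[0, 1]`). On the
#' opening round, and whenever no co-player made an observable choice, it
#' uses its current target, initialised to the sustainable fraction
#' `1 / (1 + r)`.
#'
#' @param noise_sd Standard deviation of truncated Gaussian noise on the
#'   fraction.
#' @return A `cpr_player`.
#' @export
player_conditional <- function(noise_sd = 0) {
  force(noise_sd)
  new_player(
    id = if (noise_sd > 0) sprintf("conditional(sd=%g)", noise_sd) else "conditional",
    reset = function(config, own_index)
      list(target = 1 / (1 + config$r), prev_offers = NULL),
    act = function(state, offers_all, prev_contribs_all, pool, own_index, config) {
      target <- state$target
      if (!is.null(state$prev_offers)) {
        fr <- others_fractions(state$prev_offers, prev_contribs_all,
                               own_index, config$offer_unit_threshold)
        if (!is.null(fr)) target <- min(max(mean(fr), 0), 1)
      }
      f <- noisy_fraction(target, noise_sd)
      list(contribution = offers_all[own_index] * f,
           state = list(target = target, prev_offers = offers_all))
    })
}

#' Grim-trigger archetype
#'
#' Reciprocates the sustainable fraction until it observes any co-player's
#' reciprocation fraction fall below `trigger_threshold`; from then on it
#' contributes 0 forever, regardless of later behaviour. The trigger depends
#' on the whole history, so predicting this archetype requires memory.
#'
#' @param trigger_threshold Fraction below which a co-player's reciprocation
#'   counts as defection.
#' @param noise_sd Standard deviation of fraction noise while cooperative.
#' @return A `cpr_player`.
#' @export
player_grim <- function(trigger_threshold = 0.1, noise_sd = 0) {
  force(trigger_threshold); force(noise_sd)
  new_player(
    id = sprintf("grim(th=%g)", trigger_threshold),
    reset = function(config, own_index)
      list(triggered = FALSE, prev_offers = NULL),
    act = function(state, offers_all, prev_contribs_all, pool, own_index, config) {
      triggered <- state$triggered
      if (!triggered && !is.null(state$prev_offers)) {
        fr <- others_fractions(state$prev_offers, prev_contribs_all,
                               own_index, config$offer_unit_threshold)
        if (!is.null(fr) && any(fr < trigger_threshold)) triggered <- TRUE
      }
      f <- if (triggered) 0 else noisy_fraction(1 / (1 + config$r), noise_sd)
      list(contribution = offers_all[own_index] * f,
           state = list(triggered = triggered, prev_offers = offers_all))
    })
}

#' Player archetype by name
#'
#' @param kind One of `"sustainer"`, `"free_rider"`, `"conditional"`,
#'   `"grim"`.
#' @param ... Parameters for the archetype constructor; values may be
#'   zero-argument functions, called (with the current RNG stream) at
#'   construction time so populations can randomise parameters per game.
#' @return A `cpr_player`.
#' @export
player_by_name <- function(kind, ...) {
  args <- lapply(list(...), function(a) if (is.function(a)) a() else a)
  ctor <- switch(kind,
    sustainer = player_sustainer,
    free_rider = player_free_rider,
    conditional = player_conditional,
    grim = player_grim,
    stop(sprintf("unknown archetype '%s'", kind), call. = FALSE))
  do.call(ctor, args)
}

#' Define a player population
#'
#' A population is a list of archetype entries, each either a fixed `count`
#' (counts must sum to `p`) or a sampling probability `prob`. Entries are
#' lists `list(kind =, count = / prob =, ...)` with remaining fields passed
#' to the archetype constructor (zero-argument functions are resolved per
#' sampled player).
#'
#' @param ... Archetype entries.
#' @return A `cpr_population` object.
#' @examples
#' pop <- population(
#'   list(kind = "sustainer", count = 2, noise_sd = 0.05),
#'   list(kind = "free_rider", count = 2)
#' )
#' @export
population <- function(...) {
  entries <- list(...)
  stopifnot(length(entries) >= 1)
  for (e in entries) {
    if (is.null(e$kind)) stop("each population entry needs a 'kind'", call. = FALSE)
    if (is.null(e$count) && is.null(e$prob))
      stop("each population entry needs 'count' or 'prob'", call. = FALSE)
  }
  structure(entries, class = "cpr_population")
}

#' Sample a player set from a population
#'
#' @param pop A [population()].
#' @param config A [game_config()].
#' @param seed Optional seed (caller's RNG preserved).
#' @return A list of `p` `cpr_player` objects in shuffled slot order.
#' @export
sample_players <- function(pop, config, seed = NULL) {
  stopifnot(inherits(pop, "cpr_population"))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  specs <- sample_player_specs(pop, config)
  lapply(specs, function(sp)
    do.call(player_by_name, c(list(kind = sp$kind), sp$args)))
}

# sample archetype kinds + resolved constructor args for the p slots
# (shared between the plain and the differentiable player builders)
sample_player_specs <- function(pop, config) {
  counts <- vapply(pop, function(e) if (is.null(e$count)) NA_real_ else e$count, numeric(1))
  if (all(!is.na(counts))) {
    if (sum(counts) != config$p)
      stop("population counts must sum to p", call. = FALSE)
    kinds_idx <- rep(seq_along(pop), times = counts)
  } else {
    probs <- vapply(pop, function(e) if (is.null(e$prob)) 0 else e$prob, numeric(1))
    kinds_idx <- sample(seq_along(pop), config$p, replace = TRUE, prob = probs)
  }
  kinds_idx <- sample(kinds_idx)   # shuffle slot assignment
  lapply(kinds_idx, function(j) {
    e <- pop[[j]]
    args <- lapply(e[setdiff(names(e), c("kind", "count", "prob"))],
                   function(a) if (is.function(a)) a() else a)
    list(kind = e$kind, args = args)
  })
}

#' Generate fixture episode logs
#'
#' Produces a corpus of synthetic gameplay for training and analysis with no
#' external data: for each game a mechanism is drawn from `mechanism_specs`
#' and a player set from the population, then an episode is run. A spec entry
#' may be a `cpr_mechanism`, a name accepted by [mechanism_by_name()], or a
#' list `list(name =, ...)` whose parameter values may be zero-argument
#' functions resolved per game (e.g. `w = function() runif(1)` for the
#' randomly mixed baseline family used during data collection).
#'
#' @param pop A [population()].
#' @param mechanism_specs List of mechanism specs (sampled uniformly).
#' @param n_games Number of games.
#' @param config A [game_config()].
#' @param seed Integer seed; the whole corpus is reproducible.
#' @return A list of `episode_log`s (with `game_index` set to the game
#'   number within the corpus).
#' @export
generate_fixture_logs <- function(pop, mechanism_specs, n_games,
                                  config = game_config(), seed = 1L) {
  if (n_games == 0) return(list())
  if (inherits(mechanism_specs, "cpr_mechanism") || !is.list(mechanism_specs) ||
      !is.null(mechanism_specs$name))
    mechanism_specs <- list(mechanism_specs)
  resolve_mech <- function(spec) {
    if (inherits(spec, "cpr_mechanism")) return(spec)
    if (is.character(spec)) return(mechanism_by_name(spec))
    args <- lapply(spec[setdiff(names(spec), "name")],
                   function(a) if (is.function(a)) a() else a)
    do.call(mechanism_by_name, c(list(name = spec$name), args))
  }
  lapply(seq_len(n_games), function(g) {
    gseed <- seed + g
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(gseed * 2L + 1L)
    spec <- mechanism_specs[[sample.int(length(mechanism_specs), 1L)]]
    mech <- resolve_mech(spec)
    players <- sample_players(pop, config)
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
    run_episode(mech, players, config, seed = gseed, game_index = g)
  })
}
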