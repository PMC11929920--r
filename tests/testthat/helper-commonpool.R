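# shared fixtures: all built in code at test time

# a mid-game state with chosen previous contributions
mid_state <- function(R = 100, c_prev = c(10, 0, 0, 10), e_prev = NULL,
                      t = 1L, config = game_config()) {
  st <- init_state(config)
  st$t <- as.integer(t)
  st$R <- R
  st$prev_contributions <- c_prev
  st$prev_offers <- if (is.null(e_prev)) pmax(c_prev, 1) else e_prev
  st
}

# O(n^2) pairwise-difference Gini oracle
gini_oracle <- function(x) {
  n <- length(x)
  if (mean(x) == 0) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

four <- function(p) replicate(4, p, simplify = FALSE)

sustainer_team <- function() four(player_sustainer())
free_rider_team <- function() four(player_free_rider())

# build an episode_log by hand from offer/contribution matrices
manual_log <- function(offers, contributions, config = game_config(p = ncol(offers))) {
  state <- init_state(config)
  recs <- vector("list", nrow(offers))
  for (t in seq_len(nrow(offers))) {
    step <- apply_round(state, offers[t, ], contributions[t, ], config)
    recs[[t]] <- step$record
    state <- step$state
  }
  structure(list(
    config = config, mechanism_id = "manual",
    player_ids = rep("manual", config$p), seed = NA_integer_,
    game_index = 1L, sampled_length = nrow(offers),
    offers = offers, contributions = contributions,
    pool_before = vapply(recs, function(r) r$pool_before, numeric(1)),
    pool_after = vapply(recs, function(r) r$pool_after, numeric(1)),
    retained = vapply(recs, function(r) r$retained, numeric(1)),
    depleted_at = state$depleted_at
  ), class = "episode_log")
}

# a player that replays a fixed contribution sequence
scripted_player <- function(contribs) {
  force(contribs)
  new_player("scripted",
    reset = function(config, own_index) list(t = 0L),
    act = function(state, offers_all, prev_contribs_all, pool, own_index, config) {
      t <- state$t + 1L
      c_t <- if (t <= length(contribs)) contribs[t] else 0
      list(contribution = min(c_t, offers_all[own_index]), state = list(t = t))
    })
}

# a mechanism that replays fixed offer rows
scripted_mechanism <- function(offer_matrix) {
  force(offer_matrix)
  new_mechanism("scripted",
    reset = function(config) list(t = 0L),
    act = function(state, game_state, config) {
      t <- state$t + 1L
      offs <- pmin(offer_matrix[min(t, nrow(offer_matrix)), ], game_state$R)
      if (sum(offs) > game_state$R) offs <- offs * game_state$R / sum(offs)
      list(offers = offs, retained = game_state$R - sum(offs),
           state = list(t = t))
    })
}
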