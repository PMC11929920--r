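test_that("initial state starts at the full pool with zeroed history", {
  st <- init_state(game_config(p = 4, R0 = 200, r = 0.4))
  expect_equal(st$R, 200)
  expect_equal(st$t, 0L)
  expect_equal(st$prev_offers, rep(0, 4))
  expect_equal(st$prev_contributions, rep(0, 4))
  expect_true(is.na(st$depleted_at))

  expect_equal(init_state(game_config(R0 = 1))$R, 1)
  expect_equal(init_state(game_config(p = 1))$R, 200)  # degenerate single player
  expect_error(game_config(R0 = -5), "R0")
  expect_error(game_config(min_rounds = 25, end_prob = 0), "end_prob")
})

test_that("pool update follows R' = min(R0, R - sum(e) + (1+r) sum(c))", {
  cfg1 <- game_config(p = 1)
  out <- apply_round(init_state(cfg1), 2, 1, cfg1)
  expect_equal(out$record$surpluses[[1]], 1)        # keeps 1 of the 2 received
  expect_equal(out$state$R, 200 - 2 + 1.4 * 1)      # pool credited (1+r)c = 1.4

  cfg <- game_config()
  st <- mid_state(R = 150)
  out <- apply_round(st, rep(10, 4), rep(10, 4), cfg)
  expect_equal(out$state$R, 166)                     # -40 + 56 = +16

  st$R <- 195
  out <- apply_round(st, rep(10, 4), rep(10, 4), cfg)
  expect_equal(out$state$R, 200)                     # cap binds at R0

  st$R <- 100
  out <- apply_round(st, rep(25, 4), rep(0, 4), cfg)
  expect_equal(out$state$R, 0)
  expect_equal(out$state$depleted_at, st$t)
})

test_that("round validation names the offending player", {
  cfg <- game_config()
  st <- init_state(cfg)
  expect_error(apply_round(st, c(-1, 0, 0, 0), rep(0, 4), cfg), "player 1")
  expect_error(apply_round(st, rep(100, 4), rep(0, 4), cfg), "exceeding the pool")
  expect_error(apply_round(st, rep(10, 4), c(0, 11, 0, 0), cfg), "player 2")
  icfg <- game_config(integer_contributions = TRUE)
  expect_error(apply_round(st, rep(10, 4), c(0, 0, 1.5, 0), icfg), "player 3")
})

test_that("full reciprocation at 1/(1+r) is a replenishment fixed point", {
  cfg <- game_config()
  out <- apply_round(init_state(cfg), rep(50, 4), rep(50, 4) / 1.4, cfg)
  expect_equal(out$state$R, 200)
  log <- run_episode(mechanism_equal(), sustainer_team(), cfg, seed = 1)
  expect_equal(episode_pool(log), rep(200, 40))
})

test_that("episode length sampling follows the termination rule", {
  expect_equal(sample_episode_length(game_config(horizon = 40)), 40)
  geo1 <- game_config(min_rounds = 25, end_prob = 1)
  expect_equal(sample_episode_length(geo1), 25)
  geo <- game_config(min_rounds = 25, end_prob = 0.2)
  set.seed(42)
  draws <- replicate(1e5, sample_episode_length(geo))
  expect_equal(mean(draws), 25 + 0.8 / 0.2, tolerance = 0.01)  # 29 +- MC error
  expect_true(all(draws >= 25))
})

test_that("equal split among pure free riders exhausts the pool in one round", {
  cfg <- game_config()
  log <- run_episode(mechanism_equal(), free_rider_team(), cfg, seed = 1)
  expect_equal(log$offers[1, ], rep(50, 4))
  expect_equal(sum(log$contributions), 0)
  expect_equal(episode_pool(log), rep(0, 40))
  expect_equal(sum(episode_surpluses(log)), 200)
  # after depletion all offers, contributions and surpluses stay at zero
  expect_equal(sum(log$offers[-1, ]), 0)
})

test_that("episodes are bitwise reproducible under a fixed seed", {
  cfg <- game_config(horizon = 15)
  pls <- function() list(player_sustainer(noise_sd = 0.1), player_free_rider(),
                         player_conditional(noise_sd = 0.05), player_grim())
  a <- run_episode(mechanism_random(), pls(), cfg, seed = 99)
  b <- run_episode(mechanism_random(), pls(), cfg, seed = 99)
  expect_identical(a, b)
  c <- run_episode(mechanism_random(), pls(), cfg, seed = 100)
  expect_false(identical(a$offers, c$offers))
})

test_that("episode logs satisfy the pool-arithmetic invariants", {
  cfg <- game_config(horizon = 25)
  pop_players <- list(player_sustainer(noise_sd = 0.1), player_free_rider(),
                      player_conditional(noise_sd = 0.1), player_grim())
  for (s in 1:5) {
    mech <- list(mechanism_random(), mechanism_mixed(),
                 mechanism_interpolating(22))[[1 + s %% 3]]
    log <- run_episode(mech, pop_players, cfg, seed = s)
    expect_true(all(log$pool_after <= cfg$R0 + 1e-9))
    expect_true(all(log$pool_after >= 0))
    # conservation: offers + retained = pool before the round
    expect_equal(rowSums(log$offers) + log$retained, log$pool_before,
                 tolerance = 1e-9)
    # closed-form update
    expect_equal(log$pool_after,
                 pmin(cfg$R0, log$pool_before - rowSums(log$offers) +
                        1.4 * rowSums(log$contributions)),
                 tolerance = 1e-9)
    expect_true(all(log$contributions <= log$offers + 1e-9))
    # sub-unit offers force zero contributions
    expect_true(all(log$contributions[log$offers < 1] == 0))
  }
})

test_that("depletion truncates the episode only when configured", {
  cfg_t <- game_config(truncate_on_depletion = TRUE)
  log <- run_episode(mechanism_equal(), free_rider_team(), cfg_t, seed = 1)
  expect_equal(episode_length(log), 1L)
  expect_equal(log$depleted_at, 0L)      # 0-based round index of depletion
})

test_that("integer mode floors contributions to whole units", {
  cfg <- game_config(integer_contributions = TRUE)
  log <- run_episode(mechanism_equal(), sustainer_team(), cfg, seed = 1)
  expect_true(all(log$contributions == floor(log$contributions)))
  expect_equal(log$contributions[1, ], rep(floor(50 / 1.4), 4))
})

test_that("consecutive-game sessions reset the pool between games", {
  cfg <- game_config(horizon = 5, n_consecutive_games = 3L)
  logs <- run_session(mechanism_equal(), free_rider_team(), cfg, seed = 5)
  expect_length(logs, 3L)
  expect_equal(vapply(logs, function(l) l$game_index, integer(1)), 1:3)
  for (l in logs) expect_equal(l$pool_before[1], 200)
})

test_that("tidy episode view carries one row per player per round", {
  log <- run_episode(mechanism_equal(), sustainer_team(),
                     game_config(horizon = 3), seed = 1)
  tab <- as_tibble(log)
  expect_equal(nrow(tab), 12L)
  expect_named(tab, c("game", "trial", "player", "offer", "contribution",
                      "surplus", "pool_before", "pool_after", "retained"))
  expect_equal(tab$surplus, tab$offer - tab$contribution)
})

test_that("the sustainable keep fraction is r/(1+r), printed as 29%", {
  expect_equal(sustainable_keep_fraction(0.4), 0.4 / 1.4)
  expect_equal(round(100 * sustainable_keep_fraction(0.4)), 29)
})
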