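test_that("gini matches the pairwise oracle and its closed-form cases", {
  expect_equal(gini(c(5, 5, 5, 5)), 0)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75)
  expect_equal(gini(rep(0, 4)), 0)          # collapse: nobody gets anything
  expect_error(gini(c(1, -1)), "non-negative")
  set.seed(5)
  for (i in 1:200) {
    x <- runif(sample(2:100, 1), 0, 10)
    expect_equal(gini(x), gini_oracle(x), tolerance = 1e-12)
    expect_equal(gini(2 * x), gini(x), tolerance = 1e-12)  # scale invariance
  }
})

test_that("episode metrics summarise sustained and collapsed games", {
  cfg <- game_config()
  sus <- run_episode(mechanism_equal(), sustainer_team(), cfg, seed = 1)
  m <- episode_metrics(sus)
  expect_equal(m$depletion_trial, 40L)
  expect_true(m$sustained)
  expect_equal(m$surplus_gini, 0)
  expect_equal(m$total_surplus, 40 * 200 * 0.4 / 1.4, tolerance = 1e-9)

  fr <- run_episode(mechanism_equal(), free_rider_team(), cfg, seed = 1)
  mf <- episode_metrics(fr)
  expect_equal(mf$total_surplus, 200)
  expect_equal(mf$depletion_trial, 1L)
  expect_false(mf$sustained)
  expect_equal(mf$active_players, 4 / 40)   # only the opening round is active
})

test_that("per-player aggregation feeds the surplus Gini", {
  offers <- matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE)
  contribs <- matrix(0, 3, 2)
  log <- manual_log(offers, contribs, game_config(p = 2))
  m <- episode_metrics(log)
  expect_equal(m$per_player_surplus, c(3, 0))
  expect_equal(m$surplus_gini, 0.5)   # pairwise oracle: |3-0|/(2*2*1.5)
})

test_that("metrics are invariant under player relabelling", {
  cfg <- game_config(horizon = 15)
  players <- list(player_sustainer(), player_free_rider(),
                  player_conditional(), player_grim())
  log <- run_episode(mechanism_mixed(), players, cfg, seed = 3)
  perm <- c(3, 1, 4, 2)
  plog <- log
  plog$offers <- log$offers[, perm]
  plog$contributions <- log$contributions[, perm]
  m1 <- episode_metrics(log); m2 <- episode_metrics(plog)
  expect_equal(m2$total_surplus, m1$total_surplus)
  expect_equal(m2$surplus_gini, m1$surplus_gini)
  expect_equal(m2$active_players, m1$active_players)
  expect_equal(m2$per_player_surplus, m1$per_player_surplus[perm])
})

test_that("exclusion events follow the hand-traced runs", {
  mk_log <- function(o1) {
    offers <- cbind(o1, 50, 50, 50)
    manual_log(offers, offers * 0, game_config(R0 = 10000))
  }
  ev <- exclusion_events(mk_log(c(50, 0.5, 0.2, 30, 40, 40)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_trial, 2L)
  expect_equal(ev$duration, 2L)
  expect_true(ev$reincluded)

  expect_equal(nrow(exclusion_events(mk_log(rep(50, 6)))), 0L)

  ev2 <- exclusion_events(mk_log(c(rep(50, 38), 0, 0)))
  expect_equal(ev2$start_trial, 39L)
  expect_equal(ev2$duration, 2L)
  expect_false(ev2$reincluded)

  # sub-threshold from the very first trial is a poverty start, not an exclusion
  ev3 <- exclusion_events(mk_log(c(0, 0, 50, 50, 0, 50)))
  expect_equal(ev3$start_trial, 5L)
  expect_equal(ev3$duration, 1L)
})

test_that("exclusion durations partition the sub-threshold trials", {
  set.seed(8)
  for (i in 1:20) {
    offers <- matrix(sample(c(0, 0.5, 2, 50), 40 * 4, replace = TRUE), 40, 4)
    log <- manual_log(offers, offers * 0, game_config(R0 = 1e5))
    ev <- exclusion_events(log)
    for (pl in 1:4) {
      inc <- offers[, pl] >= 1
      idx <- 2:length(inc)
      # sub-unit trials with at least one inclusion somewhere before them
      expected <- sum(!inc[idx] & cumsum(inc)[idx - 1] > 0)
      got <- sum(ev$duration[ev$player == pl])
      expect_equal(got, expected)
    }
  }
})

test_that("lag regressions recover an exact lag-minus-1 rule", {
  set.seed(6)
  T_len <- 30
  # contributions are exogenous; offers follow offer_t = 2 * c_{t-1} exactly
  logs <- lapply(1:4, function(g) {
    contribs <- matrix(runif(T_len * 4, 0, 5), T_len, 4)
    offers <- matrix(5, T_len, 4)
    offers[2:T_len, ] <- 2 * contribs[1:(T_len - 1), ]
    l <- manual_log(offers, contribs * 0, game_config(R0 = 1e6))
    l$contributions <- contribs
    l
  })
  fit <- lagged_offer_regression(logs)
  w <- tidy(fit)
  expect_equal(w$weight[w$lag == -1], 2, tolerance = 1e-8)
  expect_equal(max(abs(w$weight[w$lag != -1])), 0, tolerance = 1e-8)
  expect_equal(glance(fit)$dominant_lag, -1L)
})

test_that("constant offers yield all-zero weights under the zero-variance rule", {
  offers <- matrix(10, 20, 4)
  contribs <- matrix(5, 20, 4)
  log <- manual_log(offers, pmin(contribs, offers), game_config(R0 = 1e4))
  fit <- lagged_offer_regression(list(log))
  expect_equal(tidy(fit)$weight, rep(0, 9))
})

test_that("the proportional mechanism's lag profile peaks at lag -1", {
  cfg <- game_config()
  logs <- lapply(1:6, function(s)
    run_episode(mechanism_proportional(),
                list(player_sustainer(noise_sd = 0.15),
                     player_conditional(noise_sd = 0.15),
                     player_sustainer(noise_sd = 0.15),
                     player_conditional(noise_sd = 0.15)),
                cfg, seed = 20 + s, game_index = s))
  fit <- lagged_offer_regression(logs)
  w <- tidy(fit)
  expect_equal(w$lag[which.max(abs(w$weight))], -1L)
  expect_gt(abs(w$weight[w$lag == -1]), 2 * max(abs(w$weight[w$lag != -1])))
})

test_that("condition summaries split sustained from depleted games", {
  cfg <- game_config()
  logs <- c(
    lapply(1:2, function(s) run_episode(mechanism_equal(), sustainer_team(),
                                        cfg, seed = s, game_index = s)),
    list(run_episode(mechanism_equal(), free_rider_team(), cfg, seed = 3,
                     game_index = 3)))
  sm <- summarize_condition(logs)
  expect_equal(sm$means$n_games, c(3L, 2L, 1L))
  all_row <- sm$means[sm$means$subset == "all", ]
  expect_equal(all_row$mean_surplus,
               mean(sm$per_game$total_surplus))
  dep <- sm$means[sm$means$subset == "depleted", ]
  expect_equal(dep$mean_surplus, 200)
  expect_equal(dep$mean_depletion, 1)
  # two identical sustained games: zero variance, correlation undefined
  expect_true(is.na(sm$means$cor_surplus_gini[sm$means$subset == "sustained"]))
})

test_that("three-game summaries match hand-computed means", {
  mk <- function(surplus_per_round) {
    offers <- matrix(surplus_per_round, 2, 2)
    manual_log(offers, offers * 0, game_config(p = 2, R0 = 1e4))
  }
  logs <- list(mk(1), mk(2), mk(3))
  for (g in 1:3) logs[[g]]$game_index <- g
  sm <- summarize_condition(logs)
  expect_equal(sm$means$mean_surplus[1], mean(c(4, 8, 12)))
})

test_that("offer gini by pool pairs each trial's equality with its pool", {
  cfg <- game_config(horizon = 5)
  logs <- list(run_episode(mechanism_proportional(),
                           list(player_sustainer(), player_free_rider(),
                                player_sustainer(), player_sustainer()),
                           cfg, seed = 2))
  tab <- offer_gini_by_pool(logs)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$offer_gini[1], 0)     # equal opening round
  expect_gt(tab$offer_gini[2], 0)        # the defector is cut out
})
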