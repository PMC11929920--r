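test_that("the game state maps to a fully connected directed graph", {
  cfg <- game_config()
  g <- build_graph(init_state(cfg), cfg)
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(length(g$senders), 12L)           # p(p-1) directed edges
  expect_equal(ncol(g$edges), 0L)                # initially empty attributes
  expect_equal(g$global[1], 1)                   # full pool / normaliser
  expect_true(all(g$nodes[, "pool"] == 1))
  expect_true(all(g$nodes[, c(1, 2)] == 0))      # round 0: no history
  st <- mid_state(R = 100, c_prev = c(1, 2, 3, 4), e_prev = c(4, 3, 2, 1))
  g2 <- build_graph(st, cfg)
  expect_equal(g2$nodes[, "prev_offer"], c(4, 3, 2, 1) / 200)
  expect_equal(g2$global[1], 0.5)
})

test_that("a graph block is permutation equivariant with an invariant global", {
  set.seed(10)
  W_e <- matrix(runif(7 * 5, -1, 1), 7, 5)
  W_v <- matrix(runif(9 * 5, -1, 1), 9, 5)
  W_u <- matrix(runif(11 * 5, -1, 1), 11, 5)
  phis <- list(edge = function(x) pmax(x %*% W_e, 0),
               node = function(x) tanh(x %*% W_v),
               global = function(x) x %*% W_u)
  cfg <- game_config()
  st <- mid_state(R = 120, c_prev = c(5, 0, 9, 2), e_prev = c(10, 1, 9, 7))
  g <- build_graph(st, cfg)
  out <- gnn_block(phis, g)
  perm <- c(2, 4, 1, 3)
  stp <- st
  stp$prev_contributions <- st$prev_contributions[perm]
  stp$prev_offers <- st$prev_offers[perm]
  outp <- gnn_block(phis, build_graph(stp, cfg))
  expect_equal(outp$nodes, out$nodes[perm, ], tolerance = 1e-12)
  expect_equal(outp$global, out$global, tolerance = 1e-12)
  # identical node inputs give identical node outputs
  st_sym <- mid_state(R = 120, c_prev = rep(3, 4), e_prev = rep(10, 4))
  outs <- gnn_block(phis, build_graph(st_sym, cfg))
  expect_equal(outs$nodes, outs$nodes[c(2, 3, 4, 1), ], tolerance = 1e-12)
})

test_that("allocation weights form a simplex and open uniformly", {
  cfg <- game_config()
  for (s in 1:3) {
    mp <- mech_init_params(width = 6, gru = 4, proj = 6, seed = s)
    st0 <- init_state(cfg)
    fw <- mech_forward(mp, st0$prev_offers, st0$prev_contributions, st0$R,
                       matrix(0, 4, 4), cfg)
    expect_equal(sum(fw$weights), 1, tolerance = 1e-9)
    # symmetric round-0 inputs: the four player weights are equal
    expect_equal(fw$weights[1:4], rep(fw$weights[1], 4), tolerance = 1e-12)
  }
})

test_that("the full policy is permutation equivariant", {
  cfg <- game_config()
  set.seed(12)
  for (s in 1:3) {
    mp <- mech_init_params(width = 6, gru = 4, proj = 6, seed = 30 + s)
    e_prev <- runif(4, 0, 50); c_prev <- runif(4, 0, 30); R <- runif(1, 10, 200)
    h <- matrix(rnorm(16, sd = 0.3), 4, 4)
    fw <- mech_forward(mp, e_prev, c_prev, R, h, cfg)
    perm <- sample(4)
    fwp <- mech_forward(mp, e_prev[perm], c_prev[perm], R, h[perm, ], cfg)
    expect_equal(fwp$weights[1:4], fw$weights[perm], tolerance = 1e-12)
    expect_equal(fwp$weights[5], fw$weights[5], tolerance = 1e-12)
    expect_equal(fwp$h, fw$h[perm, ], tolerance = 1e-12)
  }
})

test_that("weights convert to feasible offers", {
  out <- offers_from_weights(rep(0.2, 5), 100)
  expect_equal(out$offers, rep(20, 4))
  expect_equal(out$retained, 20)
  out0 <- offers_from_weights(rep(0.2, 5), 0)
  expect_equal(out0$offers, rep(0, 4))
  w <- c(0.5, 0.1, 0.1, 0.1, 0.2)
  out2 <- offers_from_weights(w, 73)
  expect_equal(sum(out2$offers) + out2$retained, 73)
})

test_that("the graph mechanism is feasible at every round of a rollout", {
  cfg <- game_config(horizon = 15)
  for (recurrent in c(TRUE, FALSE)) {
    mp <- mech_init_params(width = 8, gru = 4, proj = 8, recurrent = recurrent,
                           seed = 7)
    players <- list(player_sustainer(), player_free_rider(),
                    player_conditional(), player_grim())
    log <- run_episode(mechanism_gnn(mp), players, cfg, seed = 2)
    expect_equal(rowSums(log$offers) + log$retained, log$pool_before,
                 tolerance = 1e-9)
    expect_true(all(log$offers >= 0))
    expect_equal(log$offers[1, ], rep(log$offers[1, 1], 4))  # uniform opening
  }
})

test_that("memoryless and recurrent variants share the tape forward pass", {
  cfg <- game_config()
  for (recurrent in c(TRUE, FALSE)) {
    mp <- mech_init_params(width = 5, gru = 3, proj = 5, recurrent = recurrent,
                           seed = 11)
    st <- mid_state(R = 90, c_prev = c(3, 0, 8, 1), e_prev = c(9, 1, 8, 4))
    h <- matrix(0.1, 4, 3)
    fw <- mech_forward(mp, st$prev_offers, st$prev_contributions, st$R, h, cfg)
    tape <- ad_tape()
    ptt <- commonpool:::params_to_tape(tape, mp$blocks)
    stc <- commonpool:::gnn_structures_ad(tape, 4)
    fw2 <- commonpool:::mech_forward_ad(
      ptt$nodes, mp, tape,
      ad_const(tape, matrix(st$prev_offers, 1)),
      ad_const(tape, matrix(st$prev_contributions, 1)),
      ad_const(tape, matrix(st$R, 1, 1)), ad_const(tape, h), cfg, stc)
    expect_equal(as.numeric(ad_value(fw2$weights)), fw$weights, tolerance = 1e-12)
    expect_equal(ad_value(fw2$h), fw$h, tolerance = 1e-12)
  }
})

test_that("mechanism training is deterministic and records checkpoints", {
  cfg <- game_config(horizon = 6)
  pop <- population(list(kind = "sustainer", count = 2),
                    list(kind = "free_rider", count = 2))
  tc <- mech_train_config(updates = 4L, batch = 1L, ckpt_every = 2L,
                          eval_episodes = 2L, width = 4L, gru = 3L, proj = 4L,
                          seed = 3L)
  f1 <- train_mechanism(pop, tc, cfg)
  f2 <- train_mechanism(pop, tc, cfg)
  expect_identical(f1$params$blocks, f2$params$blocks)
  expect_identical(f1$trace, f2$trace)
  expect_equal(vapply(f1$checkpoints, `[[`, integer(1), "step"), c(0L, 2L, 4L))
})

test_that("checkpoint selection maximises evaluation surplus, ties to later", {
  mk <- function(step, ev) list(step = step, params = list(step = step),
                                eval_surplus = ev)
  expect_equal(select_mechanism(list(mk(1L, 5)))$step, 1L)
  expect_equal(select_mechanism(list(mk(1L, 5), mk(2L, 9), mk(3L, 7)))$step, 2L)
  expect_equal(select_mechanism(list(mk(1L, 5), mk(2L, 5)))$step, 2L)
  expect_equal(select_mechanism(list(mk(1L, 1), mk(2L, 2), mk(3L, 3)))$step, 3L)
})
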