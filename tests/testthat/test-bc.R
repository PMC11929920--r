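test_that("the bin codec partitions proportion space and round-trips", {
  expect_equal(contribution_to_bin(7.3, 10, 10), 7L)
  expect_equal(contribution_to_bin(10, 10, 10), 9L)   # clamp at the top edge
  expect_equal(contribution_to_bin(0, 10, 10), 0L)
  expect_equal(contribution_to_bin(0, 0, 10), 0L)     # zero offer maps to bin 0
  expect_error(contribution_to_bin(11, 10, 10), "outside")
  expect_equal(bin_to_contribution(7, 0.5, 10, 10), 7.5)
  expect_equal(bin_to_contribution(0, 0, 10, 10), 0)
  set.seed(1)
  for (N in c(2:10, 25, 50)) {
    b <- sample(0:(N - 1), 20, replace = TRUE)
    u <- runif(20, 0, 0.999)
    e <- runif(20, 0.5, 60)
    expect_equal(contribution_to_bin(bin_to_contribution(b, u, e, N), e, N), b)
  }
})

test_that("observations are normalised and rotated to the focal player", {
  cfg <- game_config()
  obs <- bc_observation(c(10, 20, 30, 40), c(1, 2, 3, 4), 100, 2L, cfg)
  expect_length(obs, 9L)
  expect_equal(obs, c(20, 30, 40, 10, 2, 3, 4, 1, 100) / 200)
})

test_that("the clone forward pass is deterministic with uniform untrained logits", {
  cfg <- game_config()
  hyper <- bc_hyper(n_bins = 6, enc = c(8, 8), gru = 5, dec = c(8, 8), updates = 1)
  set.seed(2)
  params <- commonpool:::bc_init_params(hyper, cfg)
  obs <- matrix(runif(5 * 9), 5, 9)
  l1 <- bc_forward(params, obs, hyper)
  expect_equal(dim(l1), c(5L, 6L))                   # one logit row per step
  expect_identical(l1, bc_forward(params, obs, hyper))
  # zero weights: all-equal logits at every step
  zp <- rapply(params, function(m) m * 0, how = "replace")
  l0 <- bc_forward(zp, obs, hyper)
  expect_true(all(abs(l0 - l0[, 1]) < 1e-12))
})

test_that("an untrained clone scores ln N cross-entropy", {
  cfg <- game_config(horizon = 6)
  hyper <- bc_hyper(n_bins = 10, enc = c(8, 8), gru = 5, dec = c(8, 8))
  set.seed(3)
  params <- rapply(commonpool:::bc_init_params(hyper, cfg),
                   function(m) m * 0, how = "replace")
  logs <- generate_fixture_logs(population(list(kind = "sustainer", count = 4)),
                                "equal", 2, cfg, seed = 1)
  ds <- bc_dataset(logs, cfg)
  expect_equal(bc_cross_entropy(params, ds, hyper), log(10), tolerance = 1e-9)
})

test_that("training reduces the loss on sustainer data", {
  cfg <- game_config(horizon = 10)
  pop <- population(list(kind = "sustainer", count = 4, noise_sd = 0.03))
  logs <- generate_fixture_logs(pop, list(list(name = "weighted",
                                               w = function() runif(1))),
                                8, cfg, seed = 2)
  hyper <- bc_hyper(n_bins = 10, enc = c(16, 16), gru = 8, dec = c(16, 16),
                    batch = 16, updates = 120L, ckpt_every = 40L,
                    lr0 = 3e-3, seed = 4)
  fit <- train_bc(bc_dataset(logs, cfg), hyper, cfg)
  gl <- glance(fit)
  expect_lt(gl$final_loss, gl$first_loss)
  expect_lt(gl$final_loss, log(10))      # beats the uniform policy
  expect_equal(length(fit$checkpoints), 3L)
  # the modal bin at the sustainable fraction 1/1.4 is bin 7 of 10
  ds <- bc_dataset(logs, cfg)
  logits <- bc_forward(fit$params, ds$seqs[[1]]$obs, hyper)
  modal <- apply(logits, 1, which.max) - 1L
  expect_equal(as.integer(stats::median(modal)), 7L)
  expect_error(train_bc(structure(list(seqs = list(), config = cfg),
                                  class = "bc_dataset"), hyper, cfg),
               "empty")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- game_config(horizon = 6)
  logs <- generate_fixture_logs(population(list(kind = "sustainer", count = 4,
                                                noise_sd = 0.05)),
                                "equal", 3, cfg, seed = 5)
  hyper <- bc_hyper(n_bins = 5, enc = c(6, 6), gru = 4, dec = c(6, 6),
                    batch = 4, updates = 10L, ckpt_every = 5L, seed = 9)
  f1 <- train_bc(bc_dataset(logs, cfg), hyper, cfg)
  f2 <- train_bc(bc_dataset(logs, cfg), hyper, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("clone action modes follow their definitions", {
  cfg <- game_config()
  hyper <- bc_hyper(n_bins = 10, enc = c(6, 6), gru = 4, dec = c(6, 6))
  zp <- rapply(commonpool:::bc_init_params(hyper, cfg),
               function(m) m * 0, how = "replace")
  member <- list(params = zp, hyper = hyper)
  # all-equal logits: argmax ties break to the lowest bin (bin 0)
  pl <- bc_player(member, mode = "argmax_uniform")
  set.seed(1)
  r <- pl$act(pl$reset(cfg, 1L), c(10, 10, 10, 10), rep(0, 4), 200, 1L, cfg)
  expect_lt(r$contribution, 1)           # bin 0 of 10: c in [0, 1)
  # expectation under uniform softmax: e * mean((b + 0.5) / N) = e / 2
  ple <- bc_player(member, mode = "expectation")
  re <- ple$act(ple$reset(cfg, 1L), c(10, 10, 10, 10), rep(0, 4), 200, 1L, cfg)
  expect_equal(re$contribution, 5)
  # sub-unit offers force a zero action whatever the logits
  r0 <- ple$act(ple$reset(cfg, 1L), c(0.5, 10, 10, 10), rep(0, 4), 200, 1L, cfg)
  expect_equal(r0$contribution, 0)
})

test_that("ensembles keep the best-scoring checkpoints", {
  cfg <- game_config(horizon = 5)
  hyper <- bc_hyper(n_bins = 5, enc = c(6, 6), gru = 4, dec = c(6, 6))
  set.seed(6)
  cks <- lapply(1:3, function(i)
    list(step = i, params = commonpool:::bc_init_params(hyper, cfg), loss = 1))
  ens <- assemble_ensemble(cks, hyper, cfg, m = 2L, n_episodes = 2L, seed = 1)
  expect_s3_class(ens, "bc_ensemble")
  expect_length(ens$members, 2L)
  sc <- vapply(ens$members, `[[`, numeric(1), "score")
  expect_true(diff(sc) <= 0)             # ordered by score
  # single checkpoint: that checkpoint
  e1 <- assemble_ensemble(cks[1], hyper, cfg, m = 1L, n_episodes = 1L, seed = 1)
  expect_length(e1$members, 1L)
  # fixed-slot analysis mode pins members in order
  pls <- ensemble_players(e1, cfg, sample = FALSE)
  expect_length(pls, 4L)
})

test_that("sequences with forced sub-unit offers are masked out of the loss", {
  cfg <- game_config(horizon = 4)
  offers <- matrix(c(0.5, 10, 10, 10), 4, 4, byrow = TRUE)
  log <- manual_log(offers, offers * 0, game_config(R0 = 1e4))
  ds <- bc_dataset(list(log), cfg)
  expect_equal(ds$seqs[[1]]$mask, rep(FALSE, 4))   # player 1 never acts freely
  expect_equal(ds$seqs[[2]]$mask, rep(TRUE, 4))
})
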