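# Behavioural cloning of game players: recurrent probabilistic policies
# trained by supervised imitation on episode logs. The action head is a
# categorical-uniform distribution over N bins partitioning the proportion
# of the offer reciprocated.

#' Bin codec for the categorical-uniform action head
#'
#' The N bins partition the proportion space `[0, 1]` of the offer:
#' `contribution_to_bin()` maps a contribution to its bin index
#' (`floor(N * c / e)`, clamped to `N - 1` at `c = e`; an offer of 0 maps to
#' bin 0), and `bin_to_contribution()` inverts it by placing the
#' contribution uniformly within the bin, `c = e * (bin + u) / N`.
#'
#' @param c Contribution (vectorised), `0 <= c <= e`.
#' @param e Offer (vectorised).
#' @param N Number of bins (>= 2).
#' @param bin 0-based bin index.
#' @param u Uniform draw in `[0, 1)`.
#' @return `contribution_to_bin()`: integer bin in `0..N-1`;
#'   `bin_to_contribution()`: numeric contribution.
#' @examples
#' contribution_to_bin(7.3, 10, 10)      # 7
#' bin_to_contribution(7, 0.5, 10, 10)   # 7.5
#' @export
contribution_to_bin <- function(c, e, N) {
  stopifnot(N >= 2)
  if (any(c > e + 1e-9 * pmax(e, 1)) || any(c < -1e-12))
    stop("contribution outside [0, offer]", call. = FALSE)
  out <- ifelse(e <= 0, 0L, pmin(floor(N * c / e), N - 1L))
  as.integer(out)
}

#' @rdname contribution_to_bin
#' @export
bin_to_contribution <- function(bin, u, e, N) {
  stopifnot(all(bin >= 0), all(bin < N), all(u >= 0), all(u < 1))
  e * (bin + u) / N
}

#' Behavioural-clone hyperparameters
#'
#' Architecture: two fully connected encoder layers, a GRU memory core, two
#' fully connected decoder layers and a final linear projection onto the
#' `n_bins` logits. Training uses Adam with an exponentially annealed
#' learning rate (multiplied by `1 - decay` every `decay_every` updates,
#' floored at `lr_floor`); the reference recipe anneals 5e-4 by 0.05 every
#' 1000 steps to a 5e-6 floor. Defaults here are desk-scale; widths and the
#' update budget are fully configurable.
#'
#' @param n_bins Number of action bins N.
#' @param enc Encoder layer widths (length 2).
#' @param gru GRU hidden size; with `recurrent = FALSE` the memory core is
#'   replaced by a dense layer of the same width (the memoryless ablation).
#' @param dec Decoder layer widths (length 2).
#' @param recurrent Use the GRU memory core.
#' @param batch Sequences per update.
#' @param lr0,decay,decay_every,lr_floor Learning-rate schedule.
#' @param updates Total update steps.
#' @param ckpt_every Checkpoint interval in updates.
#' @param seed Seed for initialisation and batch sampling.
#' @return A `bc_hyper` list.
#' @export
bc_hyper <- function(n_bins = 10L, enc = c(64L, 64L), gru = 32L,
                     dec = c(64L, 64L), recurrent = TRUE,
                     batch = 64L, lr0 = 5e-4, decay = 0.05,
                     decay_every = 1000L, lr_floor = 5e-6,
                     updates = 2000L, ckpt_every = 500L, seed = 1L) {
  stopifnot(n_bins >= 2, length(enc) == 2, length(dec) == 2,
            gru >= 1, batch >= 1, updates >= 1)
  structure(list(n_bins = as.integer(n_bins), enc = as.integer(enc),
                 gru = as.integer(gru), dec = as.integer(dec),
                 recurrent = isTRUE(recurrent), batch = as.integer(batch),
                 lr0 = lr0, decay = decay, decay_every = as.integer(decay_every),
                 lr_floor = lr_floor, updates = as.integer(updates),
                 ckpt_every = as.integer(ckpt_every), seed = as.integer(seed)),
            class = "bc_hyper")
}

bc_obs_dim <- function(config) 2L * config$p + 1L

bc_init_params <- function(hyper, config) {
  d <- bc_obs_dim(config)
  params <- list(
    enc1 = dense_init(d, hyper$enc[1]),
    enc2 = dense_init(hyper$enc[1], hyper$enc[2]),
    dec1 = dense_init(hyper$gru, hyper$dec[1]),
    dec2 = dense_init(hyper$dec[1], hyper$dec[2]),
    out = dense_init(hyper$dec[2], hyper$n_bins)
  )
  params$core <- if (hyper$recurrent) gru_init(hyper$enc[2], hyper$gru)
                 else dense_init(hyper$enc[2], hyper$gru)
  params
}

#' Player-centred observation vector
#'
#' The 9-dimensional (at p = 4) observation: the current round's offers to
#' all players, everyone's previous-round contributions, and the pool size,
#' all divided by the normaliser (200 by default). Vectors are rotated so
#' the focal player occupies the first slot, matching an interface where
#' each player sees themselves as player 1.
#'
#' @param offers_all,prev_contribs_all Length-`p` vectors.
#' @param pool Current pool size.
#' @param own_index Focal player slot.
#' @param config A [game_config()].
#' @return Numeric vector of length `2p + 1`.
#' @export
bc_observation <- function(offers_all, prev_contribs_all, pool, own_index, config) {
  p <- config$p
  rot <- ((own_index - 1L + seq_len(p) - 1L) %% p) + 1L
  c(offers_all[rot], prev_contribs_all[rot], pool) / config$normalizer
}

#' Build a supervised dataset from episode logs
#'
#' One training sequence per player per game: per-step observations, the
#' focal offer and contribution, and a validity mask excluding rounds where
#' the focal offer is below the unit threshold (the action there is forced
#' to zero and carries no behavioural signal).
#'
#' @param logs List of `episode_log`s.
#' @param config A [game_config()]; defaults to the first log's config.
#' @return A `bc_dataset`: list of sequences with fields `obs` (T x (2p+1)),
#'   `e`, `c`, `mask`.
#' @export
bc_dataset <- function(logs, config = NULL) {
  stopifnot(length(logs) >= 1)
  if (is.null(config)) config <- logs[[1]]$config
  seqs <- list()
  for (log in logs) {
    T_len <- episode_length(log)
    p <- log$config$p
    for (i in seq_len(p)) {
      obs <- matrix(0, T_len, bc_obs_dim(config))
      for (t in seq_len(T_len)) {
        prev_c <- if (t == 1L) rep(0, p) else log$contributions[t - 1L, ]
        obs[t, ] <- bc_observation(log$offers[t, ], prev_c,
                                   log$pool_before[t], i, config)
      }
      seqs[[length(seqs) + 1L]] <- list(
        obs = obs,
        e = log$offers[, i],
        c = log$contributions[, i],
        mask = log$offers[, i] >= config$offer_unit_threshold
      )
    }
  }
  structure(list(seqs = seqs, config = config), class = "bc_dataset")
}

#' Forward pass of a behavioural clone over an observation sequence
#'
#' Deterministic: returns the per-step bin logits with the recurrent state
#' threaded through the sequence.
#'
#' @param params Clone parameters (as in a `bc_member`).
#' @param obs Observation matrix (T x obs_dim).
#' @param hyper The `bc_hyper` used to build `params`.
#' @return T x N matrix of logits.
#' @export
bc_forward <- function(params, obs, hyper) {
  T_len <- nrow(obs)
  h <- matrix(0, 1, hyper$gru)
  out <- matrix(0, T_len, hyper$n_bins)
  for (t in seq_len(T_len)) {
    st <- bc_step(params, obs[t, , drop = FALSE], h, hyper)
    out[t, ] <- st$logits
    h <- st$h
  }
  out
}

# one step, plain matrices; x is (B x obs_dim), h is (B x gru)
bc_step <- function(params, x, h, hyper) {
  z <- dense_fwd(x, params$enc1, "relu")
  z <- dense_fwd(z, params$enc2, "relu")
  h <- if (hyper$recurrent) gru_fwd(z, h, params$core)
       else dense_fwd(z, params$core, "relu")
  y <- dense_fwd(h, params$dec1, "relu")
  y <- dense_fwd(y, params$dec2, "relu")
  list(logits = dense_fwd(y, params$out, "linear"), h = h)
}

# tape version of bc_step
bc_step_ad <- function(pn, x, h, hyper) {
  z <- dense_fwd_ad(x, pn$enc1, "relu")
  z <- dense_fwd_ad(z, pn$enc2, "relu")
  h <- if (hyper$recurrent) gru_fwd_ad(z, h, pn$core)
       else dense_fwd_ad(z, pn$core, "relu")
  y <- dense_fwd_ad(h, pn$dec1, "relu")
  y <- dense_fwd_ad(y, pn$dec2, "relu")
  list(logits = dense_fwd_ad(y, pn$out, "linear"), h = h)
}

#' Train a behavioural clone
#'
#' Back-propagation through time minimising the masked cross-entropy between
#' the predicted bin distribution and the bin of the logged contribution,
#' with Adam and the annealed learning rate from the hyper block. Sequences
#' are mini-batched (grouped by length); checkpoints are saved periodically.
#'
#' @param data A [bc_dataset()] or a list of `episode_log`s.
#' @param hyper A [bc_hyper()].
#' @param config A [game_config()]; defaults to the dataset's.
#' @return A `bc_fit`: final `params`, `checkpoints` (list of
#'   `list(step, params, loss)`), `loss_trace` tibble, plus the hyper and
#'   config. Deterministic given `hyper$seed`.
#' @export
train_bc <- function(data, hyper = bc_hyper(), config = NULL) {
  if (!inherits(data, "bc_dataset")) data <- bc_dataset(data, config)
  if (is.null(config)) config <- data$config
  seqs <- data$seqs
  if (!length(seqs)) stop("empty training dataset", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(hyper$seed)
  params <- bc_init_params(hyper, config)
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  lens <- vapply(seqs, function(s) nrow(s$obs), integer(1))
  by_len <- split(seq_along(seqs), lens)
  N <- hyper$n_bins
  checkpoints <- list()
  losses <- numeric(hyper$updates)
  for (step in seq_len(hyper$updates)) {
    cls <- if (length(by_len) == 1L) by_len[[1]] else
      by_len[[sample.int(length(by_len), 1L,
                         prob = vapply(by_len, length, integer(1)))]]
    idx <- cls[sample.int(length(cls), min(hyper$batch, length(cls)),
                          replace = length(cls) < hyper$batch)]
    B <- length(idx)
    T_len <- nrow(seqs[[idx[1]]]$obs)
    params <- unflatten_params(flat, params)
    tape <- ad_tape()
    ptt <- params_to_tape(tape, params)
    h <- ad_const(tape, matrix(0, B, hyper$gru))
    loss <- NULL
    n_valid <- 0
    for (t in seq_len(T_len)) {
      X <- t(vapply(idx, function(j) seqs[[j]]$obs[t, ], numeric(ncol(seqs[[idx[1]]]$obs))))
      x <- ad_const(tape, X)
      st <- bc_step_ad(ptt$nodes, x, h, hyper)
      h <- st$h
      tgt <- vapply(idx, function(j)
        contribution_to_bin(seqs[[j]]$c[t], seqs[[j]]$e[t], N), integer(1))
      msk <- vapply(idx, function(j) seqs[[j]]$mask[t], logical(1))
      if (!any(msk)) next
      M <- matrix(0, B, N)
      M[cbind(which(msk), tgt[msk] + 1L)] <- 1
      logp <- ad_logsoftmax_rows(st$logits)
      loss_t <- ad_scale(ad_sum(ad_mul(logp, ad_const(tape, M))), -1)
      loss <- if (is.null(loss)) loss_t else ad_add(loss, loss_t)
      n_valid <- n_valid + sum(msk)
    }
    if (is.null(loss)) next
    loss <- ad_scale(loss, 1 / n_valid)
    losses[step] <- ad_value(loss)[1]
    grads <- ad_backward(loss, ptt$ids)
    names(grads) <- ptt$names
    lr <- lr_schedule(step, hyper$lr0, hyper$decay, hyper$decay_every, hyper$lr_floor)
    upd <- adam_step(flat, grads, opt, lr)
    flat <- upd$params
    opt <- upd$state
    if (step %% hyper$ckpt_every == 0L || step == hyper$updates) {
      recent <- losses[max(1L, step - hyper$ckpt_every + 1L):step]
      checkpoints[[length(checkpoints) + 1L]] <- list(
        step = step, params = unflatten_params(flat, params),
        loss = mean(recent[recent > 0]))
    }
  }
  structure(list(
    params = unflatten_params(flat, params),
    checkpoints = checkpoints,
    loss_trace = tibble::tibble(step = seq_len(hyper$updates), loss = losses),
    hyper = hyper, config = config
  ), class = "bc_fit")
}

#' @export
print.bc_fit <- function(x, ...) {
  cat(sprintf("<bc_fit> %d updates, %d checkpoints, final loss %.4f (ln N = %.4f)\n",
              x$hyper$updates, length(x$checkpoints),
              utils::tail(x$loss_trace$loss[x$loss_trace$loss > 0], 1),
              log(x$hyper$n_bins)))
  invisible(x)
}

#' Held-out cross-entropy of a clone on a dataset
#'
#' Mean masked cross-entropy (nats) of the clone's bin distribution against
#' the logged contributions. A uniform (untrained) policy scores `ln N`.
#'
#' @param params Clone parameters.
#' @param data A [bc_dataset()].
#' @param hyper The clone's `bc_hyper`.
#' @return Mean cross-entropy over valid steps.
#' @export
bc_cross_entropy <- function(params, data, hyper) {
  stopifnot(inherits(data, "bc_dataset"))
  N <- hyper$n_bins
  tot <- 0; n <- 0
  for (s in data$seqs) {
    logits <- bc_forward(params, s$obs, hyper)
    m <- logits - apply(logits, 1L, max)
    logp <- m - log(rowSums(exp(m)))
    tgt <- contribution_to_bin(s$c, s$e, N)
    keep <- which(s$mask)
    if (!length(keep)) next
    tot <- tot - sum(logp[cbind(keep, tgt[keep] + 1L)])
    n <- n + length(keep)
  }
  tot / n
}

#' Assemble a behavioural-clone ensemble
#'
#' Scores each checkpoint by simulation — mean total surplus in games where
#' four copies of the clone play under hand-coded baseline mechanisms, minus
#' `lambda` times its mean surplus under the random mechanism (clones that
#' merely exploit arbitrary allocations score badly) — and keeps the top
#' `m`. Checkpoints from several differently seeded fits can be pooled by
#' passing a combined list.
#'
#' @param checkpoints List of checkpoints (from one or more `bc_fit`s), or a
#'   `bc_fit`.
#' @param hyper The clones' `bc_hyper`.
#' @param config A [game_config()].
#' @param m Ensemble size.
#' @param lambda Weight of the random-mechanism penalty.
#' @param baselines Mechanisms used for the positive score.
#' @param n_episodes Episodes per mechanism per checkpoint.
#' @param seed Evaluation seed.
#' @return A `bc_ensemble`: members (each `list(params, hyper, score)`) in
#'   score order.
#' @export
assemble_ensemble <- function(checkpoints, hyper, config = game_config(),
                              m = 4L, lambda = 1,
                              baselines = list(mechanism_equal(),
                                               mechanism_mixed(),
                                               mechanism_proportional()),
                              n_episodes = 4L, seed = 1L) {
  if (inherits(checkpoints, "bc_fit")) checkpoints <- checkpoints$checkpoints
  stopifnot(length(checkpoints) >= 1)
  score_ckpt <- function(ck) {
    clone_players <- function() replicate(config$p,
      bc_player(list(params = ck$params, hyper = hyper), mode = "argmax_uniform"),
      simplify = FALSE)
    base_s <- mean(vapply(baselines, function(mech)
      mean(vapply(seq_len(n_episodes), function(k)
        sum(episode_surpluses(run_episode(mech, clone_players(), config,
                                          seed = seed + k))), numeric(1))),
      numeric(1)))
    rand_s <- mean(vapply(seq_len(n_episodes), function(k)
      sum(episode_surpluses(run_episode(mechanism_random(), clone_players(),
                                        config, seed = seed + 100L + k))),
      numeric(1)))
    base_s - lambda * rand_s
  }
  scores <- vapply(checkpoints, score_ckpt, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  keep <- ord[seq_len(min(m, length(ord)))]
  members <- lapply(keep, function(j)
    list(params = checkpoints[[j]]$params, hyper = hyper, score = scores[j]))
  structure(list(members = members, hyper = hyper), class = "bc_ensemble")
}

#' @export
print.bc_ensemble <- function(x, ...) {
  cat(sprintf("<bc_ensemble> %d members, scores: %s\n", length(x$members),
              paste(sprintf("%.1f", vapply(x$members, `[[`, numeric(1), "score")),
                    collapse = ", ")))
  invisible(x)
}

#' Wrap a trained clone as a player policy
#'
#' Inference modes: `"argmax_uniform"` takes the modal bin (ties to the
#' lowest index) and samples the proportion uniformly within it;
#' `"sample_full"` samples the bin from the categorical distribution first;
#' `"expectation"` is the deterministic mean action
#' `c = e * sum(softmax_b * (b + 0.5)) / N`.
#'
#' @param member A list with `params` and `hyper` (e.g. an ensemble member).
#' @param mode Action mode.
#' @return A `cpr_player`.
#' @export
bc_player <- function(member, mode = c("argmax_uniform", "sample_full", "expectation")) {
  mode <- match.arg(mode)
  hyper <- member$hyper
  params <- member$params
  new_player(
    id = sprintf("bc(%s)", mode),
    reset = function(config, own_index) list(h = matrix(0, 1, hyper$gru)),
    act = function(state, offers_all, prev_contribs_all, pool, own_index, config) {
      obs <- matrix(bc_observation(offers_all, prev_contribs_all, pool,
                                   own_index, config), 1)
      st <- bc_step(params, obs, state$h, hyper)
      e <- offers_all[own_index]
      if (e < config$offer_unit_threshold)
        return(list(contribution = 0, state = list(h = st$h)))
      N <- hyper$n_bins
      logits <- as.numeric(st$logits)
      cc <- if (mode == "expectation") {
        sm <- exp(logits - max(logits)); sm <- sm / sum(sm)
        e * sum(sm * (seq_len(N) - 0.5)) / N
      } else {
        bin <- if (mode == "argmax_uniform") which.max(logits) - 1L
               else {
                 sm <- exp(logits - max(logits)); sm <- sm / sum(sm)
                 sample.int(N, 1L, prob = sm) - 1L
               }
        bin_to_contribution(bin, stats::runif(1), e, N)
      }
      list(contribution = min(max(cc, 0), e), state = list(h = st$h))
    })
}

#' Player set from an ensemble
#'
#' Training mode samples members with replacement into the `p` slots at the
#' start of each episode; analysis mode pins member `i` into slot `i`
#' (recycling when the ensemble is smaller than `p`).
#'
#' @param ensemble A `bc_ensemble`.
#' @param config A [game_config()].
#' @param sample Sample with replacement (`TRUE`) or pin slots (`FALSE`).
#' @param mode Action mode passed to [bc_player()].
#' @return List of `p` players; sampling uses the current RNG stream.
#' @export
ensemble_players <- function(ensemble, config, sample = TRUE,
                             mode = "argmax_uniform") {
  k <- length(ensemble$members)
  idx <- if (sample) sample.int(k, config$p, replace = TRUE)
         else rep_len(seq_len(k), config$p)
  lapply(idx, function(j) bc_player(ensemble$members[[j]], mode = mode))
}

#' Mean reciprocation fraction of players in rollouts
#'
#' Rolls out episodes and returns the mean of `c / e` over all player-rounds
#' with an offer of at least one unit. Used to compare a clone population's
#' behaviour with the population it was trained on.
#'
#' @param make_players `function()` returning a fresh list of `p` players.
#' @param mechanism A `cpr_mechanism`.
#' @param config A [game_config()].
#' @param n_episodes Number of rollouts.
#' @param seed Base seed.
#' @return Mean reciprocation fraction.
#' @export
mean_reciprocation_fraction <- function(make_players, mechanism,
                                        config = game_config(),
                                        n_episodes = 20L, seed = 1L) {
  fr <- unlist(lapply(seq_len(n_episodes), function(k) {
    log <- run_episode(mechanism, make_players(), config, seed = seed + k)
    keep <- log$offers >= config$offer_unit_threshold
    (log$contributions[keep] / log$offers[keep])
  }))
  mean(fr)
}
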