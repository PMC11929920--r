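# Gradient training of the graph-network mechanism: batched differentiable
# episode rollouts against virtual players, ascending cumulative player
# surplus. In expected-action mode every policy acts through its
# deterministic mean action, so the whole rollout is differentiable and
# reproducible; pathwise-sample mode reparameterises the categorical-uniform
# head with a fixed per-update uniform draw.

# ---- differentiable player contract ----
# list(reset_ad = function(tape, config, own_index) state,
#      act_ad   = function(state, tape, offers, prev_contribs, pool,
#                          own_index, config) list(contribution, state))
# offers / prev_contribs are 1 x p tape nodes, pool is 1 x 1.

# select one entry of a 1 x p row node as a 1 x 1 node
ad_entry <- function(row, i, p) {
  sel <- matrix(0, p, 1); sel[i, 1] <- 1
  ad_matmul(row, ad_const(row$tape, sel))
}

# multiply by the (constant) indicator that the offer is deliverable
gate_sub_unit <- function(c_node, e_node, config) {
  ok <- as.numeric(ad_value(e_node)[1] >= config$offer_unit_threshold)
  ad_scale(c_node, ok)
}

diff_player_sustainer <- function(noise_sd = 0) {
  list(kind = "sustainer",
       reset_ad = function(tape, config, own_index) NULL,
       act_ad = function(state, tape, offers, prev_contribs, pool, own_index, config) {
         e <- ad_entry(offers, own_index, config$p)
         list(contribution = gate_sub_unit(ad_scale(e, 1 / (1 + config$r)), e, config),
              state = state)
       })
}

diff_player_free_rider <- function(base_fraction = 0, cooperate_rounds = 0L) {
  list(kind = "free_rider",
       reset_ad = function(tape, config, own_index) list(t = 0L),
       act_ad = function(state, tape, offers, prev_contribs, pool, own_index, config) {
         e <- ad_entry(offers, own_index, config$p)
         f <- if (state$t < cooperate_rounds) 1 / (1 + config$r) else base_fraction
         list(contribution = gate_sub_unit(ad_scale(e, f), e, config),
              state = list(t = state$t + 1L))
       })
}

diff_player_conditional <- function(noise_sd = 0) {
  list(kind = "conditional",
       reset_ad = function(tape, config, own_index)
         list(target = ad_const(tape, matrix(1 / (1 + config$r), 1, 1)),
              prev_offers = NULL),
       act_ad = function(state, tape, offers, prev_contribs, pool, own_index, config) {
         p <- config$p
         target <- state$target
         if (!is.null(state$prev_offers)) {
           eprev <- as.numeric(ad_value(state$prev_offers))
           idx <- setdiff(seq_len(p), own_index)
           idx <- idx[eprev[idx] >= config$offer_unit_threshold]
           if (length(idx)) {
             fr <- ad_div(prev_contribs,
                          ad_max_const(state$prev_offers, config$offer_unit_threshold))
             wsel <- matrix(0, p, 1); wsel[idx, 1] <- 1 / length(idx)
             target <- ad_clamp(ad_matmul(fr, ad_const(tape, wsel)), 0, 1)
           }
         }
         e <- ad_entry(offers, own_index, p)
         list(contribution = gate_sub_unit(ad_mul(e, target), e, config),
              state = list(target = target, prev_offers = offers))
       })
}

diff_player_grim <- function(trigger_threshold = 0.1, noise_sd = 0) {
  list(kind = "grim",
       reset_ad = function(tape, config, own_index)
         list(triggered = FALSE, prev_offers = NULL),
       act_ad = function(state, tape, offers, prev_contribs, pool, own_index, config) {
         p <- config$p
         triggered <- state$triggered
         if (!triggered && !is.null(state$prev_offers)) {
           eprev <- as.numeric(ad_value(state$prev_offers))
           cprev <- as.numeric(ad_value(prev_contribs))
           fr <- others_fractions(eprev, cprev, own_index, config$offer_unit_threshold)
           if (!is.null(fr) && any(fr < trigger_threshold)) triggered <- TRUE
         }
         e <- ad_entry(offers, own_index, p)
         f <- if (triggered) 0 else 1 / (1 + config$r)
         list(contribution = gate_sub_unit(ad_scale(e, f), e, config),
              state = list(triggered = triggered, prev_offers = offers))
       })
}

diff_player_by_name <- function(kind, ...) {
  switch(kind,
    sustainer = diff_player_sustainer(...),
    free_rider = diff_player_free_rider(...),
    conditional = diff_player_conditional(...),
    grim = diff_player_grim(...),
    stop(sprintf("no differentiable archetype '%s'", kind), call. = FALSE))
}

# differentiable behavioural clone: expected-action (deterministic mean of
# the categorical-uniform head) or pathwise (fixed uniform draws, gradient
# through the sampled proportion)
diff_player_bc <- function(member, mode = "expected_action") {
  hyper <- member$hyper
  flatp <- flatten_params(member$params)
  list(kind = "bc",
       reset_ad = function(tape, config, own_index) {
         nodes <- unflatten_params(lapply(flatp, function(m) ad_const(tape, m)),
                                   member$params)
         rot <- ((own_index - 1L + seq_len(config$p) - 1L) %% config$p) + 1L
         P <- matrix(0, config$p, config$p)
         P[cbind(rot, seq_len(config$p))] <- 1
         list(h = ad_const(tape, matrix(0, 1, hyper$gru)),
              pn = nodes, P = ad_const(tape, P))
       },
       act_ad = function(state, tape, offers, prev_contribs, pool, own_index, config) {
         inv <- 1 / config$normalizer
         obs <- ad_cbind_all(list(
           ad_scale(ad_matmul(offers, state$P), inv),
           ad_scale(ad_matmul(prev_contribs, state$P), inv),
           ad_scale(pool, inv)))
         st <- bc_step_ad(state$pn, obs, state$h, hyper)
         sm <- ad_softmax_rows(st$logits)
         N <- hyper$n_bins
         frac <- if (identical(mode, "pathwise_sample")) {
           u <- stats::runif(N)
           ad_matmul(sm, ad_const(tape, matrix((seq_len(N) - 1 + u) / N, N, 1)))
         } else {
           ad_matmul(sm, ad_const(tape, matrix((seq_len(N) - 0.5) / N, N, 1)))
         }
         e <- ad_entry(offers, own_index, config$p)
         state$h <- st$h
         list(contribution = gate_sub_unit(ad_mul(e, frac), e, config),
              state = state)
       })
}

# build per-episode differentiable players + matched plain players for eval
training_population <- function(population, config, mode = "expected_action") {
  if (inherits(population, "bc_ensemble")) {
    k <- length(population$members)
    function(seed) {
      set.seed(seed)
      idx <- sample.int(k, config$p, replace = TRUE)
      list(ad = lapply(idx, function(j) diff_player_bc(population$members[[j]], mode)),
           plain = lapply(idx, function(j)
             bc_player(population$members[[j]], mode = "expectation")))
    }
  } else if (inherits(population, "cpr_population")) {
    function(seed) {
      set.seed(seed)
      specs <- sample_player_specs(population, config)
      list(ad = lapply(specs, function(sp)
             do.call(diff_player_by_name, c(list(kind = sp$kind),
                                            sp$args))),
           plain = lapply(specs, function(sp)
             do.call(player_by_name, c(list(kind = sp$kind), sp$args))))
    }
  } else stop("population must be a cpr_population or bc_ensemble", call. = FALSE)
}

#' Mechanism training configuration
#'
#' Training uses Adam with an annealed learning rate (reference recipe:
#' start 1e-3, decay 0.05 every 1000 steps, floor 1e-5); defaults here are
#' desk-scale. `gradient_mode` selects how virtual players act inside the
#' differentiable rollout: `"expected_action"` (deterministic mean action)
#' or `"pathwise_sample"` (gradient through sampled proportions).
#'
#' @param updates Total update steps.
#' @param batch Episodes per update (losses averaged).
#' @param lr0,decay,decay_every,lr_floor Learning-rate schedule.
#' @param horizon Rollout length; `NULL` uses the game's horizon.
#' @param gradient_mode `"expected_action"` or `"pathwise_sample"`.
#' @param ckpt_every Checkpoint interval.
#' @param eval_episodes Fixed-seed evaluation episodes per checkpoint.
#' @param width,gru,proj,recurrent Network sizes, see [mech_init_params()].
#' @param seed Seed for initialisation and episode sampling.
#' @return A `mech_train_config` list.
#' @export
mech_train_config <- function(updates = 500L, batch = 2L, lr0 = 1e-3,
                              decay = 0.05, decay_every = 1000L,
                              lr_floor = 1e-5, horizon = NULL,
                              gradient_mode = c("expected_action", "pathwise_sample"),
                              ckpt_every = 100L, eval_episodes = 32L,
                              width = 32L, gru = 16L, proj = 32L,
                              recurrent = TRUE, seed = 1L) {
  gradient_mode <- match.arg(gradient_mode)
  structure(list(updates = as.integer(updates), batch = as.integer(batch),
                 lr0 = lr0, decay = decay, decay_every = as.integer(decay_every),
                 lr_floor = lr_floor, horizon = horizon,
                 gradient_mode = gradient_mode,
                 ckpt_every = as.integer(ckpt_every),
                 eval_episodes = as.integer(eval_episodes),
                 width = as.integer(width), gru = as.integer(gru),
                 proj = as.integer(proj), recurrent = isTRUE(recurrent),
                 seed = as.integer(seed)),
            class = "mech_train_config")
}

# one differentiable rollout; returns the total-surplus node
rollout_ad <- function(tape, pn, mp, players_ad, T_len, config, stc) {
  p <- config$p
  R <- ad_const(tape, matrix(config$R0, 1, 1))
  prev_offers <- ad_const(tape, matrix(0, 1, p))
  prev_contribs <- ad_const(tape, matrix(0, 1, p))
  h <- ad_const(tape, matrix(0, p, mp$gru))
  pstates <- lapply(seq_len(p), function(i)
    players_ad[[i]]$reset_ad(tape, config, i))
  total <- ad_const(tape, matrix(0, 1, 1))
  # (p+1) x p: drops the retained-share weight, keeping the player weights
  sel_off <- ad_const(tape, rbind(diag(p), rep(0, p)))
  for (t in seq_len(T_len)) {
    fw <- mech_forward_ad(pn, mp, tape, prev_offers, prev_contribs, R, h, config, stc)
    h <- fw$h
    offers <- ad_mul(ad_matmul(fw$weights, sel_off), R)    # 1 x p
    cs <- vector("list", p)
    for (i in seq_len(p)) {
      res <- players_ad[[i]]$act_ad(pstates[[i]], tape, offers, prev_contribs,
                                    R, i, config)
      pstates[i] <- list(res$state)   # list-assign: state may be NULL
      cs[[i]] <- res$contribution
    }
    contribs <- ad_cbind_all(cs)
    total <- ad_add(total, ad_sub(ad_sum(offers), ad_sum(contribs)))
    R <- ad_max_const(
      ad_min_const(ad_add(ad_sub(R, ad_sum(offers)),
                          ad_scale(ad_sum(contribs), 1 + config$r)),
                   config$R0), 0)
    prev_offers <- offers
    prev_contribs <- contribs
  }
  total
}

#' Train the graph-network mechanism
#'
#' Gradient ascent on cumulative player surplus through batched
#' differentiable episode rollouts against virtual players (scripted
#' differentiable archetypes from a [population()], or behavioural clones
#' from a `bc_ensemble`, sampled with replacement at each episode start).
#' Checkpoints are saved periodically and scored by mean total surplus on a
#' fixed set of evaluation seeds.
#'
#' @param population A [population()] or `bc_ensemble`.
#' @param train_config A [mech_train_config()].
#' @param config A [game_config()].
#' @param init_params Optional starting `mech_params`.
#' @return A `mech_fit`: final `params`, `init_params`, `checkpoints` (each
#'   with `step`, `params`, `eval_surplus`), `trace` tibble of per-update
#'   surplus, and the configs. Deterministic given the seed.
#' @export
train_mechanism <- function(population, train_config = mech_train_config(),
                            config = game_config(), init_params = NULL) {
  tc <- train_config
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(tc$seed)
  mp <- if (is.null(init_params)) {
    mech_init_params(tc$width, tc$gru, tc$proj, tc$recurrent)
  } else init_params
  T_len <- if (is.null(tc$horizon)) config$horizon else as.integer(tc$horizon)
  stopifnot(is.finite(T_len), T_len >= 1)
  make_players <- training_population(population, config, tc$gradient_mode)
  eval_seeds <- tc$seed * 1000L + seq_len(tc$eval_episodes)
  eval_params <- function(blocks) {
    mpe <- mp; mpe$blocks <- blocks
    mech <- mechanism_gnn(mpe)
    mean(vapply(eval_seeds, function(s) {
      pls <- make_players(s)$plain
      sum(episode_surpluses(run_episode(mech, pls, config, seed = s,
                                        length = T_len)))
    }, numeric(1)))
  }
  flat <- flatten_params(mp$blocks)
  opt <- adam_init(flat)
  init_eval <- eval_params(mp$blocks)
  checkpoints <- list(list(step = 0L, params = mp, eval_surplus = init_eval))
  trace <- numeric(tc$updates)
  scale <- 1 / (config$R0 * T_len)
  for (step in seq_len(tc$updates)) {
    grads_acc <- NULL
    surpl <- 0
    for (b in seq_len(tc$batch)) {
      ep_seed <- tc$seed + step * tc$batch + b
      players_ad <- make_players(ep_seed)$ad
      tape <- ad_tape()
      ptt <- params_to_tape(tape, unflatten_params(flat, mp$blocks))
      stc <- gnn_structures_ad(tape, config$p)
      total <- rollout_ad(tape, ptt$nodes, mp, players_ad, T_len, config, stc)
      loss <- ad_scale(total, -scale)
      surpl <- surpl + ad_value(total)[1]
      g <- ad_backward(loss, ptt$ids)
      names(g) <- ptt$names
      if (any(!vapply(g, function(x) all(is.finite(x)), logical(1))))
        stop(sprintf("non-finite gradient at update %d", step), call. = FALSE)
      grads_acc <- if (is.null(grads_acc)) g
                   else purrr::map2(grads_acc, g, `+`)
    }
    grads_acc <- lapply(grads_acc, function(x) x / tc$batch)
    trace[step] <- surpl / tc$batch
    lr <- lr_schedule(step, tc$lr0, tc$decay, tc$decay_every, tc$lr_floor)
    upd <- adam_step(flat, grads_acc, opt, lr)
    flat <- upd$params
    opt <- upd$state
    if (step %% tc$ckpt_every == 0L || step == tc$updates) {
      blocks <- unflatten_params(flat, mp$blocks)
      mck <- mp; mck$blocks <- blocks
      checkpoints[[length(checkpoints) + 1L]] <- list(
        step = step, params = mck, eval_surplus = eval_params(blocks))
    }
  }
  final <- mp; final$blocks <- unflatten_params(flat, mp$blocks)
  structure(list(
    params = final, init_params = mp, checkpoints = checkpoints,
    trace = tibble::tibble(step = seq_len(tc$updates), surplus = trace),
    train_config = tc, config = config
  ), class = "mech_fit")
}

#' @export
print.mech_fit <- function(x, ...) {
  ev <- vapply(x$checkpoints, `[[`, numeric(1), "eval_surplus")
  cat(sprintf("<mech_fit> %d updates; eval surplus %.1f (init) -> %.1f (best checkpoint)\n",
              x$train_config$updates, ev[1], max(ev)))
  invisible(x)
}

#' Select the best mechanism checkpoint
#'
#' The checkpoint with the highest mean evaluation surplus; ties break to
#' the later checkpoint.
#'
#' @param fit A `mech_fit`, or a list of checkpoints with `eval_surplus`.
#' @return The selected checkpoint's `mech_params`.
#' @export
select_mechanism <- function(fit) {
  ckpts <- if (inherits(fit, "mech_fit")) fit$checkpoints else fit
  stopifnot(length(ckpts) >= 1)
  ev <- vapply(ckpts, `[[`, numeric(1), "eval_surplus")
  best <- max(which(ev >= max(ev) - 1e-12))
  ckpts[[best]]$params
}
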