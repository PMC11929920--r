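# Episode-log serialisation (JSON Lines), CSV export, checkpoint archives
# and run configuration files.

config_to_list <- function(config) {
  list(p = config$p, R0 = config$R0, r = config$r,
       horizon = if (config$geometric) NULL else config$horizon,
       min_rounds = config$min_rounds, end_prob = config$end_prob,
       n_consecutive_games = config$n_consecutive_games,
       offer_unit_threshold = config$offer_unit_threshold,
       integer_contributions = config$integer_contributions,
       truncate_on_depletion = config$truncate_on_depletion,
       normalizer = config$normalizer)
}

config_from_list <- function(lst) {
  do.call(game_config, lst[!vapply(lst, is.null, logical(1))])
}

#' Write an episode log as JSON Lines
#'
#' First line is a header (config and episode metadata); each subsequent
#' line is one round. Numeric fields are serialised at full precision so
#' logs round-trip losslessly.
#'
#' @param log An `episode_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_episode_log <- function(log, path) {
  hdr <- list(type = "header", config = config_to_list(log$config),
              mechanism_id = log$mechanism_id, player_ids = log$player_ids,
              seed = log$seed, game_index = log$game_index,
              sampled_length = log$sampled_length,
              depleted_at = if (is.na(log$depleted_at)) NULL else log$depleted_at)
  s <- episode_surpluses(log)
  lines <- c(
    jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = I(17), null = "null"),
    vapply(seq_len(episode_length(log)), function(t)
      as.character(jsonlite::toJSON(list(
        type = "round", t = t - 1L, trial = t,
        pool_before = log$pool_before[t],
        offers = log$offers[t, ], contributions = log$contributions[t, ],
        surpluses = s[t, ], retained = log$retained[t],
        pool_after = log$pool_after[t]
      ), auto_unbox = TRUE, digits = I(17))), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an episode log from JSON Lines
#'
#' @param path File written by [write_episode_log()].
#' @return An `episode_log`.
#' @export
read_episode_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop(sprintf("parse error in %s at line 1: empty file", path),
                           call. = FALSE)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e)
               stop(sprintf("parse error in %s at line %d: %s", path, i,
                            conditionMessage(e)), call. = FALSE))
  }
  hdr <- parse_line(1L)
  if (!identical(hdr$type, "header"))
    stop(sprintf("parse error in %s at line 1: missing header", path), call. = FALSE)
  config <- config_from_list(hdr$config)
  n <- length(lines) - 1L
  p <- config$p
  offers <- matrix(0, n, p); contribs <- matrix(0, n, p)
  pool_before <- numeric(n); pool_after <- numeric(n); retained <- numeric(n)
  for (i in seq_len(n)) {
    rec <- parse_line(i + 1L)
    if (!identical(rec$type, "round"))
      stop(sprintf("parse error in %s at line %d: expected a round record",
                   path, i + 1L), call. = FALSE)
    offers[i, ] <- rec$offers
    contribs[i, ] <- rec$contributions
    pool_before[i] <- rec$pool_before
    pool_after[i] <- rec$pool_after
    retained[i] <- rec$retained
  }
  structure(list(
    config = config, mechanism_id = hdr$mechanism_id,
    player_ids = as.character(hdr$player_ids),
    seed = if (is.null(hdr$seed)) NA_integer_ else as.integer(hdr$seed),
    game_index = as.integer(hdr$game_index),
    sampled_length = as.integer(hdr$sampled_length),
    offers = offers, contributions = contribs,
    pool_before = pool_before, pool_after = pool_after, retained = retained,
    depleted_at = if (is.null(hdr$depleted_at)) NA_integer_ else as.integer(hdr$depleted_at)
  ), class = "episode_log")
}

#' Flattened CSV export of episode logs
#'
#' One row per game, trial and player with offer, contribution, surplus,
#' pool before/after and retained amount.
#'
#' @param logs List of `episode_log`s (or one log).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_episode_csv <- function(logs, path) {
  if (inherits(logs, "episode_log")) logs <- list(logs)
  tab <- dplyr::bind_rows(lapply(logs, function(l)
    dplyr::mutate(as_tibble(l), mechanism = l$mechanism_id, .before = 1L)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a checkpoint archive
#'
#' Flat named-array JSON archive with an embedded hyperparameter header:
#' parameters are flattened to named matrices stored with their dimensions.
#'
#' @param params Nested named list of matrices.
#' @param meta Hyperparameter/metadata list (stored verbatim).
#' @param path Archive path.
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: a
#'   list with `params` and `meta`.
#' @export
save_checkpoint <- function(params, meta, path) {
  cls <- class(params)
  flat <- flatten_params(unclass(params))
  arrays <- lapply(flat, function(m)
    list(dim = dim(m), data = as.numeric(m)))
  obj <- list(meta = meta, class = cls, arrays = arrays)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
  flat <- lapply(obj$arrays, function(a) matrix(a$data, a$dim[1], a$dim[2]))
  # rebuild nesting from dotted names
  nested <- list()
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      nested[[parts]] <- flat[[nm]]
    } else {
      if (is.null(nested[[parts[1]]])) nested[[parts[1]]] <- list()
      nested[[parts[1]]][[parts[2]]] <- flat[[nm]]
    }
  }
  list(params = nested, meta = obj$meta)
}

#' Read a run configuration file
#'
#' YAML with blocks: `game` (arguments of [game_config()]), `mechanisms`
#' (list of `{name, ...}` specs), `population` (list of archetype entries),
#' `bc` (arguments of [bc_hyper()]), `mech_train` (arguments of
#' [mech_train_config()]), `seed`, `out_dir`, `n_games`. Every omitted
#' field is filled with the package default and echoed.
#'
#' @param path YAML file.
#' @param quiet Suppress the echo of defaulted fields.
#' @return A `run_config` list with resolved `config`, `mechanisms`,
#'   `population`, `bc`, `mech_train`, `seed`, `out_dir`, `n_games`.
#' @export
read_run_config <- function(path, quiet = FALSE) {
  raw <- yaml::read_yaml(path)
  note <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (is.null(raw$game)) note("run config: using default game settings (p=4, R0=200, r=0.4, 40 rounds)")
  config <- config_from_list(raw$game %||% list())
  mechs <- raw$mechanisms %||% list(list(name = "equal"))
  if (is.null(raw$mechanisms)) note("run config: defaulting to the equal mechanism")
  pop <- if (is.null(raw$population)) {
    note("run config: defaulting to a noisy-sustainer population")
    population(list(kind = "sustainer", count = config$p, noise_sd = 0.05))
  } else do.call(population, raw$population)
  bc <- do.call(bc_hyper, raw$bc %||% list())
  if (is.null(raw$bc)) note("run config: using default clone hyperparameters (N=%d, GRU %d)",
                            bc$n_bins, bc$gru)
  mt <- do.call(mech_train_config, raw$mech_train %||% list())
  if (is.null(raw$mech_train)) note("run config: using default mechanism-training settings (%d updates)",
                                    mt$updates)
  seed <- raw$seed %||% 1L
  if (is.null(raw$seed)) note("run config: defaulting seed to 1")
  list(config = config, mechanisms = mechs, population = pop, bc = bc,
       mech_train = mt, seed = as.integer(seed),
       out_dir = raw$out_dir %||% ".", n_games = raw$n_games %||% 10L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
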