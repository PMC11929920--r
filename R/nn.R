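# Small neural-network building blocks shared by the behavioural clones and
# the graph-network mechanism: parameter initialisation, dense and GRU
# layers (plain-matrix forward for inference, tape forward for training),
# the Adam optimiser and the exponentially annealed learning-rate schedule.

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Initialise a dense layer
#' @param n_in,n_out Input/output widths.
#' @return Named list with weight `W` (n_in x n_out) and bias `b` (1 x n_out).
#' @keywords internal
#' @export
dense_init <- function(n_in, n_out) list(W = glorot(n_in, n_out), b = matrix(0, 1, n_out))

#' Initialise a GRU cell
#' @param n_in,n_h Input width and hidden size.
#' @return Named list of gate weights (`Wz`, `Uz`, `bz`, `Wr`, `Ur`, `br`,
#'   `Wn`, `Un`, `bn`).
#' @keywords internal
#' @export
gru_init <- function(n_in, n_h) {
  list(Wz = glorot(n_in, n_h), Uz = glorot(n_h, n_h), bz = matrix(0, 1, n_h),
       Wr = glorot(n_in, n_h), Ur = glorot(n_h, n_h), br = matrix(0, 1, n_h),
       Wn = glorot(n_in, n_h), Un = glorot(n_h, n_h), bn = matrix(0, 1, n_h))
}

# ---- plain-matrix forward (inference) ----

dense_fwd <- function(x, layer, act = c("relu", "linear", "tanh")) {
  act <- match.arg(act)
  y <- sweep(x %*% layer$W, 2L, as.numeric(layer$b), "+")
  switch(act, relu = pmax(y, 0), tanh = tanh(y), linear = y)
}

sigm <- function(x) 1 / (1 + exp(-x))

# GRU step; h' = (1 - z) * h + z * n with update gate z
gru_fwd <- function(x, h, cell) {
  z <- sigm(sweep(x %*% cell$Wz + h %*% cell$Uz, 2L, as.numeric(cell$bz), "+"))
  r <- sigm(sweep(x %*% cell$Wr + h %*% cell$Ur, 2L, as.numeric(cell$br), "+"))
  n <- tanh(sweep(x %*% cell$Wn + (r * h) %*% cell$Un, 2L, as.numeric(cell$bn), "+"))
  (1 - z) * h + z * n
}

# ---- tape forward (training) ----

# layer_nodes: list with W, b as ad nodes
dense_fwd_ad <- function(x, layer_nodes, act = "relu") {
  y <- ad_addbias(ad_matmul(x, layer_nodes$W), layer_nodes$b)
  switch(act, relu = ad_relu(y), tanh = ad_tanh(y), linear = y)
}

gru_fwd_ad <- function(x, h, cell) {
  z <- ad_sigmoid(ad_addbias(ad_add(ad_matmul(x, cell$Wz), ad_matmul(h, cell$Uz)), cell$bz))
  r <- ad_sigmoid(ad_addbias(ad_add(ad_matmul(x, cell$Wr), ad_matmul(h, cell$Ur)), cell$br))
  n <- ad_tanh(ad_addbias(ad_add(ad_matmul(x, cell$Wn),
                                 ad_matmul(ad_mul(r, h), cell$Un)), cell$bn))
  one <- ad_const(x$tape, matrix(1, 1, 1))
  ad_add(ad_mul(ad_sub(one, z), h), ad_mul(z, n))
}

# ---- parameter plumbing ----

# flatten a nested named list of matrices into a flat named list
flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    v <- params[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.matrix(v)) out[[key]] <- v
    else out <- c(out, flatten_params(v, key))
  }
  out
}

unflatten_params <- function(flat, skeleton, prefix = "") {
  out <- skeleton
  for (nm in names(skeleton)) {
    v <- skeleton[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.matrix(v)) out[[nm]] <- flat[[key]]
    else out[[nm]] <- unflatten_params(flat, v, key)
  }
  out
}

# register every matrix of a nested parameter list on a tape; returns the
# same nesting with ad nodes plus the flat id vector for ad_backward()
params_to_tape <- function(tape, params) {
  flat <- flatten_params(params)
  nodes_flat <- lapply(flat, function(m) ad_param(tape, m))
  ids <- vapply(nodes_flat, function(nd) nd$id, integer(1))
  nested <- unflatten_params(nodes_flat, params)
  list(nodes = nested, ids = ids, names = names(flat))
}

# ---- Adam ----

adam_init <- function(flat_params) {
  list(m = lapply(flat_params, function(x) x * 0),
       v = lapply(flat_params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat_params, flat_grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat_params)) {
    g <- flat_grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat_params[[nm]] <- flat_params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = flat_params, state = state)
}

#' Annealed learning rate
#'
#' Multiplies the starting rate by `(1 - decay)` every `every` updates,
#' floored at `floor_lr`.
#'
#' @param step Update step (1-based).
#' @param lr0 Starting learning rate.
#' @param decay Decay fraction per interval.
#' @param every Interval in update steps.
#' @param floor_lr Minimum learning rate.
#' @keywords internal
#' @export
lr_schedule <- function(step, lr0, decay = 0.05, every = 1000L, floor_lr = lr0 / 100) {
  max(lr0 * (1 - decay)^(max(step - 1L, 0L) %/% every), floor_lr)
}
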