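# Permutation-equivariant graph-network allocation mechanism.
#
# Players are vertices of a fully connected directed graph; each vertex
# carries (previous endowment, previous contribution, pool), all
# normalised, edges start empty and the global attribute holds the pool.
# A graph block updates edges first, then nodes from summed incoming
# updated edges, then the global attribute; the same functions are shared
# across all edges/nodes, which (with sum aggregation) yields permutation
# equivariance and a uniform opening move for free.

gnn_structures <- function(p) {
  pairs <- expand.grid(s = seq_len(p), r = seq_len(p))
  pairs <- pairs[pairs$s != pairs$r, , drop = FALSE]
  E <- nrow(pairs)
  Ss <- matrix(0, E, p); Sr <- matrix(0, E, p)
  for (k in seq_len(E)) {
    Ss[k, pairs$s[k]] <- 1
    Sr[k, pairs$r[k]] <- 1
  }
  list(p = p, E = E, s = pairs$s, r = pairs$r, Ss = Ss, Sr = Sr, tA = t(Sr))
}

#' Graph observation of the game state
#'
#' @param state A `cpr_state`.
#' @param config A [game_config()].
#' @return A list: `nodes` (p x 3 matrix of normalised previous endowment,
#'   previous contribution, pool), `edges` (p(p-1) x 0, initially empty),
#'   `global` (1 x 1 normalised pool), `senders`, `receivers`.
#' @export
build_graph <- function(state, config) {
  p <- config$p
  st <- gnn_structures(p)
  norm <- config$normalizer
  nodes <- cbind(state$prev_offers, state$prev_contributions, rep(state$R, p)) / norm
  colnames(nodes) <- c("prev_offer", "prev_contribution", "pool")
  list(nodes = nodes, edges = matrix(0, st$E, 0),
       global = matrix(state$R / norm, 1, 1),
       senders = st$s, receivers = st$r)
}

#' One feedforward graph-block update
#'
#' Edges update first from `(e_sr, v_s, v_r, u)`, then nodes from the sum of
#' incoming updated edges with `(sum_e', v_r, u)`, then the global attribute
#' from `(sum e', sum v', u)`. The same functions apply at every edge and
#' node.
#'
#' @param phis List of `edge`, `node`, `global` functions, each mapping a
#'   row-wise input matrix to a row-wise output matrix.
#' @param graph A graph as from [build_graph()].
#' @return The updated graph (same connectivity).
#' @export
gnn_block <- function(phis, graph) {
  p <- nrow(graph$nodes); E <- length(graph$senders)
  ub_E <- matrix(graph$global, E, ncol(graph$global), byrow = TRUE)
  ub_p <- matrix(graph$global, p, ncol(graph$global), byrow = TRUE)
  e_in <- cbind(graph$edges,
                graph$nodes[graph$senders, , drop = FALSE],
                graph$nodes[graph$receivers, , drop = FALSE], ub_E)
  e2 <- phis$edge(e_in)
  agg <- if (E > 0) unname(rowsum(e2, graph$receivers)) else matrix(0, p, ncol(e2))
  v2 <- phis$node(cbind(agg, graph$nodes, ub_p))
  u2 <- phis$global(cbind(matrix(colSums(e2), 1), matrix(colSums(v2), 1),
                          graph$global))
  list(nodes = v2, edges = e2, global = u2,
       senders = graph$senders, receivers = graph$receivers)
}

#' Initialise graph-network mechanism parameters
#'
#' Two sequential graph blocks. Block 1 uses single nonlinear layers of
#' `width` outputs for the edge, node and global updates. Block 2 uses a
#' nonlinear edge layer of `width`; its node update is a GRU memory of size
#' `gru` (persistent across rounds within an episode) followed by a
#' nonlinear `proj` layer and a linear scalar head; its global update is a
#' nonlinear `proj` layer and a linear scalar head. The 4 node scalars and
#' the global scalar are softmax-normalised into the 5 allocation weights.
#'
#' @param width Hidden width of block-1 layers and block-2 edge layer.
#' @param gru Node memory size (block 2).
#' @param proj Projection width before the scalar heads.
#' @param recurrent If `FALSE`, the node memory is replaced by a dense layer
#'   of the same size (the memoryless variant).
#' @param seed Initialisation seed (caller's RNG preserved).
#' @return A `mech_params` object.
#' @export
mech_init_params <- function(width = 32L, gru = 16L, proj = 32L,
                             recurrent = TRUE, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  blocks <- list(
    e1 = dense_init(7L, width),
    v1 = dense_init(width + 3L + 1L, width),
    u1 = dense_init(2L * width + 1L, width),
    e2 = dense_init(4L * width, width),
    core = if (recurrent) gru_init(3L * width, gru) else dense_init(3L * width, gru),
    vproj = dense_init(gru, proj),
    vout = dense_init(proj, 1L),
    uproj = dense_init(width + 1L + width, proj),
    uout = dense_init(proj, 1L)
  )
  structure(list(width = as.integer(width), gru = as.integer(gru),
                 proj = as.integer(proj), recurrent = isTRUE(recurrent),
                 blocks = blocks),
            class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf("<mech_params> width %d, memory %d (%s), proj %d\n",
              x$width, x$gru, if (x$recurrent) "GRU" else "memoryless", x$proj))
  invisible(x)
}

#' Forward pass of the graph-network mechanism
#'
#' Deterministic given inputs and memory: returns the five allocation
#' weights (softmax over the four node scalars and the global scalar) and
#' the updated node memory.
#'
#' @param mp A `mech_params`.
#' @param prev_offers,prev_contribs Length-`p` vectors (previous round).
#' @param R Current pool.
#' @param h Node memory (p x gru matrix); zeros at episode start.
#' @param config A [game_config()].
#' @return `list(weights, h)` with `weights` of length `p + 1` summing to 1.
#' @export
mech_forward <- function(mp, prev_offers, prev_contribs, R, h, config) {
  p <- config$p
  st <- gnn_structures(p)
  norm <- config$normalizer
  w <- mp$width
  V <- unname(cbind(prev_offers, prev_contribs, rep(R, p))) / norm
  u <- matrix(R / norm, 1, 1)
  e_in <- cbind(V[st$s, , drop = FALSE], V[st$r, , drop = FALSE],
                matrix(u[1], st$E, 1))
  E1 <- dense_fwd(e_in, mp$blocks$e1, "relu")
  agg <- if (st$E > 0) unname(rowsum(E1, st$r)) else matrix(0, p, w)
  V1 <- dense_fwd(cbind(agg, V, matrix(u[1], p, 1)), mp$blocks$v1, "relu")
  u1 <- dense_fwd(cbind(matrix(colSums(E1), 1), matrix(colSums(V1), 1), u),
                  mp$blocks$u1, "relu")
  e2_in <- cbind(E1, V1[st$s, , drop = FALSE], V1[st$r, , drop = FALSE],
                 matrix(u1, st$E, w, byrow = TRUE))
  E2 <- dense_fwd(e2_in, mp$blocks$e2, "relu")
  agg2 <- if (st$E > 0) unname(rowsum(E2, st$r)) else matrix(0, p, w)
  v2_in <- cbind(agg2, V1, matrix(u1, p, w, byrow = TRUE))
  h2 <- if (mp$recurrent) gru_fwd(v2_in, h, mp$blocks$core)
        else dense_fwd(v2_in, mp$blocks$core, "relu")
  ns <- dense_fwd(dense_fwd(h2, mp$blocks$vproj, "relu"), mp$blocks$vout, "linear")
  u2_in <- cbind(matrix(colSums(E2), 1), matrix(sum(ns), 1, 1), u1)
  gs <- dense_fwd(dense_fwd(u2_in, mp$blocks$uproj, "relu"), mp$blocks$uout, "linear")
  logits <- c(ns, gs)
  m <- logits - max(logits)
  wts <- exp(m) / sum(exp(m))
  list(weights = wts, h = h2)
}

# tape forward; prev_offers/prev_contribs are 1xp nodes, R is 1x1 node,
# h is a p x gru node; stc holds constant structure nodes for this tape
mech_forward_ad <- function(pn, mp, tape, prev_offers, prev_contribs, R, h,
                            config, stc) {
  p <- config$p
  w <- mp$width
  inv <- 1 / config$normalizer
  Vo <- ad_scale(ad_transpose(prev_offers), inv)
  Vc <- ad_scale(ad_transpose(prev_contribs), inv)
  Vr <- ad_matmul(stc$onesP, ad_scale(R, inv))
  V <- ad_cbind_all(list(Vo, Vc, Vr))
  u <- ad_scale(R, inv)
  uE <- ad_matmul(stc$onesE, u)
  uP <- ad_matmul(stc$onesP, u)
  e_in <- ad_cbind_all(list(ad_matmul(stc$Ss, V), ad_matmul(stc$Sr, V), uE))
  E1 <- dense_fwd_ad(e_in, pn$e1, "relu")
  agg <- ad_matmul(stc$tA, E1)
  V1 <- dense_fwd_ad(ad_cbind_all(list(agg, V, uP)), pn$v1, "relu")
  sumE1 <- ad_matmul(stc$rowE, E1)
  sumV1 <- ad_matmul(stc$rowP, V1)
  u1 <- dense_fwd_ad(ad_cbind_all(list(sumE1, sumV1, u)), pn$u1, "relu")
  u1E <- ad_matmul(stc$onesE, u1)
  u1P <- ad_matmul(stc$onesP, u1)
  e2_in <- ad_cbind_all(list(E1, ad_matmul(stc$Ss, V1), ad_matmul(stc$Sr, V1), u1E))
  E2 <- dense_fwd_ad(e2_in, pn$e2, "relu")
  agg2 <- ad_matmul(stc$tA, E2)
  v2_in <- ad_cbind_all(list(agg2, V1, u1P))
  h2 <- if (mp$recurrent) gru_fwd_ad(v2_in, h, pn$core)
        else dense_fwd_ad(v2_in, pn$core, "relu")
  ns <- dense_fwd_ad(dense_fwd_ad(h2, pn$vproj, "relu"), pn$vout, "linear")
  sumE2 <- ad_matmul(stc$rowE, E2)
  sum_ns <- ad_matmul(stc$rowP, ns)
  gs <- dense_fwd_ad(dense_fwd_ad(ad_cbind_all(list(sumE2, sum_ns, u1)),
                                  pn$uproj, "relu"), pn$uout, "linear")
  logits <- ad_cbind2(ad_transpose(ns), gs)     # 1 x (p+1)
  list(weights = ad_softmax_rows(logits), h = h2)
}

# constant structure nodes for one tape
gnn_structures_ad <- function(tape, p) {
  st <- gnn_structures(p)
  list(Ss = ad_const(tape, st$Ss), Sr = ad_const(tape, st$Sr),
       tA = ad_const(tape, st$tA),
       onesE = ad_const(tape, matrix(1, st$E, 1)),
       onesP = ad_const(tape, matrix(1, p, 1)),
       rowE = ad_const(tape, matrix(1, 1, st$E)),
       rowP = ad_const(tape, matrix(1, 1, p)))
}

#' Offers from allocation weights
#'
#' @param weights Simplex weights of length `p + 1`.
#' @param R Current pool size.
#' @return `list(offers, retained)` with `sum(offers) + retained == R`.
#' @export
offers_from_weights <- function(weights, R) {
  p <- length(weights) - 1L
  list(offers = weights[seq_len(p)] * R, retained = weights[p + 1L] * R)
}

#' Wrap graph-network parameters as a mechanism policy
#'
#' @param mp A `mech_params`.
#' @param id Identifier recorded in logs.
#' @return A `cpr_mechanism` with per-episode node memory.
#' @export
mechanism_gnn <- function(mp, id = "gnn") {
  force(mp)
  new_mechanism(
    id = id,
    reset = function(config) list(h = matrix(0, config$p, mp$gru)),
    act = function(state, game_state, config) {
      fw <- mech_forward(mp, game_state$prev_offers,
                         game_state$prev_contributions,
                         game_state$R, state$h, config)
      out <- offers_from_weights(fw$weights, game_state$R)
      list(offers = out$offers, retained = out$retained,
           state = list(h = fw$h))
    })
}
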