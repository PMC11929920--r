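# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records every operation; ad_backward() sweeps it in reverse to
# accumulate gradients. Values are numeric matrices (scalars are 1x1).
# This is deliberately small: just the operations needed by the recurrent
# behavioural-clone networks and the graph-network mechanism, each with a
# hand-written adjoint, gradient-checked against finite differences in the
# test suite.

#' Create an autodiff tape
#'
#' @return A tape environment; pass it to [ad_const()] / [ad_param()] to
#'   create leaf nodes.
#' @keywords internal
#' @export
ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$n <- 0L
  cap <- 1024L
  tape$vals <- vector("list", cap)
  tape$parents <- vector("list", cap)
  tape$backs <- vector("list", cap)
  tape$cap <- cap
  tape
}

ad_push <- function(tape, value, parents = integer(0), backward = NULL) {
  n <- tape$n + 1L
  if (n > tape$cap) {
    newcap <- tape$cap * 2L
    length(tape$vals) <- newcap
    length(tape$parents) <- newcap
    length(tape$backs) <- newcap
    tape$cap <- newcap
  }
  tape$vals[[n]] <- value
  tape$parents[[n]] <- parents
  tape$backs[[n]] <- backward
  tape$n <- n
  list(tape = tape, id = n)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' Tape leaf nodes and node value
#'
#' `ad_const()` creates a constant (no gradient), `ad_param()` a
#' differentiable leaf; `ad_value()` reads a node's current value.
#'
#' @param tape A tape from [ad_tape()].
#' @param x Numeric matrix or vector (vectors become 1-row matrices).
#' @param a An ad node.
#' @keywords internal
#' @export
ad_const <- function(tape, x) ad_push(tape, as_mat(x))

#' @rdname ad_const
#' @export
ad_param <- function(tape, x) ad_push(tape, as_mat(x))

#' @rdname ad_const
#' @export
ad_value <- function(a) a$tape$vals[[a$id]]

# broadcast-aware reduction of a gradient back to the shape of the operand
reduce_grad <- function(g, target) {
  if (length(target) == 1L && length(g) > 1L) matrix(sum(g), 1, 1) else g
}

bcast <- function(x, y) {
  # returns dims for elementwise op between x and y (one may be 1x1)
  if (all(dim(x) == dim(y))) return(NULL)
  if (length(x) == 1L || length(y) == 1L) return(NULL)
  stop("ad: incompatible shapes", call. = FALSE)
}

#' Elementwise and matrix operations on tape nodes
#'
#' Binary operations accept operands of equal shape or a 1x1 scalar node;
#' `ad_addbias()` adds a 1-row bias to every row; `ad_matmul()` is matrix
#' multiplication; `ad_rows()` selects rows; `ad_cbind2()` concatenates
#' columns; `ad_clamp()` clips with zero gradient outside the interval;
#' `ad_min_const()` caps values at a constant (zero gradient where capped).
#'
#' @param a,b Ad nodes.
#' @param idx Integer row indices.
#' @param lo,hi,k Numeric constants.
#' @keywords internal
#' @name ad-ops
NULL

#' @rdname ad-ops
#' @export
ad_add <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b); bcast(va, vb)
  v <- if (length(vb) == 1L) va + vb[1] else if (length(va) == 1L) va[1] + vb else va + vb
  ad_push(a$tape, as_mat(v), c(a$id, b$id), function(g)
    list(reduce_grad(g, va), reduce_grad(g, vb)))
}

#' @rdname ad-ops
#' @export
ad_sub <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b); bcast(va, vb)
  v <- if (length(vb) == 1L) va - vb[1] else if (length(va) == 1L) va[1] - vb else va - vb
  ad_push(a$tape, as_mat(v), c(a$id, b$id), function(g)
    list(reduce_grad(g, va), reduce_grad(-g, vb)))
}

#' @rdname ad-ops
#' @export
ad_mul <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b); bcast(va, vb)
  v <- if (length(vb) == 1L) va * vb[1] else if (length(va) == 1L) va[1] * vb else va * vb
  ad_push(a$tape, as_mat(v), c(a$id, b$id), function(g) {
    ga <- if (length(vb) == 1L) g * vb[1] else g * vb
    gb <- if (length(va) == 1L) g * va[1] else g * va
    list(reduce_grad(ga, va), reduce_grad(gb, vb))
  })
}

#' @rdname ad-ops
#' @export
ad_div <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b); bcast(va, vb)
  v <- if (length(vb) == 1L) va / vb[1] else if (length(va) == 1L) va[1] / vb else va / vb
  ad_push(a$tape, as_mat(v), c(a$id, b$id), function(g) {
    ga <- if (length(vb) == 1L) g / vb[1] else g / vb
    gb <- -g * (if (length(va) == 1L) va[1] else va) /
      (if (length(vb) == 1L) vb[1]^2 else vb^2)
    list(reduce_grad(ga, va), reduce_grad(gb, vb))
  })
}

#' @rdname ad-ops
#' @export
ad_scale <- function(a, k) {
  ad_push(a$tape, ad_value(a) * k, a$id, function(g) list(g * k))
}

#' @rdname ad-ops
#' @export
ad_matmul <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  ad_push(a$tape, va %*% vb, c(a$id, b$id), function(g)
    list(g %*% t(vb), t(va) %*% g))
}

#' @rdname ad-ops
#' @export
ad_addbias <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  stopifnot(nrow(vb) == 1L, ncol(va) == ncol(vb))
  ad_push(a$tape, sweep(va, 2L, as.numeric(vb), "+"), c(a$id, b$id),
          function(g) list(g, matrix(colSums(g), 1)))
}

#' @rdname ad-ops
#' @export
ad_relu <- function(a) {
  va <- ad_value(a)
  mask <- va > 0
  ad_push(a$tape, va * mask, a$id, function(g) list(g * mask))
}

#' @rdname ad-ops
#' @export
ad_tanh <- function(a) {
  v <- tanh(ad_value(a))
  ad_push(a$tape, v, a$id, function(g) list(g * (1 - v^2)))
}

#' @rdname ad-ops
#' @export
ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ad_value(a)))
  ad_push(a$tape, v, a$id, function(g) list(g * v * (1 - v)))
}

#' @rdname ad-ops
#' @export
ad_softmax_rows <- function(a) {
  va <- ad_value(a)
  m <- va - apply(va, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ad_push(a$tape, s, a$id, function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

#' @rdname ad-ops
#' @export
ad_logsoftmax_rows <- function(a) {
  va <- ad_value(a)
  m <- va - apply(va, 1L, max)
  lse <- log(rowSums(exp(m)))
  v <- m - lse
  sm <- exp(v)
  ad_push(a$tape, v, a$id, function(g) {
    list(g - sm * rowSums(g))
  })
}

#' @rdname ad-ops
#' @export
ad_sum <- function(a) {
  va <- ad_value(a)
  ad_push(a$tape, matrix(sum(va), 1, 1), a$id, function(g)
    list(matrix(g[1], nrow(va), ncol(va))))
}

#' @rdname ad-ops
#' @export
ad_rows <- function(a, idx) {
  va <- ad_value(a)
  ad_push(a$tape, va[idx, , drop = FALSE], a$id, function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    for (j in seq_along(idx)) out[idx[j], ] <- out[idx[j], ] + g[j, ]
    list(out)
  })
}

#' @rdname ad-ops
#' @export
ad_cbind2 <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  ad_push(a$tape, cbind(va, vb), c(a$id, b$id), function(g)
    list(g[, seq_len(ncol(va)), drop = FALSE],
         g[, ncol(va) + seq_len(ncol(vb)), drop = FALSE]))
}

#' Concatenate several nodes column-wise
#' @param nodes List of ad nodes with equal row counts.
#' @keywords internal
#' @export
ad_cbind_all <- function(nodes) {
  out <- nodes[[1]]
  for (k in seq_along(nodes)[-1]) out <- ad_cbind2(out, nodes[[k]])
  out
}

#' @rdname ad-ops
#' @export
ad_rbind2 <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  ad_push(a$tape, rbind(va, vb), c(a$id, b$id), function(g)
    list(g[seq_len(nrow(va)), , drop = FALSE],
         g[nrow(va) + seq_len(nrow(vb)), , drop = FALSE]))
}

#' @rdname ad-ops
#' @export
ad_clamp <- function(a, lo, hi) {
  va <- ad_value(a)
  mask <- va >= lo & va <= hi
  ad_push(a$tape, pmin(pmax(va, lo), hi), a$id, function(g) list(g * mask))
}

#' @rdname ad-ops
#' @export
ad_min_const <- function(a, k) {
  va <- ad_value(a)
  mask <- va < k
  ad_push(a$tape, pmin(va, k), a$id, function(g) list(g * mask))
}

#' @rdname ad-ops
#' @export
ad_max_const <- function(a, k) {
  va <- ad_value(a)
  mask <- va > k
  ad_push(a$tape, pmax(va, k), a$id, function(g) list(g * mask))
}

#' @rdname ad-ops
#' @export
ad_transpose <- function(a) {
  va <- ad_value(a)
  ad_push(a$tape, t(va), a$id, function(g) list(t(g)))
}

#' Reverse sweep: gradients of a scalar node
#'
#' @param root A 1x1 ad node (typically a loss).
#' @param wrt Integer vector of leaf node ids.
#' @return A list of gradients (same order as `wrt`; zero matrices where the
#'   leaf does not influence the root).
#' @keywords internal
#' @export
ad_backward <- function(root, wrt) {
  tape <- root$tape
  n <- root$id
  grads <- vector("list", n)
  rv <- tape$vals[[n]]
  stopifnot(length(rv) == 1L)
  grads[[n]] <- matrix(1, 1, 1)
  for (i in n:1) {
    g <- grads[[i]]
    if (is.null(g)) next
    bk <- tape$backs[[i]]
    if (is.null(bk)) next
    pg <- bk(g)
    ps <- tape$parents[[i]]
    for (j in seq_along(ps)) {
      pid <- ps[j]
      if (is.null(grads[[pid]])) grads[[pid]] <- pg[[j]]
      else grads[[pid]] <- grads[[pid]] + pg[[j]]
    }
  }
  lapply(wrt, function(id) {
    if (is.null(grads[[id]])) {
      v <- tape$vals[[id]]
      matrix(0, nrow(v), ncol(v))
    } else grads[[id]]
  })
}
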