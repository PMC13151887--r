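#' @name autodiff
#' @title Minimal reverse-mode automatic differentiation over dense matrices
#'
#' @description
#' A small tape-based reverse-mode AD engine used to train the denoiser, the
#' property-conditioning transformer and the PPO critic.  Values are numeric
#' matrices; each operation records a backward closure on a tape, and
#' [ad_backward()] propagates gradients in reverse creation order.  The engine
#' deliberately supports only the operations those networks need (matrix
#' product, broadcast add, elementwise arithmetic, sigmoid/tanh/SiLU, softmax
#' rows, reductions, clamping) and keeps everything dense: molecules here have
#' at most a few dozen atoms, so dense n x n algebra is the fast path.
#'
#' Gradients at non-differentiable points (clamp boundaries, the min() used by
#' the PPO clipped surrogate) use the usual subgradient convention: the mask is
#' computed from forward values and treated as constant.
#' @keywords internal
NULL

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  t
}

ad_new <- function(tape, v, back = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$back <- back
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$k]] <- n
  n$tape <- tape
  n
}

is_ad <- function(x) is.environment(x) && !is.null(x$v)

ad_val <- function(x) if (is_ad(x)) x$v else x

# accumulate gradient g into node (no-op for plain numerics)
ad_acc <- function(node, g) {
  if (!is_ad(node)) return(invisible(NULL))
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

ad_const <- function(tape, x) ad_new(tape, x)

tape_of <- function(...) {
  for (a in list(...)) if (is_ad(a)) return(a$tape)
  stop("no tape among arguments")
}

#' Matrix product on the tape
#' @noRd
ad_matmul <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_new(tp, av %*% bv)
  out$back <- function(g) {
    ad_acc(a, g %*% t(bv))
    ad_acc(b, t(av) %*% g)
  }
  out
}

# addition; b may be a matrix of equal shape, a length-ncol row vector
# (broadcast over rows) or a scalar
ad_add <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_val(a); bv <- ad_val(b)
  v <- if (is.matrix(av) && is.matrix(bv) && nrow(bv) == 1L && nrow(av) > 1L) {
    sweep(av, 2L, as.numeric(bv), "+")
  } else {
    av + bv
  }
  out <- ad_new(tp, v)
  out$back <- function(g) {
    ad_acc(a, g)
    if (is_ad(b)) {
      gb <- if (is.matrix(ad_val(b)) && nrow(ad_val(b)) == 1L && nrow(as.matrix(g)) > 1L) {
        matrix(colSums(g), nrow = 1L)
      } else if (!is.matrix(ad_val(b)) && length(ad_val(b)) == 1L) {
        sum(g)
      } else g
      ad_acc(b, gb)
    }
  }
  out
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_scale <- function(a, s) {
  tp <- tape_of(a)
  out <- ad_new(tp, ad_val(a) * s)
  out$back <- function(g) ad_acc(a, g * s)
  out
}

ad_emul <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_val(a); bv <- ad_val(b)
  out <- ad_new(tp, av * bv)
  out$back <- function(g) {
    ad_acc(a, g * bv)
    ad_acc(b, g * av)
  }
  out
}

ad_sigmoid <- function(a) {
  tp <- tape_of(a)
  s <- 1 / (1 + exp(-ad_val(a)))
  out <- ad_new(tp, s)
  out$back <- function(g) ad_acc(a, g * s * (1 - s))
  out
}

ad_tanh <- function(a) {
  tp <- tape_of(a)
  v <- tanh(ad_val(a))
  out <- ad_new(tp, v)
  out$back <- function(g) ad_acc(a, g * (1 - v^2))
  out
}

ad_silu <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  s <- 1 / (1 + exp(-x))
  out <- ad_new(tp, x * s)
  out$back <- function(g) ad_acc(a, g * (s + x * s * (1 - s)))
  out
}

ad_exp <- function(a) {
  tp <- tape_of(a)
  v <- exp(ad_val(a))
  out <- ad_new(tp, v)
  out$back <- function(g) ad_acc(a, g * v)
  out
}

ad_log <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  out <- ad_new(tp, log(x))
  out$back <- function(g) ad_acc(a, g / x)
  out
}

ad_square <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  out <- ad_new(tp, x^2)
  out$back <- function(g) ad_acc(a, 2 * g * x)
  out
}

# max(x, 0) hinge
ad_relu <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  m <- (x > 0) * 1
  out <- ad_new(tp, x * m)
  out$back <- function(g) ad_acc(a, g * m)
  out
}

# clamp to [lo, hi]; subgradient 1 strictly inside, 0 outside
ad_clip <- function(a, lo, hi) {
  tp <- tape_of(a)
  x <- ad_val(a)
  m <- (x > lo & x < hi) * 1
  out <- ad_new(tp, pmin(pmax(x, lo), hi))
  out$back <- function(g) ad_acc(a, g * m)
  out
}

# elementwise min of two nodes (mask from forward values)
ad_min2 <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_val(a); bv <- ad_val(b)
  m <- (av <= bv) * 1
  out <- ad_new(tp, pmin(av, bv))
  out$back <- function(g) {
    ad_acc(a, g * m)
    ad_acc(b, g * (1 - m))
  }
  out
}

ad_sum <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  out <- ad_new(tp, sum(x))
  out$back <- function(g) ad_acc(a, g + 0 * x)
  out
}

ad_mean <- function(a) {
  n <- length(ad_val(a))
  ad_scale(ad_sum(a), 1 / n)
}

ad_t <- function(a) {
  tp <- tape_of(a)
  out <- ad_new(tp, t(ad_val(a)))
  out$back <- function(g) ad_acc(a, t(g))
  out
}

# row-wise softmax
ad_softmax_rows <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  out <- ad_new(tp, s)
  out$back <- function(g) {
    dot <- rowSums(g * s)
    ad_acc(a, s * (g - dot))
  }
  out
}

ad_rowsums <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  out <- ad_new(tp, matrix(rowSums(x), ncol = 1L))
  out$back <- function(g) ad_acc(a, matrix(g, nrow = nrow(x), ncol = ncol(x)))
  out
}

ad_colmeans <- function(a) {
  tp <- tape_of(a)
  x <- ad_val(a)
  out <- ad_new(tp, matrix(colMeans(x), nrow = 1L))
  out$back <- function(g) {
    ad_acc(a, matrix(rep(as.numeric(g), each = nrow(x)) / nrow(x), nrow = nrow(x)))
  }
  out
}

# column-bind a list of nodes/matrices
ad_cbind <- function(nodes) {
  tp <- NULL
  for (n in nodes) if (is_ad(n)) { tp <- n$tape; break }
  stopifnot(!is.null(tp))
  vals <- lapply(nodes, ad_val)
  ncols <- vapply(vals, function(v) ncol(as.matrix(v)), integer(1))
  out <- ad_new(tp, do.call(cbind, vals))
  out$back <- function(g) {
    off <- 0L
    for (i in seq_along(nodes)) {
      ad_acc(nodes[[i]], g[, (off + 1L):(off + ncols[i]), drop = FALSE])
      off <- off + ncols[i]
    }
  }
  out
}

#' Run the backward pass from a scalar loss node
#' @noRd
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(ad_val(loss)) == 1L)
  tp <- loss$tape
  loss$g <- 1
  for (i in seq(tp$k, 1L)) {
    n <- tp$nodes[[i]]
    if (!is.null(n$g) && !is.null(n$back)) n$back(n$g)
  }
  invisible(NULL)
}

# ---- parameter containers -------------------------------------------------

# Wrap a (possibly nested) list of numeric matrices as tape nodes; returns a
# structure of the same shape whose leaves are nodes, plus a flat list of the
# leaf nodes in deterministic order for gradient collection.
ad_wrap_params <- function(tape, params) {
  leaves <- list()
  wrap <- function(p, path) {
    if (is.list(p)) {
      out <- lapply(seq_along(p), function(i) wrap(p[[i]], c(path, i)))
      names(out) <- names(p)
      out
    } else {
      n <- ad_const(tape, p)
      leaves[[length(leaves) + 1L]] <<- n
      n
    }
  }
  w <- wrap(params, integer())
  list(nodes = w, leaves = leaves)
}

# Collect gradients (zeros where untouched) aligned with ad_wrap_params leaves
ad_grads <- function(wrapped) {
  lapply(wrapped$leaves, function(n) {
    if (is.null(n$g)) 0 * n$v else n$g
  })
}

# Flatten a nested numeric parameter list into leaves (same order as wrap)
param_leaves <- function(params) {
  leaves <- list()
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else leaves[[length(leaves) + 1L]] <<- p
    invisible(NULL)
  }
  walk(params)
  leaves
}

# Rebuild nested structure from flat leaves
param_rebuild <- function(template, leaves) {
  i <- 0L
  build <- function(p) {
    if (is.list(p)) {
      out <- lapply(p, build)
      names(out) <- names(p)
      out
    } else {
      i <<- i + 1L
      leaves[[i]]
    }
  }
  build(template)
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  lv <- param_leaves(params)
  list(m = lapply(lv, function(x) 0 * x),
       v = lapply(lv, function(x) 0 * x),
       t = 0L)
}

# Returns list(params, state).  `grads` is a flat leaf list aligned with
# params; `clip` is a global gradient-norm clip (NULL to disable).
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, clip = NULL) {
  lv <- param_leaves(params)
  stopifnot(length(lv) == length(grads))
  if (!is.null(clip)) {
    nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (nrm > clip && nrm > 0) grads <- lapply(grads, function(g) g * clip / nrm)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(lv)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mh <- state$m[[i]] / bc1
    vh <- state$v[[i]] / bc2
    lv[[i]] <- lv[[i]] - lr * (mh / (sqrt(vh) + eps) + weight_decay * lv[[i]])
  }
  list(params = param_rebuild(params, lv), state = state)
}
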