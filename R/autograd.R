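# Minimal reverse-mode automatic differentiation on a linear tape.
#
# A tape records operations in execution order; each node stores its value,
# its parent node ids and a backward closure mapping the output gradient to
# parent gradients. backward() walks the tape in reverse, accumulating
# gradients by node id. Every op also works "eagerly" on plain arrays when
# tape = NULL, which is the no-grad inference path (intermediates are then
# garbage-collected as they go out of scope).

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  class(t) <- "ag_tape"
  t
}

ag_record <- function(tape, val, parents = integer(0), bwd = NULL) {
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- list(parents = parents, bwd = bwd)
  structure(list(tape = tape, id = tape$n, val = val), class = "ag_node")
}

is_node <- function(x) inherits(x, "ag_node")

ag_val <- function(x) if (is_node(x)) x$val else x

ag_id <- function(x) if (is_node(x)) x$id else NA_integer_

# wrap a plain array as a differentiable leaf
ag_leaf <- function(tape, val) ag_record(tape, val)

acc_grad <- function(grads, id, g) {
  if (is.na(id)) return(grads)
  cur <- grads[[id]]
  grads[[id]] <- if (is.null(cur)) g else cur + g
  grads
}

# Reverse pass from a scalar loss node; returns a list of gradients by id.
ag_backward <- function(loss) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$bwd)) next
    pg <- nd$bwd(g)
    for (j in seq_along(nd$parents))
      if (!is.null(pg[[j]])) grads <- acc_grad(grads, nd$parents[j], pg[[j]])
    grads[[i]] <- NULL   # free as we go
  }
  grads
}

# ---- ops -------------------------------------------------------------------

op_conv3d <- function(tape, x, W, b, k, stride, pad) {
  xv <- ag_val(x); Wv <- ag_val(W); bv <- ag_val(b)
  y <- cpp_conv3d_fwd(xv, Wv, bv, as.integer(k), as.integer(stride),
                      as.integer(pad))
  if (is.null(tape)) return(y)
  need_gx <- is_node(x)
  ag_record(tape, y, parents = c(ag_id(x), ag_id(W), ag_id(b)),
            bwd = function(gy) {
              g <- cpp_conv3d_bwd(xv, Wv, gy, as.integer(k),
                                  as.integer(stride), as.integer(pad), need_gx)
              list(if (need_gx) g$gx, g$gW, as.numeric(g$gb))
            })
}

# Batch normalization over (spatial, batch) per channel. `layer` is an
# environment carrying gamma/beta ids handled by the caller plus running
# moments, updated in training mode.
op_batchnorm <- function(tape, x, gamma, beta, layer, training, eps = 1e-5,
                         momentum = 0.1) {
  xv <- ag_val(x)
  d <- dim(xv); C <- d[4]
  st <- bn_moments(xv)
  if (training) {
    layer$run_mean <- (1 - momentum) * layer$run_mean + momentum * st$mean
    layer$run_var <- (1 - momentum) * layer$run_var + momentum * st$var
    m <- st$mean; v <- st$var
  } else {
    m <- layer$run_mean; v <- layer$run_var
  }
  gv <- ag_val(gamma); bv <- ag_val(beta)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep_channel(xv, m, `-`)
  xhat <- sweep_channel(xhat, inv, `*`)
  y <- sweep_channel(xhat, gv, `*`)
  y <- sweep_channel(y, bv, `+`)
  if (is.null(tape)) return(y)
  ag_record(tape, y, parents = c(ag_id(x), ag_id(gamma), ag_id(beta)),
            bwd = function(gy) {
              dgamma <- channel_sum(gy * xhat)
              dbeta <- channel_sum(gy)
              nper <- length(xv) / C
              if (training) {
                t1 <- sweep_channel(gy, dbeta / nper, `-`)
                t2 <- xhat * sweep_channel(array(1, dim(xv)), dgamma / nper, `*`)
                dx <- sweep_channel(t1 - t2, gv * inv, `*`)
              } else {
                dx <- sweep_channel(gy, gv * inv, `*`)
              }
              list(dx, dgamma, dbeta)
            })
}

# per-channel moments of a (d1,d2,d3,C,N) array
bn_moments <- function(x) {
  d <- dim(x); C <- d[4]
  xm <- aperm(x, c(1, 2, 3, 5, 4))
  dim(xm) <- c(length(x) / C, C)
  m <- colMeans(xm)
  v <- colMeans(xm^2) - m^2
  list(mean = m, var = pmax(v, 0))
}

sweep_channel <- function(x, s, fun) {
  d <- dim(x)
  sc <- rep(rep(s, each = prod(d[1:3])), times = d[5])
  out <- fun(x, sc)
  dim(out) <- d
  out
}

channel_sum <- function(x) {
  d <- dim(x); C <- d[4]
  xm <- aperm(x, c(1, 2, 3, 5, 4))
  dim(xm) <- c(length(x) / C, C)
  colSums(xm)
}

op_relu <- function(tape, x) {
  xv <- ag_val(x)
  y <- pmax(xv, 0); dim(y) <- dim(xv)
  if (is.null(tape)) return(y)
  ag_record(tape, y, parents = ag_id(x),
            bwd = function(gy) list(gy * (xv > 0)))
}

op_leaky_relu <- function(tape, x, slope = 0.2) {
  xv <- ag_val(x)
  y <- ifelse(xv > 0, xv, slope * xv); dim(y) <- dim(xv)
  if (is.null(tape)) return(y)
  ag_record(tape, y, parents = ag_id(x),
            bwd = function(gy) list(gy * ifelse(xv > 0, 1, slope)))
}

op_tanh <- function(tape, x) {
  y <- tanh(ag_val(x))
  if (is.null(tape)) return(y)
  ag_record(tape, y, parents = ag_id(x),
            bwd = function(gy) list(gy * (1 - y^2)))
}

# trilinear resize to an explicit spatial size (used for x2 upsampling)
op_resize <- function(tape, x, out_dim) {
  xv <- ag_val(x)
  in_dim <- dim(xv)[1:3]
  y <- cpp_resize3d(xv, as.integer(out_dim), 0L)
  if (is.null(tape)) return(y)
  ag_record(tape, y, parents = ag_id(x),
            bwd = function(gy) list(cpp_resize3d_bwd(gy, as.integer(in_dim))))
}

op_avgpool <- function(tape, x, f) {
  xv <- ag_val(x)
  in_dim <- dim(xv)[1:3]
  y <- cpp_avgpool3d_fwd(xv, as.integer(f))
  if (is.null(tape)) return(y)
  ag_record(tape, y, parents = ag_id(x),
            bwd = function(gy)
              list(cpp_avgpool3d_bwd(gy, as.integer(in_dim), as.integer(f))))
}

# concatenate along the channel axis (inputs may mix nodes and arrays)
op_concat <- function(tape, xs) {
  vals <- lapply(xs, ag_val)
  d <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[4], numeric(1))
  y <- array(0, c(d[1:3], sum(Cs), d[5]))
  at <- 0L
  for (v in vals) {
    y[, , , (at + 1):(at + dim(v)[4]), ] <- v
    at <- at + dim(v)[4]
  }
  if (is.null(tape)) return(y)
  ids <- vapply(xs, ag_id, integer(1))
  ag_record(tape, y, parents = ids,
            bwd = function(gy) {
              out <- vector("list", length(xs))
              at <- 0L
              for (j in seq_along(xs)) {
                C <- Cs[j]
                if (!is.na(ids[j])) {
                  g <- gy[, , , (at + 1):(at + C), , drop = FALSE]
                  dim(g) <- c(d[1:3], C, d[5])
                  out[[j]] <- g
                }
                at <- at + C
              }
              out
            })
}

# stable mean BCE-with-logits against a constant label (1 = real, 0 = fake)
op_bce_logits <- function(tape, x, target) {
  xv <- ag_val(x)
  n <- length(xv)
  L <- if (target == 1) mean(softplus(-xv)) else mean(softplus(xv))
  if (is.null(tape)) return(L)
  ag_record(tape, L, parents = ag_id(x),
            bwd = function(g) {
              s <- 1 / (1 + exp(-xv))
              list(g * (s - target) / n)
            })
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

op_l1 <- function(tape, pred, gt, reduction = "mean") {
  pv <- ag_val(pred)
  diff <- pv - gt
  L <- if (reduction == "mean") mean(abs(diff)) else sum(abs(diff))
  if (is.null(tape)) return(L)
  den <- if (reduction == "mean") length(diff) else 1
  ag_record(tape, L, parents = ag_id(pred),
            bwd = function(g) list(g * sign(diff) / den))
}

# adjacent-voxel-difference loss between prediction node and constant gt;
# shares the array implementation with avd_loss()
op_avd <- function(tape, pred, gt, reduction = "mean") {
  pv <- ag_val(pred)
  r <- avd_core(gt, pv, reduction)
  if (is.null(tape)) return(r$loss)
  ag_record(tape, r$loss, parents = ag_id(pred),
            bwd = function(g) list(g * r$grad_pred))
}

# weighted sum of scalar nodes
op_weighted_sum <- function(tape, xs, w) {
  L <- sum(vapply(seq_along(xs), function(i) w[i] * ag_val(xs[[i]]), numeric(1)))
  if (is.null(tape)) return(L)
  ag_record(tape, L, parents = vapply(xs, ag_id, integer(1)),
            bwd = function(g) as.list(g * w))
}

op_scale_shift <- function(tape, x, a, b) {
  y <- a * ag_val(x) + b
  if (is.null(tape)) return(y)
  ag_record(tape, y, parents = ag_id(x), bwd = function(g) list(a * g))
}
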