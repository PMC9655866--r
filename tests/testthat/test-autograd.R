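test_that("convolution forward matches a direct sliding-window oracle", {
  set.seed(14)
  x <- array(rnorm(5 * 5 * 5 * 2), c(5, 5, 5, 2, 1))
  W <- matrix(rnorm(54 * 3) * 0.2, 54, 3)
  b <- rnorm(3)
  y <- fusedose:::cpp_conv3d_fwd(x, W, b, 3L, 1L, 1L)
  # direct evaluation at an interior voxel for each output channel
  for (co in 1:3) {
    acc <- b[co]; t <- 0
    for (c in 1:2) for (a1 in 0:2) for (a2 in 0:2) for (a3 in 0:2) {
      t <- t + 1
      acc <- acc + x[2 + a1, 2 + a2, 2 + a3, c, 1] * W[t, co]
    }
    expect_equal(y[3, 3, 3, co, 1], acc, tolerance = 1e-12)
  }
  # border voxel: zero padding
  acc <- b[1]; t <- 0
  for (c in 1:2) for (a1 in 0:2) for (a2 in 0:2) for (a3 in 0:2) {
    t <- t + 1
    i <- c(a1, a2, a3)            # voxel (1,1,1): offsets -1,0,1 -> index 0..2
    if (all(i >= 1)) acc <- acc + x[i[1], i[2], i[3], c, 1] * W[t, 1]
  }
  expect_equal(y[1, 1, 1, 1, 1], acc, tolerance = 1e-12)
})

test_that("convolution gradients match central differences for every stride/kernel", {
  set.seed(15)
  eps <- 1e-6
  for (cfg in list(list(k = 3L, s = 1L), list(k = 3L, s = 2L),
                   list(k = 4L, s = 2L), list(k = 4L, s = 1L))) {
    x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2, 2))
    K <- cfg$k^3 * 2L
    W <- matrix(rnorm(K * 3) * 0.1, K, 3)
    b <- rnorm(3)
    y <- fusedose:::cpp_conv3d_fwd(x, W, b, cfg$k, cfg$s, 1L)
    gy <- array(rnorm(length(y)), dim(y))
    g <- fusedose:::cpp_conv3d_bwd(x, W, gy, cfg$k, cfg$s, 1L, TRUE)
    f <- function(xx, WW, bb)
      sum(fusedose:::cpp_conv3d_fwd(xx, WW, bb, cfg$k, cfg$s, 1L) * gy)
    for (r in 1:4) {
      i <- sample(length(x), 1)
      xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
      expect_equal(g$gx[i], (f(xp, W, b) - f(xm, W, b)) / (2 * eps),
                   tolerance = 1e-4)
      j <- sample(length(W), 1)
      Wp <- W; Wp[j] <- Wp[j] + eps; Wm <- W; Wm[j] <- Wm[j] - eps
      expect_equal(g$gW[j], (f(x, Wp, b) - f(x, Wm, b)) / (2 * eps),
                   tolerance = 1e-4)
    }
    expect_equal(as.numeric(g$gb),
                 apply(gy, 4, sum), tolerance = 1e-8)
  }
})

test_that("batch norm normalizes per channel and backpropagates exactly", {
  set.seed(16)
  l <- fusedose:::new_conv_layer(1, 3, 3, 1, 1, norm = "batch")
  x <- array(rnorm(6 * 6 * 6 * 3 * 2, mean = 2, sd = 4), c(6, 6, 6, 3, 2))
  y <- fusedose:::op_batchnorm(NULL, x, l$gamma, l$beta, l, training = TRUE)
  st <- fusedose:::bn_moments(y)
  expect_equal(st$mean, rep(0, 3), tolerance = 1e-10)
  expect_equal(st$var, rep(1, 3), tolerance = 1e-6)
  # gradient wrt input, gamma and beta against central differences
  gamma <- runif(3, 0.5, 2); beta <- rnorm(3)
  gy <- array(rnorm(length(x)), dim(x))
  fwd <- function(xx, gg, bb) {
    ll <- fusedose:::new_conv_layer(1, 3, 3, 1, 1, norm = "batch")
    sum(fusedose:::op_batchnorm(NULL, xx, gg, bb, ll, training = TRUE) * gy)
  }
  tape <- fusedose:::new_tape()
  xi <- fusedose:::ag_leaf(tape, x)
  gi <- fusedose:::ag_leaf(tape, gamma)
  bi <- fusedose:::ag_leaf(tape, beta)
  yy <- fusedose:::op_batchnorm(tape, xi, gi, bi, l, training = TRUE)
  L <- fusedose:::ag_record(tape, sum(fusedose:::ag_val(yy) * gy),
                            parents = yy$id, bwd = function(g) list(g * gy))
  grads <- fusedose:::ag_backward(L)
  eps <- 1e-6
  for (r in 1:5) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
    expect_equal(grads[[xi$id]][i],
                 (fwd(xp, gamma, beta) - fwd(xm, gamma, beta)) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (c in 1:3) {
    gp <- gamma; gp[c] <- gp[c] + eps; gm <- gamma; gm[c] <- gm[c] - eps
    expect_equal(grads[[gi$id]][c],
                 (fwd(x, gp, beta) - fwd(x, gm, beta)) / (2 * eps),
                 tolerance = 1e-4)
    bp <- beta; bp[c] <- bp[c] + eps; bm <- beta; bm[c] <- bm[c] - eps
    expect_equal(grads[[bi$id]][c],
                 (fwd(x, gamma, bp) - fwd(x, gamma, bm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(17)
  net <- build_discriminator(discriminator_spec("C", width_mult = 1 / 24),
                             seed = 9)
  x <- array(rnorm(24^3 * 2, sd = 0.5), c(24, 24, 24, 2, 2))
  loss_of <- function(n) {
    l <- discriminator_forward(n, x, tape = NULL, training = TRUE)
    mean(fusedose:::softplus(-l))
  }
  tape <- fusedose:::new_tape()
  wd <- fusedose:::wrap_network(tape, net)
  st0 <- fusedose:::network_state(net)
  l <- discriminator_forward(net, fusedose:::ag_leaf(tape, x), tape,
                             training = TRUE, wrapped = wd)
  L <- fusedose:::op_bce_logits(tape, l, 1)
  gd <- fusedose:::wrapped_grads(wd, fusedose:::ag_backward(L), net)
  fusedose:::restore_network_state(net, st0)
  eps <- 1e-6
  for (key in c("d1/W", "d2/W", "d2/gamma", "d3/beta", "d4/W", "d5/b")) {
    parts <- strsplit(key, "/")[[1]]
    for (r in 1:2) {
      idx <- sample(length(net$layers[[parts[1]]][[parts[2]]]), 1)
      v0 <- net$layers[[parts[1]]][[parts[2]]][idx]
      net$layers[[parts[1]]][[parts[2]]][idx] <- v0 + eps
      lp <- loss_of(net); fusedose:::restore_network_state(net, st0)
      net$layers[[parts[1]]][[parts[2]]][idx] <- v0 - eps
      lm <- loss_of(net); fusedose:::restore_network_state(net, st0)
      num <- (lp - lm) / (2 * eps)
      expect_equal(gd[[key]][idx], num, tolerance = 2e-3)
    }
  }
})

test_that("pooling and resize adjoints are exact", {
  set.seed(18)
  x <- array(rnorm(8 * 8 * 8 * 2 * 1), c(8, 8, 8, 2, 1))
  # adjoint identity <A x, y> = <x, A^T y>
  y <- array(rnorm(4 * 4 * 4 * 2 * 1), c(4, 4, 4, 2, 1))
  Ax <- fusedose:::cpp_avgpool3d_fwd(x, 2L)
  Aty <- fusedose:::cpp_avgpool3d_bwd(y, dim(x)[1:3], 2L)
  expect_equal(sum(Ax * y), sum(x * Aty), tolerance = 1e-10)
  yb <- array(rnorm(16 * 16 * 16 * 2 * 1), c(16, 16, 16, 2, 1))
  Bx <- fusedose:::cpp_resize3d(x, c(16L, 16L, 16L), 0L)
  Bty <- fusedose:::cpp_resize3d_bwd(yb, dim(x)[1:3])
  expect_equal(sum(Bx * yb), sum(x * Bty), tolerance = 1e-10)
})
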