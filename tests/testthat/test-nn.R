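test_that("GCN on a single isolated node reduces to a feedforward map", {
  set.seed(1)
  p <- init_gcn(c(6, 4, 1))
  x <- matrix(runif(6), 1, 6)
  out <- gcn_forward(x, matrix(0, 1, 1), p)
  expect_equal(dim(out), c(1, 1))
  expect_equal(out[1, 1], (pmax(x %*% p$W[[1]], 0) %*% p$W[[2]])[1, 1])
})

test_that("GCN is equivariant under simultaneous permutation", {
  set.seed(2)
  p <- init_gcn(c(6, 8, 8, 1))
  for (i in 1:20) {
    L <- sample(3:10, 1)
    X <- matrix(runif(L * 6), L, 6)
    A <- random_adjacency(L)
    perm <- sample(L)
    y <- gcn_forward(X, A, p)
    yp <- gcn_forward(X[perm, , drop = FALSE], A[perm, perm], p)
    expect_equal(yp, y[perm, , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("GCN maps zero features to zero and rejects bad shapes", {
  set.seed(3)
  p <- init_gcn(c(6, 4, 1))
  out <- gcn_forward(matrix(0, 5, 6), random_adjacency(5), p)
  expect_equal(out, matrix(0, 5, 1))
  expect_error(gcn_forward(matrix(0, 5, 4), random_adjacency(5), p), "shape")
})

test_that("GCN analytic gradients match finite differences", {
  set.seed(4)
  p <- init_gcn(c(6, 5, 1))
  L <- 4
  X <- matrix(runif(L * 6), L, 6)
  S <- spreadrank:::gcn_propagation(random_adjacency(L))
  cvec <- matrix(rnorm(L), ncol = 1)
  loss <- function(flat) {
    p2 <- p
    p2$W <- unflatten(flat, p$W)
    sum(spreadrank:::.gcn_fwd(X, S, p2)$out * cvec)
  }
  cache <- spreadrank:::.gcn_fwd(X, S, p)
  ana <- unlist(spreadrank:::.gcn_bwd(cache, cvec, p)$W)
  fd <- num_grad(loss, unlist(p$W))
  expect_equal(ana, fd, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("LSTM recurrence matches a hand-computed two-unit example", {
  p <- init_lstm(input_width = 1, hidden = 2)
  p$W$i <- matrix(c(0.5, 0.5, 0.1, -0.3, 0.2, 0.4), 2, byrow = TRUE)
  p$W$f <- matrix(c(0.2, -0.1, 0.3, 0.4, 0.1, -0.2), 2, byrow = TRUE)
  p$W$o <- matrix(c(-0.2, 0.3, 0.5, 0.1, -0.4, 0.2), 2, byrow = TRUE)
  p$W$c <- matrix(c(0.3, 0.2, -0.1, -0.5, 0.1, 0.3), 2, byrow = TRUE)
  p$b <- list(i = c(0.1, -0.1), f = c(1, 1), o = c(0, 0.2), c = c(-0.2, 0.1))
  p$wy <- c(0.7, -0.6); p$by <- 0.05
  X <- matrix(c(0.8, -0.5), 2, 1)
  fw <- spreadrank:::.lstm_fwd(X, p)
  # frozen values from an independent implementation of the gate equations
  expect_equal(fw$out[, 1], c(-0.0753742491, -0.0488977747), tolerance = 1e-9)
  expect_equal(fw$steps[[2]]$cc, c(-0.18260239, 0.13754411), tolerance = 1e-7)
  # cell update identity C_t = f*C_{t-1} + i*g at every step
  for (t in 1:2) {
    s <- fw$steps[[t]]
    expect_equal(s$cc, s$gf * s$c_prev + s$gi * s$gc, tolerance = 1e-12)
    expect_true(all(s$gi > 0 & s$gi < 1))
    expect_true(all(s$gf > 0 & s$gf < 1))
    expect_true(all(s$go > 0 & s$go < 1))
  }
})

test_that("LSTM with zero input, state and biases stays at zero", {
  set.seed(5)
  p <- init_lstm(input_width = 3, hidden = 4)
  p$b <- lapply(p$b, function(b) b * 0)
  p$by <- 0
  fw <- spreadrank:::.lstm_fwd(matrix(0, 5, 3), p)
  expect_true(all(vapply(fw$steps, function(s) max(abs(s$h)), 1) == 0))
  expect_equal(fw$out, matrix(0, 5, 1))
  expect_error(lstm_forward(matrix(0, 0, 3), p), "empty")
})

test_that("LSTM analytic gradients match finite differences", {
  set.seed(6)
  p <- init_lstm(input_width = 2, hidden = 3)
  X <- matrix(rnorm(8), 4, 2)
  dy <- rnorm(4)
  skel <- list(W = p$W, b = p$b, wy = p$wy, by = p$by)
  loss <- function(flat) {
    t2 <- unflatten(flat, skel)
    p2 <- p
    p2$W <- t2$W; p2$b <- t2$b; p2$wy <- t2$wy; p2$by <- t2$by
    sum(spreadrank:::.lstm_fwd(X, p2)$out[, 1] * dy)
  }
  cache <- spreadrank:::.lstm_fwd(X, p)
  g <- spreadrank:::.lstm_bwd(cache, dy, p)
  ana <- unlist(list(W = g$W, b = g$b, wy = g$wy, by = g$by))
  fd <- num_grad(loss, unlist(skel))
  expect_equal(ana, fd, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("batch normalisation centres the batch and back-propagates exactly", {
  bn <- init_bn()
  v <- c(0.2, 1.5, -0.7, 0.9)
  fw <- spreadrank:::.bn_fwd(v, bn, train = TRUE)
  expect_equal(mean(fw$out), 0, tolerance = 1e-12)  # gamma=1, beta=0
  expect_equal(sd(fw$out) * sqrt(3 / 4), 1, tolerance = 1e-3)
  # fusion keeps shape and zero maps to zero at beta=0
  fused <- bn_fuse(rep(0, 4), rep(0, 4), init_bn(), init_bn(), train = FALSE)
  expect_equal(fused$out, matrix(0, 4, 1))
  # gradient check (train mode)
  dout <- rnorm(4)
  loss <- function(x) sum(spreadrank:::.bn_fwd(x, bn, TRUE)$out * dout)
  bw <- spreadrank:::.bn_bwd(fw$cache, dout, bn)
  expect_equal(bw$dv, num_grad(loss, v), tolerance = 1e-6)
  expect_equal(bw$beta, sum(dout))
})

test_that("running statistics drive evaluation-mode normalisation", {
  bn <- init_bn(momentum = 0.5)
  fw1 <- spreadrank:::.bn_fwd(c(1, 2, 3), bn, train = TRUE)
  bn2 <- fw1$params
  expect_gt(bn2$running_mean, 0)
  ev <- spreadrank:::.bn_fwd(c(1, 2, 3), bn2, train = FALSE)
  manual <- (c(1, 2, 3) - bn2$running_mean) / sqrt(bn2$running_var + bn2$eps)
  expect_equal(ev$out, manual)
})

test_that("the MLP head computes the documented feedforward map", {
  p <- init_mlp(input_width = 4, hidden = 3)
  # single effective linear layer: relu passthrough with identity-ish W1
  p$W1 <- matrix(0, 3, 4); p$W1[1, ] <- 1 / 4
  p$b1 <- rep(0, 3)
  p$W2 <- matrix(c(1, 0, 0), 1, 3); p$b2 <- 0
  expect_equal(mlp_score(c(1, 2, 3, 4), p), 2.5)  # row mean
  expect_equal(mlp_score(rep(0, 4), p), 0)
  set.seed(7)
  p2 <- init_mlp(4, 3)
  x <- runif(4)
  expect_identical(mlp_score(x, p2), mlp_score(x, p2))
  # gradient check
  X <- matrix(rnorm(8), 2, 4)
  ds <- rnorm(2)
  skel <- list(W1 = p2$W1, b1 = p2$b1, W2 = p2$W2, b2 = p2$b2)
  loss <- function(flat) {
    t2 <- unflatten(flat, skel)
    p3 <- p2; p3$W1 <- t2$W1; p3$b1 <- t2$b1; p3$W2 <- t2$W2; p3$b2 <- t2$b2
    sum(spreadrank:::.mlp_fwd(X, p3)$out * ds)
  }
  g <- spreadrank:::.mlp_bwd(spreadrank:::.mlp_fwd(X, p2), ds, p2)
  ana <- unlist(list(W1 = g$W1, b1 = g$b1, W2 = g$W2, b2 = g$b2))
  expect_equal(ana, num_grad(loss, unlist(skel)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mean absolute error satisfies its identities", {
  expect_equal(mae_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae_loss(c(0, 1), c(1, 0)), 1)
  expect_equal(mae_loss(c(1, 2, 3), c(1, 2, 3) + 0.7), 0.7)
  set.seed(8)
  a <- rnorm(10); b <- rnorm(10)
  expect_gte(mae_loss(a, b), 0)
  expect_error(mae_loss(1:3, 1:4), "length")
})

test_that("forward passes stay finite on [0,1]-scaled inputs", {
  set.seed(9)
  p <- init_gcn()
  q <- init_lstm(input_width = 6 + 10)
  for (i in 1:5) {
    L <- sample(2:8, 1)
    X <- matrix(runif(L * 6), L, 6)
    A <- random_adjacency(L)
    expect_true(all(is.finite(gcn_forward(X, A, p))))
    M <- cbind(X, matrix(runif(L * 10), L, 10))
    expect_true(all(is.finite(lstm_forward(M, q))))
  }
})
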