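# Neural scoring machinery, written as transparent base-R matrix code with
# analytic gradients (verified against finite differences in the test
# suite):
#
#   * GCN spatial encoder: symmetric-normalised propagation with self-loops,
#     ReLU hidden layers, linear scalar output per subnetwork member;
#   * LSTM temporal encoder over the member sequence, scalar per-step head;
#   * per-branch batch normalisation followed by elementwise summation;
#   * MLP global head mapping a history-matrix row to one influence score;
#   * mean-absolute-error loss; Adam optimiser.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) pmax(x, 0)

.glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# ---------------------------------------------------------------- GCN ------

#' Initialise GCN parameters
#'
#' Layer widths default to 6 -> 32 -> 32 -> 1 (two ReLU hidden layers, a
#' linear scalar output). Weights are Glorot-uniform draws from the current
#' RNG state; the propagation uses no biases.
#'
#' @param widths Integer vector of chained layer widths; first must be 6
#'   columns of the spatial feature matrix unless features differ.
#' @return A list of weight matrices (class `"gcn_params"`).
#' @export
init_gcn <- function(widths = c(6, 32, 32, 1)) {
  stopifnot(length(widths) >= 2)
  W <- lapply(seq_len(length(widths) - 1),
              function(l) .glorot(widths[l], widths[l + 1]))
  structure(list(W = W, widths = widths), class = "gcn_params")
}

# symmetric-normalised propagation matrix with self-loops
gcn_propagation <- function(adjacency) {
  L <- nrow(adjacency)
  at <- adjacency + diag(L)
  dinv <- 1 / sqrt(rowSums(at))
  at * (dinv %o% dinv)
}

.gcn_fwd <- function(X, S, params) {
  nl <- length(params$W)
  H <- vector("list", nl + 1)
  SH <- vector("list", nl)  # S %*% H[[l]] per layer, reused in backward
  H[[1]] <- X
  for (l in seq_len(nl)) {
    SH[[l]] <- S %*% H[[l]]
    Z <- SH[[l]] %*% params$W[[l]]
    H[[l + 1]] <- if (l < nl) .relu(Z) else Z
  }
  list(out = H[[nl + 1]], H = H, SH = SH, S = S)
}

.gcn_bwd <- function(cache, dY, params) {
  nl <- length(params$W)
  dW <- vector("list", nl)
  dH <- dY
  for (l in rev(seq_len(nl))) {
    dZ <- if (l < nl) dH * (cache$H[[l + 1]] > 0) else dH
    dW[[l]] <- crossprod(cache$SH[[l]], dZ)
    dH <- cache$S %*% (dZ %*% t(params$W[[l]]))  # S symmetric
  }
  list(W = dW, dX = dH)
}

#' GCN forward pass over one subnetwork
#'
#' Applies `H^{(l+1)} = sigma(D^{-1/2} (A+I) D^{-1/2} H^{(l)} W^{(l)})` with
#' ReLU on hidden layers and a linear final layer, yielding the `L x 1`
#' spatial influence representation of the subnetwork members. The pass is
#' equivariant under simultaneous permutation of rows of the features and
#' the adjacency.
#'
#' @param features `L x 6` spatial feature matrix.
#' @param adjacency Symmetric `L x L` 0/1 matrix with zero diagonal.
#' @param params A `gcn_params` object.
#' @return An `L x 1` matrix.
#' @export
gcn_forward <- function(features, adjacency, params) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(adjacency) || ncol(features) != params$widths[1]) {
    stop("gcn_forward: inconsistent shapes", call. = FALSE)
  }
  .gcn_fwd(features, gcn_propagation(adjacency), params)$out
}

# ---------------------------------------------------------------- LSTM -----

#' Initialise LSTM parameters
#'
#' Standard gated recurrence with input/forget/output/candidate paths and a
#' scalar linear head per step. Gate weights act on the concatenation
#' `[h_{t-1}, x_t]`. Weights are Glorot-uniform from the current RNG state,
#' biases zero except the forget-gate bias, initialised to +1.
#'
#' @param input_width Width of each step's input vector.
#' @param hidden Hidden width (default 32).
#' @return A list of gate matrices/biases (class `"lstm_params"`).
#' @export
init_lstm <- function(input_width, hidden = 32) {
  d <- hidden + input_width
  W <- lapply(c(i = 1, f = 2, o = 3, c = 4), function(k) .glorot(hidden, d))
  names(W) <- c("i", "f", "o", "c")
  b <- list(i = rep(0, hidden), f = rep(1, hidden), o = rep(0, hidden),
            c = rep(0, hidden))
  structure(list(W = W, b = b, wy = .glorot(hidden, 1)[, 1], by = 0,
                 hidden = hidden, input_width = input_width),
            class = "lstm_params")
}

.lstm_fwd <- function(X, params) {
  Tn <- nrow(X)
  hid <- params$hidden
  h <- numeric(hid); cc <- numeric(hid)
  steps <- vector("list", Tn)
  y <- numeric(Tn)
  for (t in seq_len(Tn)) {
    v <- c(h, X[t, ])
    gi <- .sigmoid(params$W$i %*% v + params$b$i)[, 1]
    gf <- .sigmoid(params$W$f %*% v + params$b$f)[, 1]
    go <- .sigmoid(params$W$o %*% v + params$b$o)[, 1]
    gc_ <- tanh(params$W$c %*% v + params$b$c)[, 1]
    c_prev <- cc
    cc <- gf * c_prev + gi * gc_
    th <- tanh(cc)
    h <- go * th
    y[t] <- sum(params$wy * h) + params$by
    steps[[t]] <- list(v = v, gi = gi, gf = gf, go = go, gc = gc_,
                       c_prev = c_prev, cc = cc, th = th, h = h)
  }
  list(out = matrix(y, ncol = 1), steps = steps)
}

.lstm_bwd <- function(cache, dy, params) {
  hid <- params$hidden
  Tn <- length(cache$steps)
  g <- list(W = lapply(params$W, function(w) w * 0),
            b = lapply(params$b, function(b) b * 0),
            wy = params$wy * 0, by = 0)
  dh_next <- numeric(hid); dc_next <- numeric(hid)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    g$wy <- g$wy + dy[t] * s$h
    g$by <- g$by + dy[t]
    dh <- dy[t] * params$wy + dh_next
    do_ <- dh * s$th
    dc <- dh * s$go * (1 - s$th^2) + dc_next
    di <- dc * s$gc
    dgc <- dc * s$gi
    df <- dc * s$c_prev
    dc_next <- dc * s$gf
    dz <- list(i = di * s$gi * (1 - s$gi),
               f = df * s$gf * (1 - s$gf),
               o = do_ * s$go * (1 - s$go),
               c = dgc * (1 - s$gc^2))
    dv <- numeric(length(s$v))
    for (k in names(dz)) {
      g$W[[k]] <- g$W[[k]] + dz[[k]] %o% s$v
      g$b[[k]] <- g$b[[k]] + dz[[k]]
      dv <- dv + as.numeric(crossprod(params$W[[k]], dz[[k]]))
    }
    dh_next <- dv[seq_len(hid)]
  }
  g
}

#' LSTM forward pass over a subnetwork member sequence
#'
#' Runs the gated recurrence over the rows of `sequence` (one row per
#' member, in member order) and projects each hidden state to a scalar,
#' yielding the `L x 1` temporal influence representation.
#'
#' @param sequence `L x input_width` matrix of step inputs.
#' @param params An `lstm_params` object.
#' @return An `L x 1` matrix.
#' @export
lstm_forward <- function(sequence, params) {
  sequence <- as.matrix(sequence)
  if (nrow(sequence) < 1L) stop("lstm_forward: empty sequence", call. = FALSE)
  if (ncol(sequence) != params$input_width) {
    stop("lstm_forward: input width mismatch", call. = FALSE)
  }
  .lstm_fwd(sequence, params)$out
}

# ---------------------------------------------------------------- BN -------

#' Initialise batch-normalisation parameters
#'
#' One learnable scale/shift pair plus running statistics, used per branch
#' (spatial and temporal each get their own set).
#'
#' @param eps Numerical stabiliser (default 1e-5).
#' @param momentum Running-statistics update rate (default 0.1).
#' @return A list (class `"bn_params"`).
#' @export
init_bn <- function(eps = 1e-5, momentum = 0.1) {
  structure(list(gamma = 1, beta = 0, running_mean = 0, running_var = 1,
                 eps = eps, momentum = momentum), class = "bn_params")
}

.bn_fwd <- function(v, params, train) {
  if (train) {
    mu <- mean(v)
    va <- mean((v - mu)^2)
    params$running_mean <- (1 - params$momentum) * params$running_mean +
      params$momentum * mu
    params$running_var <- (1 - params$momentum) * params$running_var +
      params$momentum * va
  } else {
    mu <- params$running_mean
    va <- params$running_var
  }
  xhat <- (v - mu) / sqrt(va + params$eps)
  list(out = params$gamma * xhat + params$beta,
       cache = list(xhat = xhat, va = va, n = length(v), train = train),
       params = params)
}

.bn_bwd <- function(cache, dout, params) {
  dgamma <- sum(dout * cache$xhat)
  dbeta <- sum(dout)
  dxhat <- dout * params$gamma
  ivar <- 1 / sqrt(cache$va + params$eps)
  if (cache$train) {
    m <- cache$n
    dv <- ivar / m * (m * dxhat - sum(dxhat) - cache$xhat * sum(dxhat * cache$xhat))
  } else {
    dv <- dxhat * ivar
  }
  list(gamma = dgamma, beta = dbeta, dv = dv)
}

#' Batch-normalised fusion of spatial and temporal branches
#'
#' Normalises each branch with its own batch-norm parameters (over the L
#' entries of the branch output) and returns the elementwise sum. In
#' training mode the batch statistics are used and the running statistics
#' updated; in evaluation mode the running statistics are used.
#'
#' @param spatial,temporal `L x 1` branch outputs.
#' @param bn_s,bn_t `bn_params` for each branch.
#' @param train Logical; training (batch statistics) or evaluation mode.
#' @return A list: `out` (`L x 1` fused representation) and the possibly
#'   updated `bn_s`, `bn_t`.
#' @export
bn_fuse <- function(spatial, temporal, bn_s, bn_t, train = FALSE) {
  stopifnot(length(spatial) == length(temporal))
  fs <- .bn_fwd(as.numeric(spatial), bn_s, train)
  ft <- .bn_fwd(as.numeric(temporal), bn_t, train)
  list(out = matrix(fs$out + ft$out, ncol = 1), bn_s = fs$params, bn_t = ft$params)
}

# ---------------------------------------------------------------- MLP ------

#' Initialise the MLP global head
#'
#' Feedforward map from a history-matrix row (width N) to one scalar
#' influence score; default one ReLU hidden layer of width 64.
#'
#' @param input_width Row width N.
#' @param hidden Hidden width (default 64).
#' @return A list (class `"mlp_params"`).
#' @export
init_mlp <- function(input_width, hidden = 64) {
  structure(list(W1 = .glorot(hidden, input_width), b1 = rep(0, hidden),
                 W2 = .glorot(1, hidden), b2 = 0,
                 input_width = input_width, hidden = hidden),
            class = "mlp_params")
}

.mlp_fwd <- function(X, params) {
  H <- .relu(X %*% t(params$W1) + rep(params$b1, each = nrow(X)))
  list(out = as.numeric(H %*% t(params$W2) + params$b2), H = H, X = X)
}

.mlp_bwd <- function(cache, ds, params) {
  dW2 <- matrix(ds, 1) %*% cache$H
  db2 <- sum(ds)
  dH <- (ds %o% params$W2[1, ]) * (cache$H > 0)
  list(W1 = crossprod(dH, cache$X), b1 = colSums(dH), W2 = dW2, b2 = db2)
}

#' MLP global influence score
#'
#' @param history_rows A history-matrix row (length N) or an `N x N` matrix
#'   of rows.
#' @param params An `mlp_params` object.
#' @return A numeric score per row.
#' @export
mlp_score <- function(history_rows, params) {
  X <- if (is.matrix(history_rows)) history_rows else matrix(history_rows, nrow = 1)
  if (ncol(X) != params$input_width) stop("mlp_score: row width mismatch", call. = FALSE)
  .mlp_fwd(X, params)$out
}

# ---------------------------------------------------------------- loss -----

#' Mean absolute error
#'
#' @param predicted,target Equal-length numeric vectors.
#' @return The mean of absolute differences (>= 0, 0 iff equal).
#' @export
mae_loss <- function(predicted, target) {
  if (length(predicted) != length(target)) {
    stop("mae_loss: length mismatch", call. = FALSE)
  }
  mean(abs(as.numeric(predicted) - as.numeric(target)))
}

.mae_grad <- function(predicted, target) {
  sign(as.numeric(predicted) - as.numeric(target)) / length(predicted)
}

# ---------------------------------------------------------------- Adam -----

# Adam over an arbitrarily nested list of numeric arrays. State mirrors the
# parameter structure; `t` is the shared step counter.
.adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
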