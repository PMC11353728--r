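# The spreadrank model: heuristic joint local/global optimisation of the
# spatiotemporal scorer.
#
# Per epoch the N x N history matrix is zeroed and the subnetworks are
# visited in ascending node-id order. For each subnetwork the local loop
# runs `local_steps` iterations of GCN -> LSTM -> batch-norm fusion, trains
# GCN/LSTM/BN on the subnetwork MAE loss, and keeps the fused output with
# the best Kendall agreement against the subnetwork labels; the best output
# is then written into the subnetwork's history-matrix column at the member
# rows. After all subnetworks, the MLP head maps each history row to a
# global score and is trained on the network-wide MAE loss. History entries
# are numeric constants between the two phases (the global step updates the
# MLP only).

# tau-b on the non-PAD entries; NA when undefined (constant input)
.kd_gate <- function(pred, lab) {
  suppressWarnings(stats::cor(pred, lab, method = "kendall"))
}

.local_theta <- function(p) {
  list(gcn = p$gcn$W,
       lstm = list(W = p$lstm$W, b = p$lstm$b, wy = p$lstm$wy, by = p$lstm$by),
       bn = list(s = list(gamma = p$bn_s$gamma, beta = p$bn_s$beta),
                 t = list(gamma = p$bn_t$gamma, beta = p$bn_t$beta)))
}

.set_local_theta <- function(p, th) {
  p$gcn$W <- th$gcn
  p$lstm$W <- th$lstm$W; p$lstm$b <- th$lstm$b
  p$lstm$wy <- th$lstm$wy; p$lstm$by <- th$lstm$by
  p$bn_s$gamma <- th$bn$s$gamma; p$bn_s$beta <- th$bn$s$beta
  p$bn_t$gamma <- th$bn$t$gamma; p$bn_t$beta <- th$bn$t$beta
  p
}

# one local forward pass; returns branch caches and fused output
.local_forward <- function(X, S, M_in, p, train) {
  gcnc <- .gcn_fwd(X, S, p$gcn)
  lstmc <- .lstm_fwd(M_in, p$lstm)
  bs <- .bn_fwd(gcnc$out[, 1], p$bn_s, train)
  bt <- .bn_fwd(lstmc$out[, 1], p$bn_t, train)
  p$bn_s <- bs$params
  p$bn_t <- bt$params
  list(fused = matrix(bs$out + bt$out, ncol = 1), gcnc = gcnc, lstmc = lstmc,
       bs = bs, bt = bt, params = p)
}

#' Fit a spatiotemporal node-influence ranking model
#'
#' Trains the full scorer on a network: SIR Monte-Carlo influence labels
#' (computed when not supplied), ego-subnetwork feature tensors, a GCN
#' spatial encoder and LSTM temporal encoder fused by batch normalisation
#' and trained per subnetwork under a Kendall-gated local loop, and an MLP
#' global head over the history matrix trained on the network-wide loss.
#' All losses are mean absolute error; optimisation is Adam.
#'
#' Typical use trains on a structure-matched null model of an empirical
#' network (see [generate_null()]) and transfers to the empirical network
#' with [predict.spreadrank()].
#'
#' @param graph The training network (igraph object).
#' @param labels Optional influence labels (length N); computed by
#'   [sir_labels()] at `beta`/`reps` when `NULL`.
#' @param beta Infection probability for label construction; `NULL` for the
#'   epidemic threshold.
#' @param reps SIR repetitions per node; `NULL` for [iteration_schedule()].
#' @param epochs Number of training epochs (default 20).
#' @param local_steps Local-loop iterations per subnetwork per epoch
#'   (default 5). The optimum is network-dependent: larger subnetworks
#'   benefit from more local iterations.
#' @param global_steps Adam iterations of the global MLP phase per epoch
#'   (default 100). The history matrix is fixed during the global phase,
#'   so these are cheap full-batch steps.
#' @param lr Adam learning rate (default 1e-3).
#' @param L Subnetwork size; `NULL` for [subnet_size()].
#' @param gcn_widths GCN layer widths (default `c(6, 32, 32, 1)`).
#' @param lstm_hidden LSTM hidden width (default 32).
#' @param mlp_hidden MLP hidden width (default 64).
#' @param seed Integer seed governing labels, initialisation and training.
#' @param verbose Print per-epoch global loss.
#' @return An object of class `"spreadrank"`; see Details.
#' @details The returned object contains `scores` (the fitted global
#'   influence scores on the training network), `history` (the final
#'   N x N history matrix), `params` (all trained parameter sets), `gloss`
#'   (per-epoch global loss), `kd_best` (per-subnetwork best local Kendall,
#'   final epoch), `kd_trace` (the gated best-Kendall sequences, final
#'   epoch), `lloss_first`/`lloss_last` (per-subnetwork local loss at the
#'   first and last local iteration, final epoch) and the training
#'   configuration.
#' @seealso [predict.spreadrank()], [kendall_tau()], [baseline_scores()]
#' @export
spreadrank <- function(graph, labels = NULL, beta = NULL, reps = NULL,
                       epochs = 20L, local_steps = 5L, global_steps = 100L,
                       lr = 1e-3, L = NULL,
                       gcn_widths = c(6, 32, 32, 1), lstm_hidden = 32L,
                       mlp_hidden = 64L, seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, local_steps >= 1)
  cl <- match.call()
  graph <- as_network(graph)
  n <- igraph::vcount(graph)
  set.seed(seed)
  if (is.null(labels)) {
    if (is.null(beta)) beta <- epidemic_threshold(graph)
    labels <- sir_labels(graph, beta = beta, reps = reps)
  }
  ds <- build_subnet_dataset(graph, labels, L)
  Ln <- ds$L

  p <- list(gcn = init_gcn(gcn_widths),
            lstm = init_lstm(input_width = 6L + n, hidden = lstm_hidden),
            bn_s = init_bn(), bn_t = init_bn(),
            mlp = init_mlp(input_width = n, hidden = mlp_hidden))
  st_local <- .adam_init(.local_theta(p))
  st_global <- .adam_init(list(W1 = p$mlp$W1, b1 = p$mlp$b1,
                               W2 = p$mlp$W2, b2 = p$mlp$b2))

  gloss <- numeric(epochs)
  kd_best_all <- numeric(n)
  kd_trace <- vector("list", n)
  lloss_first <- lloss_last <- numeric(n)
  local_iters <- 0L
  Fh <- NULL
  Is <- NULL

  # propagation matrices are fixed per subnetwork
  Slist <- lapply(seq_len(n), function(v) gcn_propagation(ds$adjacency[v, , ]))

  for (ep in seq_len(epochs)) {
    Fh <- matrix(0, n, n)
    for (ti in seq_len(n)) {
      X <- matrix(ds$features[ti, , ], Ln, 6)
      S <- Slist[[ti]]
      lab <- ds$labels[ti, , 1]
      mem <- ds$members[ti, ]
      real <- which(!is.na(mem))
      # LSTM step inputs: spatial features || member's history row. Columns
      # >= ti of the history matrix are still zero here (columns are filled
      # in ascending ti order and the matrix is reset each epoch), so only
      # past subnetworks' information is visible.
      M_in <- matrix(0, Ln, 6L + n)
      M_in[, 1:6] <- X
      M_in[real, 7:(6L + n)] <- Fh[mem[real], , drop = FALSE]

      kd_best <- -Inf
      cached <- NULL
      trace <- numeric(local_steps)
      for (stp in seq_len(local_steps)) {
        fw <- .local_forward(X, S, M_in, p, train = TRUE)
        p <- fw$params
        fused <- fw$fused
        lloss <- mae_loss(fused, lab)
        if (!is.finite(lloss)) {
          stop("non-finite local loss at epoch ", ep, ", subnet ", ti,
               call. = FALSE)
        }
        if (stp == 1L) lloss_first[ti] <- lloss
        lloss_last[ti] <- lloss
        if (length(real) < 2L) {
          cached <- fused
        } else {
          kd <- .kd_gate(fused[real], lab[real])
          if (is.null(cached) || (!is.na(kd) && kd > kd_best)) {
            cached <- fused
            if (!is.na(kd)) kd_best <- kd
          }
        }
        trace[stp] <- if (is.finite(kd_best)) kd_best else NA_real_

        dfused <- .mae_grad(fused, lab)
        gbs <- .bn_bwd(fw$bs$cache, dfused, p$bn_s)
        gbt <- .bn_bwd(fw$bt$cache, dfused, p$bn_t)
        ggcn <- .gcn_bwd(fw$gcnc, matrix(gbs$dv, ncol = 1), p$gcn)
        glstm <- .lstm_bwd(fw$lstmc, gbt$dv, p$lstm)
        grads <- list(gcn = ggcn$W,
                      lstm = glstm,
                      bn = list(s = list(gamma = gbs$gamma, beta = gbs$beta),
                                t = list(gamma = gbt$gamma, beta = gbt$beta)))
        upd <- .adam_step(.local_theta(p), grads, st_local, lr = lr)
        st_local <- upd$state
        p <- .set_local_theta(p, upd$params)
        local_iters <- local_iters + 1L
      }
      Fh[mem[real], ti] <- cached[real, 1]
      kd_best_all[ti] <- if (is.finite(kd_best)) kd_best else NA_real_
      kd_trace[[ti]] <- trace
    }
    # global phase: the history matrix is a fixed input here, so the MLP is
    # optimised with `global_steps` full-batch Adam iterations per epoch
    for (git in seq_len(global_steps)) {
      mfw <- .mlp_fwd(Fh, p$mlp)
      Is <- mfw$out
      gl <- mae_loss(Is, ds$labels01)
      if (!is.finite(gl)) stop("non-finite global loss at epoch ", ep, call. = FALSE)
      if (git == 1L) gloss[ep] <- gl
      gmlp <- .mlp_bwd(mfw, .mae_grad(Is, ds$labels01), p$mlp)
      upd <- .adam_step(list(W1 = p$mlp$W1, b1 = p$mlp$b1,
                             W2 = p$mlp$W2, b2 = p$mlp$b2),
                        gmlp, st_global, lr = lr)
      st_global <- upd$state
      p$mlp$W1 <- upd$params$W1; p$mlp$b1 <- upd$params$b1
      p$mlp$W2 <- upd$params$W2; p$mlp$b2 <- upd$params$b2
    }
    mfw <- .mlp_fwd(Fh, p$mlp)
    Is <- mfw$out
    gloss[ep] <- mae_loss(Is, ds$labels01)
    if (verbose) {
      message(sprintf("epoch %d/%d  global MAE %.5f", ep, epochs, gloss[ep]))
    }
  }

  out <- list(params = p, L = Ln, n = n, history = Fh,
              scores = as.numeric(Is),
              labels = as.numeric(labels), labels01 = ds$labels01,
              members = ds$members,
              gloss = gloss, kd_best = kd_best_all, kd_trace = kd_trace,
              lloss_first = lloss_first, lloss_last = lloss_last,
              local_iters = local_iters,
              config = list(epochs = epochs, local_steps = local_steps,
                            global_steps = global_steps, lr = lr, seed = seed,
                            beta = attr(labels, "beta"),
                            reps = attr(labels, "reps")),
              graph = graph, call = cl)
  class(out) <- "spreadrank"
  out
}

#' Score a network with a fitted model
#'
#' Rebuilds the subnetwork dataset of `newdata` at the trained subnetwork
#' size, runs one history-filling pass with frozen weights (evaluation-mode
#' batch normalisation, no gradient) and applies the MLP head to each
#' history row. When `newdata` has a different node count than the training
#' network, the MLP head (whose input width is the training N) cannot be
#' reused; a freshly sized head is then self-calibrated against each node's
#' mean cached local estimate and the result carries attribute
#' `calibrated = TRUE`.
#'
#' @param object A fitted `"spreadrank"` model.
#' @param newdata A network; `NULL` returns the fitted training scores.
#' @param ... Unused.
#' @return A numeric vector of influence scores (higher = more influential).
#' @export
predict.spreadrank <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  graph <- as_network(newdata)
  n2 <- igraph::vcount(graph)
  ds <- build_subnet_dataset(graph, labels = rep(0, n2), L = object$L)
  p <- object$params
  n_train <- object$n
  Fh <- matrix(0, n2, n2)
  for (ti in seq_len(n2)) {
    X <- matrix(ds$features[ti, , ], ds$L, 6)
    S <- gcn_propagation(ds$adjacency[ti, , ])
    mem <- ds$members[ti, ]
    real <- which(!is.na(mem))
    hist_rows <- matrix(0, ds$L, n_train)
    if (length(real) > 0) {
      rows <- Fh[mem[real], , drop = FALSE]
      k <- min(n2, n_train)  # pad/truncate history width to the trained width
      hist_rows[real, seq_len(k)] <- rows[, seq_len(k), drop = FALSE]
    }
    M_in <- cbind(X, hist_rows)
    fw <- .local_forward(X, S, M_in, p, train = FALSE)
    Fh[mem[real], ti] <- fw$fused[real, 1]
  }
  if (n2 == n_train) {
    scores <- mlp_score(Fh, p$mlp)
    attr(scores, "calibrated") <- FALSE
  } else {
    # self-calibration: fit a freshly sized head to each node's mean cached
    # local estimate (its mean nonzero history entry)
    pseudo <- vapply(seq_len(n2), function(v) {
      x <- Fh[v, Fh[v, ] != 0]
      if (length(x) == 0) 0 else mean(x)
    }, 1)
    pseudo <- .minmax01(pseudo)
    set.seed(object$config$seed + 1L)
    mlp <- init_mlp(input_width = n2, hidden = p$mlp$hidden)
    st <- .adam_init(list(W1 = mlp$W1, b1 = mlp$b1, W2 = mlp$W2, b2 = mlp$b2))
    for (it in seq_len(200L)) {
      fwd <- .mlp_fwd(Fh, mlp)
      g <- .mlp_bwd(fwd, .mae_grad(fwd$out, pseudo), mlp)
      upd <- .adam_step(list(W1 = mlp$W1, b1 = mlp$b1, W2 = mlp$W2, b2 = mlp$b2),
                        g, st, lr = object$config$lr)
      st <- upd$state
      mlp$W1 <- upd$params$W1; mlp$b1 <- upd$params$b1
      mlp$W2 <- upd$params$W2; mlp$b2 <- upd$params$b2
    }
    scores <- mlp_score(Fh, mlp)
    attr(scores, "calibrated") <- TRUE
  }
  scores
}

#' @export
print.spreadrank <- function(x, ...) {
  cat("Spatiotemporal node-influence model\n")
  cat(sprintf("  training network: N = %d, L = %d\n", x$n, x$L))
  cat(sprintf("  %d epoch(s), %d local step(s), final global MAE %.5f\n",
              x$config$epochs, x$config$local_steps, x$gloss[length(x$gloss)]))
  invisible(x)
}

#' @export
summary.spreadrank <- function(object, ...) {
  tau <- kendall_tau(object$scores, object$labels)
  out <- list(n = object$n, L = object$L, config = object$config,
              final_gloss = object$gloss[length(object$gloss)],
              train_kendall = tau,
              kd_best = summary(object$kd_best))
  class(out) <- "summary.spreadrank"
  out
}

#' @export
print.summary.spreadrank <- function(x, ...) {
  cat("Spatiotemporal node-influence model\n")
  cat(sprintf("  N = %d, L = %d, epochs = %d, local steps = %d\n",
              x$n, x$L, x$config$epochs, x$config$local_steps))
  cat(sprintf("  final global MAE:        %.5f\n", x$final_gloss))
  cat(sprintf("  training-network Kendall: %.4f\n", x$train_kendall))
  cat("  per-subnetwork best local Kendall:\n")
  print(x$kd_best)
  invisible(x)
}

#' @export
coef.spreadrank <- function(object, ...) object$params

#' @export
residuals.spreadrank <- function(object, ...) {
  object$scores - object$labels01
}

#' @export
plot.spreadrank <- function(x, which = c("loss", "fit"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("loss" %in% which) {
    graphics::plot(seq_along(x$gloss), x$gloss, type = "b", pch = 16,
                   xlab = "epoch", ylab = "global MAE",
                   main = "Training loss", ...)
  }
  if ("fit" %in% which) {
    graphics::plot(x$labels01, x$scores, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.7),
                   xlab = "normalised SIR label", ylab = "model score",
                   main = sprintf("Kendall tau = %.3f",
                                  kendall_tau(x$scores, x$labels)), ...)
  }
  invisible(x)
}

#' @export
simulate.spreadrank <- function(object, nsim = 1, seed = NULL, ...) {
  # outbreak sizes seeded at the model's top-ranked node, at the label beta
  if (!is.null(seed)) set.seed(seed)
  top <- order(-object$scores, seq_len(object$n))[1]
  beta <- object$config$beta
  if (is.null(beta)) beta <- epidemic_threshold(object$graph)
  sir_spread(object$graph, top, beta, reps = nsim)
}

#' Save or load a fitted model
#'
#' Single-file checkpoint with a bit-exact round-trip.
#'
#' @param object A fitted `"spreadrank"` model.
#' @param path File path.
#' @return Invisibly `path` (writer) or the model (reader).
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "spreadrank"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "spreadrank"))
  x
}
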