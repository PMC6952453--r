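# Minimal sequence-network engine: 1-D convolution -> bidirectional LSTM ->
# dropout -> dense head, trained with Adam on MSE or binary cross-entropy.
# Written against base R matrix algebra (BLAS-backed); gradients are exact
# analytic backpropagation, verified by finite differences in the test
# suite.
#
# Batch activations for a sequence layer are stored as an (n*T) x H matrix
# whose rows are ordered sample-fastest: rows (t-1)*n + 1:n hold timestep t.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(n_in, n_out, gain = 1) {
  limit <- gain * sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -limit, limit), n_in, n_out)
}

.init_lstm_dir <- function(n_in, units) {
  b <- numeric(4L * units)
  b[(units + 1L):(2L * units)] <- 1  # forget-gate bias starts open
  list(Wx = .glorot(n_in, 4L * units), Wh = .glorot(units, 4L * units), b = b)
}

#' Architecture description for the sequence networks
#'
#' All three predictors share one hybrid architecture: a 1-D convolution
#' (64 filters) scanning adjacent residues of the one-hot sequence matrix, a
#' 128-unit bidirectional LSTM, dropout 0.5, and a dense head. The fragment
#' intensity model uses kernel size 2 (so the 50-residue input maps onto the
#' 49 cleavage sites) and a position-wise 12-unit ReLU head; the iRT model
#' uses kernel size 5 with a scalar linear head on the final LSTM states;
#' the detectability model is the iRT variant on the 22 x 66 flanked
#' encoding with a sigmoid head.
#'
#' @param input_width Sequence positions (50 for peptides, 66 flanked).
#' @param input_channels Alphabet size (20, or 22 flanked).
#' @param conv_filters,conv_kernel Convolution filters and kernel size.
#' @param lstm_units Units per LSTM direction.
#' @param dropout_rate Dropout rate applied after the BiLSTM.
#' @param head `"sequence_relu"` (position-wise 12-dim ReLU, fragment
#'   matrix), `"scalar_linear"` (iRT) or `"scalar_sigmoid"` (detectability).
#' @param head_units Output units of the dense head.
#' @return An object of class `nn_spec`.
#' @export
nn_spec <- function(input_width, input_channels, conv_filters = 64L,
                    conv_kernel = 2L, lstm_units = 128L, dropout_rate = 0.5,
                    head = c("sequence_relu", "scalar_linear", "scalar_sigmoid"),
                    head_units = 12L) {
  head <- match.arg(head)
  if (head != "sequence_relu") head_units <- 1L
  structure(list(input_width = as.integer(input_width),
                 input_channels = as.integer(input_channels),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 lstm_units = as.integer(lstm_units),
                 dropout_rate = dropout_rate,
                 head = head, head_units = as.integer(head_units),
                 conv_width = as.integer(input_width - conv_kernel + 1L)),
            class = "nn_spec")
}

#' Initialize network weights
#'
#' Glorot-uniform weights (seeded), zero biases except the LSTM forget gate
#' (initialized to 1).
#'
#' @param spec An [nn_spec()].
#' @param seed Integer seed for the initializer.
#' @return List of parameter arrays (class `nn_params`).
#' @export
nn_init <- function(spec, seed = 1L) {
  set.seed(seed)
  u <- spec$lstm_units
  params <- list(
    conv = list(W = .glorot(spec$conv_kernel * spec$input_channels,
                            spec$conv_filters),
                b = numeric(spec$conv_filters)),
    fwd = .init_lstm_dir(spec$conv_filters, u),
    bwd = .init_lstm_dir(spec$conv_filters, u),
    dense = list(W = .glorot(2L * u, spec$head_units),
                 b = numeric(spec$head_units))
  )
  structure(params, class = "nn_params", seed = seed)
}

# --- convolution ------------------------------------------------------------

# X: array (n, T, D). Returns list(out = (n*T2) x F matrix, xc = im2col).
.conv_forward <- function(X, conv, kernel) {
  n <- dim(X)[1L]; T_in <- dim(X)[2L]; D <- dim(X)[3L]
  T2 <- T_in - kernel + 1L
  xc <- matrix(0, n * T2, kernel * D)
  for (o in seq_len(kernel)) {
    xc[, ((o - 1L) * D + 1L):(o * D)] <-
      matrix(X[, o:(o + T2 - 1L), , drop = FALSE], n * T2, D)
  }
  out <- xc %*% conv$W
  out <- sweep(out, 2L, conv$b, "+")
  list(out = out, xc = xc, n = n, T2 = T2)
}

.conv_backward <- function(cache, conv, d_out) {
  list(dW = crossprod(cache$xc, d_out), db = colSums(d_out))
}

# --- LSTM -------------------------------------------------------------------

# M: (n*T) x F input; runs one direction over timesteps `order`.
# Returns hidden states per timestep ((n*T) x H, aligned to absolute t) and
# the final state, plus caches for backprop.
.lstm_forward <- function(M, par, n, T_steps, reverse = FALSE) {
  u <- nrow(par$Wh)  # units per direction
  ord <- if (reverse) rev(seq_len(T_steps)) else seq_len(T_steps)
  h <- matrix(0, n, u); cc <- matrix(0, n, u)
  Hs <- matrix(0, n * T_steps, u)
  cache <- vector("list", T_steps)
  # input contribution to all gates, all timesteps, in one product
  Xp <- M %*% par$Wx
  Xp <- sweep(Xp, 2L, par$b, "+")
  for (s in seq_len(T_steps)) {
    t <- ord[s]
    rows <- (t - 1L) * n + seq_len(n)
    z <- Xp[rows, , drop = FALSE] + h %*% par$Wh
    gi <- .sigmoid(z[, seq_len(u), drop = FALSE])
    gf <- .sigmoid(z[, u + seq_len(u), drop = FALSE])
    gg <- tanh(z[, 2L * u + seq_len(u), drop = FALSE])
    go <- .sigmoid(z[, 3L * u + seq_len(u), drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    Hs[rows, ] <- h
    cache[[s]] <- list(rows = rows, gi = gi, gf = gf, gg = gg, go = go,
                       tc = tc, c_prev = c_prev, h_prev = h_prev)
  }
  list(Hs = Hs, h_last = h, cache = cache, ord = ord, u = u)
}

# dHs: (n*T) x H gradient on per-timestep outputs (zero matrix allowed);
# dh_last: gradient on the final hidden state (or NULL).
.lstm_backward <- function(M, par, fw, dHs, dh_last = NULL) {
  u <- fw$u
  n <- nrow(fw$cache[[1L]]$gi)
  T_steps <- length(fw$cache)
  dWh <- array(0, dim(par$Wh))
  DZ <- matrix(0, nrow(M), 4L * u)  # gate gradients, all timesteps
  dh_next <- if (is.null(dh_last)) matrix(0, n, u) else dh_last
  dc_next <- matrix(0, n, u)
  for (s in rev(seq_len(T_steps))) {
    cc <- fw$cache[[s]]
    dh <- dHs[cc$rows, , drop = FALSE] + dh_next
    d_go <- dh * cc$tc
    dc <- dh * cc$go * (1 - cc$tc^2) + dc_next
    dz <- cbind(dc * cc$gg * cc$gi * (1 - cc$gi),
                dc * cc$c_prev * cc$gf * (1 - cc$gf),
                dc * cc$gi * (1 - cc$gg^2),
                d_go * cc$go * (1 - cc$go))
    DZ[cc$rows, ] <- dz
    dWh <- dWh + crossprod(cc$h_prev, dz)
    dh_next <- tcrossprod(dz, par$Wh)
    dc_next <- dc * cc$gf
  }
  list(dWx = crossprod(M, DZ), dWh = dWh, db = colSums(DZ),
       dM = tcrossprod(DZ, par$Wx))
}

# --- full network -----------------------------------------------------------

# Forward pass. X: (n, T, D) array. Returns prediction and caches.
# training=TRUE applies inverted dropout with the current RNG.
nn_forward <- function(spec, params, X, training = FALSE) {
  n <- dim(X)[1L]
  cv <- .conv_forward(X, params$conv, spec$conv_kernel)
  T2 <- cv$T2
  fwd <- .lstm_forward(cv$out, params$fwd, n, T2, reverse = FALSE)
  bwd <- .lstm_forward(cv$out, params$bwd, n, T2, reverse = TRUE)
  if (spec$head == "sequence_relu") {
    A <- cbind(fwd$Hs, bwd$Hs)              # (n*T2) x 2u
  } else {
    A <- cbind(fwd$h_last, bwd$h_last)      # n x 2u
  }
  mask <- NULL
  if (training && spec$dropout_rate > 0) {
    keep <- 1 - spec$dropout_rate
    mask <- matrix(rbinom(length(A), 1L, keep) / keep, nrow(A), ncol(A))
    A_drop <- A * mask
  } else A_drop <- A
  Z <- sweep(A_drop %*% params$dense$W, 2L, params$dense$b, "+")
  pred <- switch(spec$head,
                 sequence_relu = pmax(Z, 0),
                 scalar_linear = Z,
                 scalar_sigmoid = .sigmoid(Z))
  list(pred = pred, n = n, T2 = T2, cv = cv, fwd = fwd, bwd = bwd,
       A = A, A_drop = A_drop, mask = mask, Z = Z)
}

# Backward pass from d_pred (gradient of the loss w.r.t. the prediction,
# pre-activation handling done here). Returns gradients in params layout.
nn_backward <- function(spec, params, fw, d_pred) {
  u <- spec$lstm_units
  dZ <- switch(spec$head,
               sequence_relu = d_pred * (fw$Z > 0),
               scalar_linear = d_pred,
               scalar_sigmoid = d_pred * fw$pred * (1 - fw$pred))
  dW_dense <- crossprod(fw$A_drop, dZ)
  db_dense <- colSums(dZ)
  dA <- dZ %*% t(params$dense$W)
  if (!is.null(fw$mask)) dA <- dA * fw$mask
  dHs_f <- dA[, seq_len(u), drop = FALSE]
  dHs_b <- dA[, u + seq_len(u), drop = FALSE]
  if (spec$head == "sequence_relu") {
    g_f <- .lstm_backward(fw$cv$out, params$fwd, fw$fwd, dHs_f)
    g_b <- .lstm_backward(fw$cv$out, params$bwd, fw$bwd, dHs_b)
  } else {
    zero <- matrix(0, fw$n * fw$T2, u)
    g_f <- .lstm_backward(fw$cv$out, params$fwd, fw$fwd, zero, dh_last = dHs_f)
    g_b <- .lstm_backward(fw$cv$out, params$bwd, fw$bwd, zero, dh_last = dHs_b)
  }
  d_conv_out <- g_f$dM + g_b$dM
  g_c <- .conv_backward(fw$cv, params$conv, d_conv_out)
  list(conv = list(W = g_c$dW, b = g_c$db),
       fwd = list(Wx = g_f$dWx, Wh = g_f$dWh, b = g_f$db),
       bwd = list(Wx = g_b$dWx, Wh = g_b$dWh, b = g_b$db),
       dense = list(W = dW_dense, b = db_dense))
}

# --- losses -----------------------------------------------------------------

# Each returns list(loss, d_pred) where d_pred matches the prediction shape.
# `weight` (optional, same shape) restricts the loss to selected cells.
.loss_mse <- function(pred, target, weight = NULL) {
  d <- pred - target
  if (is.null(weight)) return(list(loss = mean(d^2), d_pred = 2 * d / length(d)))
  w_sum <- sum(weight)
  list(loss = sum(weight * d^2) / w_sum, d_pred = 2 * weight * d / w_sum)
}

.loss_bce <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
  list(loss = loss, d_pred = (p - target) / (p * (1 - p)) / length(p))
}

# --- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else array(0, dim = dim(x) %||% length(x))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(walk, p, g, m, v)
      list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  res <- Map(walk, params, grads, state$m, state$v)
  new_params <- lapply(res, `[[`, "p")
  attributes(new_params) <- attributes(params)
  state$m <- lapply(res, `[[`, "m")
  state$v <- lapply(res, `[[`, "v")
  list(params = new_params, state = state)
}

# --- training loop ----------------------------------------------------------

# X: (n, T, D); Y: matrix of targets aligned to the head layout
# (sequence head: (n*T2) x 12 sample-fastest; scalar heads: n x 1).
# Returns list(params, history, best_epoch).
nn_train <- function(spec, params, X, Y, X_val = NULL, Y_val = NULL,
                     epochs = 100L, batch_size = 64L, lr = 1e-3,
                     patience = 10L, seed = 1L, loss = c("mse", "bce"),
                     weight = NULL, weight_val = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  loss_fn <- if (loss == "mse") .loss_mse else function(p, t, w = NULL) .loss_bce(p, t)
  n <- dim(X)[1L]
  state <- .adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  seq_head <- spec$head == "sequence_relu"
  set.seed(seed)
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    epoch_loss <- 0
    for (st in starts) {
      idx <- perm[st:min(st + batch_size - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      Yb <- .slice_targets(Y, idx, n, seq_head, spec$conv_width)
      Wb <- if (is.null(weight)) NULL else
        .slice_targets(weight, idx, n, seq_head, spec$conv_width)
      fw <- nn_forward(spec, params, Xb, training = TRUE)
      lo <- loss_fn(fw$pred, Yb, Wb)
      grads <- nn_backward(spec, params, fw, lo$d_pred)
      upd <- .adam_step(params, grads, state, lr = lr)
      params <- upd$params; state <- upd$state
      epoch_loss <- epoch_loss + lo$loss * length(idx)
    }
    epoch_loss <- epoch_loss / n
    val_loss <- NA_real_
    if (!is.null(X_val)) {
      val_pred <- nn_predict(spec, params, X_val)
      val_loss <- loss_fn(val_pred, Y_val, weight_val)$loss
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_loss = val_loss))
    monitor <- if (is.na(val_loss)) epoch_loss else val_loss
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= patience) {
      if (verbose) message("early stopping at epoch ", epoch)
      break
    }
    if (verbose) message(sprintf("epoch %d  train %.5f  val %.5f",
                                 epoch, epoch_loss, val_loss))
  }
  list(params = best$params, history = history, best_epoch = best$epoch)
}

# Extract target rows for a batch, honoring the sample-fastest layout of
# sequence targets.
.slice_targets <- function(Y, idx, n, seq_head, T2) {
  if (!seq_head) return(Y[idx, , drop = FALSE])
  rows <- as.vector(outer(idx, (seq_len(T2) - 1L) * n, "+"))
  # reorder to batch-local sample-fastest layout
  Y[rows, , drop = FALSE]
}

# Prediction in manageable chunks; dropout disabled.
nn_predict <- function(spec, params, X, chunk = 256L) {
  n <- dim(X)[1L]
  out <- NULL
  for (st in seq(1L, n, by = chunk)) {
    idx <- st:min(st + chunk - 1L, n)
    fw <- nn_forward(spec, params, X[idx, , , drop = FALSE], training = FALSE)
    if (spec$head == "sequence_relu") {
      # reassemble into global sample-fastest layout at the end
      out <- c(out, list(list(idx = idx, pred = fw$pred)))
    } else {
      out <- c(out, list(list(idx = idx, pred = fw$pred)))
    }
  }
  if (spec$head == "sequence_relu") {
    T2 <- spec$conv_width
    full <- matrix(0, n * T2, spec$head_units)
    for (part in out) {
      nb <- length(part$idx)
      rows <- as.vector(outer(part$idx, (seq_len(T2) - 1L) * n, "+"))
      full[rows, ] <- part$pred
    }
    full
  } else {
    full <- matrix(0, n, spec$head_units)
    for (part in out) full[part$idx, ] <- part$pred
    full
  }
}

# Convert one sequence-head prediction block back to a 12 x T2 fragment
# matrix for sample i of n.
.seq_pred_to_matrix <- function(pred, i, n, T2) {
  rows <- (seq_len(T2) - 1L) * n + i
  t(pred[rows, , drop = FALSE])
}
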