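# Bidirectional LSTM sequence labeller, implemented directly in base R
# matrix code. One recurrent layer (H units per direction) over the
# max_len x 27 masked bin sequence, followed by a per-bin dense sigmoid.
# Trained with masked, class-weighted binary cross entropy and Adam;
# gradients are exact backpropagation-through-time and are validated against
# finite differences in the test suite.
#
# Masking semantics: padded timesteps carry their hidden/cell state through
# unchanged in both directions and contribute nothing to the loss, so padded
# tails cannot influence predictions at real bins.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Gate order in the stacked 4H dimension: input, forget, cell, output.
bilstm_init <- function(input_dim, hidden, seed = 1) {
  with_seed(seed, {
    dir_init <- function() {
      b <- numeric(4 * hidden)
      b[(hidden + 1):(2 * hidden)] <- 1        # forget-gate bias 1
      list(Wx = glorot(input_dim, 4 * hidden),
           Wh = glorot(hidden, 4 * hidden), b = b)
    }
    list(fwd = dir_init(), bwd = dir_init(),
         Wy = glorot(2 * hidden, 1), by = 0,
         hidden = hidden, input_dim = input_dim)
  })
}

# Forward pass of one direction. X: N x T x D array; mask: N x T (1 real /
# 0 padded). Returns hidden states (list of T N x H matrices at original
# time positions) plus caches for backprop.
lstm_dir_forward <- function(p, X, mask, hidden, reverse = FALSE,
                             keep_cache = TRUE) {
  N <- dim(X)[1]; Tn <- dim(X)[2]
  H <- hidden
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  Hs <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  order_t <- if (reverse) Tn:1 else seq_len(Tn)
  for (t in order_t) {
    x <- matrix(X[, t, ], nrow = N)
    m <- mask[, t]
    z <- x %*% p$Wx + h %*% p$Wh + matrix(p$b, N, 4 * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    h_next <- m * h_new + (1 - m) * h      # carry state through padding
    c_next <- m * c_new + (1 - m) * cc
    if (keep_cache)
      cache[[t]] <- list(x = x, m = m, i = i, f = f, g = g, o = o,
                         c_prev = cc, h_prev = h, c_new = c_new, tc = tc)
    h <- h_next; cc <- c_next
    Hs[[t]] <- h
  }
  list(Hs = Hs, cache = cache)
}

# Backprop of one direction given dHs (list of T N x H gradients w.r.t. the
# direction's emitted hidden state at each time position).
lstm_dir_backward <- function(p, dHs, cache, hidden, reverse = FALSE) {
  Tn <- length(dHs)
  N <- nrow(dHs[[1]]); H <- hidden
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh_carry <- matrix(0, N, H); dc_carry <- matrix(0, N, H)
  order_t <- if (reverse) seq_len(Tn) else Tn:1   # reverse of forward order
  for (t in order_t) {
    ca <- cache[[t]]
    m <- ca$m
    dh_total <- dHs[[t]] + dh_carry
    dc_total <- dc_carry
    # split through the masked carry: masked entries route to h_new/c_new,
    # unmasked route straight to h_prev/c_prev
    dh_new <- m * dh_total
    dc_new <- m * dc_total
    dh_prev_carry <- (1 - m) * dh_total
    dc_prev_carry <- (1 - m) * dc_total
    do <- dh_new * ca$tc
    dc_new <- dc_new + dh_new * ca$o * (1 - ca$tc^2)
    di <- dc_new * ca$g
    df <- dc_new * ca$c_prev
    dg <- dc_new * ca$i
    dc_prev <- dc_new * ca$f + dc_prev_carry
    dz <- cbind(di * ca$i * (1 - ca$i), df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2), do * ca$o * (1 - ca$o))
    dWx <- dWx + crossprod(ca$x, dz)
    dWh <- dWh + crossprod(ca$h_prev, dz)
    db <- db + colSums(dz)
    dh_prev <- dz %*% t(p$Wh) + dh_prev_carry
    dh_carry <- dh_prev
    dc_carry <- dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# Full forward pass: per-bin probabilities. Returns caches when training.
bilstm_forward <- function(params, X, mask, keep_cache = FALSE) {
  N <- dim(X)[1]; Tn <- dim(X)[2]; H <- params$hidden
  fw <- lstm_dir_forward(params$fwd, X, mask, H, reverse = FALSE,
                         keep_cache = keep_cache)
  bw <- lstm_dir_forward(params$bwd, X, mask, H, reverse = TRUE,
                         keep_cache = keep_cache)
  prob <- matrix(0, N, Tn)
  logits <- matrix(0, N, Tn)
  for (t in seq_len(Tn)) {
    hcat <- cbind(fw$Hs[[t]], bw$Hs[[t]])
    lg <- hcat %*% params$Wy + params$by
    logits[, t] <- lg
    prob[, t] <- sigmoid(lg)
  }
  list(prob = prob, logits = logits, fw = fw, bw = bw)
}

# Masked (optionally class-weighted) mean binary cross entropy.
bce_loss <- function(prob, Y, mask, class_weights = c(`0` = 1, `1` = 1)) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  w <- ifelse(Y == 1, class_weights[["1"]], class_weights[["0"]])
  ll <- -(Y * log(p) + (1 - Y) * log(1 - p)) * w * mask
  sum(ll) / sum(mask)
}

# Loss and full gradient for one batch.
bilstm_grad <- function(params, X, Y, mask, class_weights = c(`0` = 1, `1` = 1)) {
  N <- dim(X)[1]; Tn <- dim(X)[2]; H <- params$hidden
  fwd <- bilstm_forward(params, X, mask, keep_cache = TRUE)
  prob <- fwd$prob
  M <- sum(mask)
  w <- ifelse(Y == 1, class_weights[["1"]], class_weights[["0"]])
  dlogit <- (prob - Y) * w * mask / M        # exact BCE-through-sigmoid
  dWy <- params$Wy * 0; dby <- 0
  dHf <- vector("list", Tn); dHb <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    hcat <- cbind(fwd$fw$Hs[[t]], fwd$bw$Hs[[t]])
    dl <- dlogit[, t, drop = FALSE]
    dWy <- dWy + crossprod(hcat, dl)
    dby <- dby + sum(dl)
    dh <- dl %*% t(params$Wy)
    dHf[[t]] <- dh[, 1:H, drop = FALSE]
    dHb[[t]] <- dh[, (H + 1):(2 * H), drop = FALSE]
  }
  gf <- lstm_dir_backward(params$fwd, dHf, fwd$fw$cache, H, reverse = FALSE)
  gb <- lstm_dir_backward(params$bwd, dHb, fwd$bw$cache, H, reverse = TRUE)
  list(loss = bce_loss(prob, Y, mask, class_weights),
       grads = list(fwd = gf, bwd = gb, Wy = dWy, by = dby), prob = prob)
}

## ---- Adam -------------------------------------------------------------

flatten_params <- function(p) {
  list(fwd.Wx = p$fwd$Wx, fwd.Wh = p$fwd$Wh, fwd.b = p$fwd$b,
       bwd.Wx = p$bwd$Wx, bwd.Wh = p$bwd$Wh, bwd.b = p$bwd$b,
       Wy = p$Wy, by = p$by)
}

unflatten_into <- function(p, flat) {
  p$fwd$Wx <- flat$fwd.Wx; p$fwd$Wh <- flat$fwd.Wh; p$fwd$b <- flat$fwd.b
  p$bwd$Wx <- flat$bwd.Wx; p$bwd$Wh <- flat$bwd.Wh; p$bwd$b <- flat$bwd.b
  p$Wy <- flat$Wy; p$by <- flat$by
  p
}

adam_init <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(x) x * 0), v = lapply(fl, function(x) x * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1
  fl <- flatten_params(params)
  gl <- flatten_params(grads)
  for (k in names(fl)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gl[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gl[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    fl[[k]] <- fl[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = unflatten_into(params, fl), state = state)
}

## ---- training loop ----------------------------------------------------

# X*, Y*, M*: N x T x D feature array, N x T labels (0/1; padded entries 0),
# N x T mask. Returns the minimum-validation-loss weights and a history
# table (epoch, loss, val_loss, P/R on train and validation at 0.5).
train_bilstm <- function(Xtr, Ytr, Mtr, Xval, Yval, Mval, hidden = 20,
                         epochs = 25, batch_size = 32, lr = 0.02,
                         class_weights = c(`0` = 1, `1` = 1), seed = 1) {
  N <- dim(Xtr)[1]
  params <- bilstm_init(dim(Xtr)[3], hidden, seed = seed)
  state <- adam_init(params)
  best <- list(val_loss = Inf, params = params, epoch = 0)
  history <- data.frame()
  with_seed(seed + 1, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      tr_loss <- 0; nb <- 0
      for (b0 in seq(1, N, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, N)]
        g <- bilstm_grad(params,
                         Xtr[idx, , , drop = FALSE],
                         Ytr[idx, , drop = FALSE],
                         Mtr[idx, , drop = FALSE], class_weights)
        st <- adam_step(params, g$grads, state, lr = lr)
        params <- st$params; state <- st$state
        tr_loss <- tr_loss + g$loss; nb <- nb + 1
      }
      trf <- bilstm_forward(params, Xtr, Mtr)
      vaf <- bilstm_forward(params, Xval, Mval)
      val_loss <- bce_loss(vaf$prob, Yval, Mval)   # unweighted, as monitored
      pr_tr <- prf(confusion(as.integer(trf$prob >= 0.5), Ytr, Mtr))
      pr_va <- prf(confusion(as.integer(vaf$prob >= 0.5), Yval, Mval))
      history <- rbind(history, data.frame(
        epoch = ep, loss = tr_loss / nb, val_loss = val_loss,
        P_train = pr_tr[["P"]], R_train = pr_tr[["R"]],
        P_val = pr_va[["P"]], R_val = pr_va[["R"]]))
      if (val_loss < best$val_loss)
        best <- list(val_loss = val_loss, params = params, epoch = ep)
      apa_log("epoch %d loss %.4f val_loss %.4f", ep, tr_loss / nb, val_loss)
    }
  })
  list(params = best$params, best_epoch = best$epoch,
       val_loss = best$val_loss, history = history)
}
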