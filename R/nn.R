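# Matrix-based neural-network engine: forward and backward passes for the
# six classifier architectures, plus the RMSprop update.
#
# Conventions:
#   * fixed-input models (lr, mlp, cnn) consume a [batch x length] matrix;
#   * recurrent models (rnn, lstm, tb_lstm) consume a [batch x steps x dim]
#     array with a [batch x steps] mask, sequences left-padded so the final
#     hidden state is the state after each sequence's last real step; on
#     masked steps the recurrent state is carried through unchanged;
#   * every architecture ends in a single sigmoid output unit, and dropout
#     (inverted, training only) is applied to the feature vector feeding it
#     (the input itself for lr, whose only layer is the output).
# Backward passes are exact analytic gradients of the mean binary
# cross-entropy; they are verified against finite differences in the tests.

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) z * (z > 0)

# Fan-in-scaled normal initialisation.
init_mat <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(fan_in)), nr, nc)
}

nn_init <- function(spec) {
  arch <- spec$architecture
  L <- spec$input_length
  H <- spec$hidden_size
  switch(arch,
    lr = list(W = init_mat(L, 1L), b = 0),
    mlp = if (H == 0L) list(W = init_mat(L, 1L), b = 0) else
      list(W1 = init_mat(L, H), b1 = numeric(H),
           W2 = init_mat(H, 1L), b2 = 0),
    cnn = {
      fl <- spec$filter_length; nf <- spec$conv_filters
      q <- (L - fl + 1L) %/% spec$pool_length
      list(Wc = init_mat(fl, nf), bc = numeric(nf),
           W = init_mat(q * nf, 1L), b = 0)
    },
    rnn = {
      D <- spec$input_dim
      list(Wx = init_mat(D, H, fan_in = D + H),
           Wh = init_mat(H, H, fan_in = D + H), bh = numeric(H),
           W = init_mat(H, 1L), b = 0)
    },
    lstm = ,
    tb_lstm = {
      D <- spec$input_dim
      bg <- numeric(4L * H)
      bg[(H + 1L):(2L * H)] <- 1  # forget-gate bias opens the memory path
      list(Wg = init_mat(D + H, 4L * H), bg = bg,
           W = init_mat(H, 1L), b = 0)
    },
    stop("unknown architecture: ", arch))
}

nn_n_params <- function(params) sum(vapply(params, length, integer(1)))

# Inverted-dropout mask (1/keep on kept units); NULL means no dropout.
make_dropout_mask <- function(dim_, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  array((stats::runif(prod(dim_)) < keep) / keep, dim_)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# ---- forward passes ---------------------------------------------------------
# Each returns list(z = logits [B], cache) with cache sufficient for backward.

forward_linear <- function(params, x, drop_mask) {
  xd <- apply_mask(x, drop_mask)
  z <- xd %*% params$W + params$b
  list(z = as.vector(z), cache = list(xd = xd, drop = drop_mask))
}

forward_mlp <- function(params, x, drop_mask) {
  a1 <- sweep(x %*% params$W1, 2L, params$b1, `+`)
  h1 <- relu(a1)
  hd <- apply_mask(h1, drop_mask)
  z <- hd %*% params$W2 + params$b2
  list(z = as.vector(z),
       cache = list(x = x, a1 = a1, hd = hd, drop = drop_mask))
}

forward_cnn <- function(params, x, spec, drop_mask) {
  B <- nrow(x); L <- ncol(x)
  fl <- spec$filter_length; nf <- spec$conv_filters; pl <- spec$pool_length
  P <- L - fl + 1L
  Q <- P %/% pl
  Z <- matrix(0, B * P, fl)
  for (k in seq_len(fl)) Z[, k] <- as.vector(x[, k:(k + P - 1L), drop = FALSE])
  A <- sweep(Z %*% params$Wc, 2L, params$bc, `+`)
  C <- relu(A)
  Carr <- array(C, c(B, P, nf))
  cols1 <- seq(1L, by = pl, length.out = Q)
  pool <- Carr[, cols1, , drop = FALSE]
  argj <- array(1L, c(B, Q, nf))
  for (j in 2:pl) {
    cand <- Carr[, seq(j, by = pl, length.out = Q), , drop = FALSE]
    upd <- cand > pool
    pool[upd] <- cand[upd]
    argj[upd] <- j
  }
  flat <- matrix(pool, B, Q * nf)
  fd <- apply_mask(flat, drop_mask)
  z <- fd %*% params$W + params$b
  list(z = as.vector(z),
       cache = list(Z = Z, A = A, argj = argj, fd = fd, drop = drop_mask,
                    B = B, L = L, P = P, Q = Q))
}

forward_rnn <- function(params, x, mask, drop_mask, need_cache = TRUE) {
  B <- dim(x)[1]; Tn <- dim(x)[2]; D <- dim(x)[3]
  H <- ncol(params$Wh)
  # project all inputs at once; rows of xp are grouped per step, B at a time
  xp <- matrix(x, B * Tn, D) %*% params$Wx
  xp <- xp + rep(params$bh, each = nrow(xp))  # bias folded in once per batch
  h <- matrix(0, B, H)
  hs <- if (need_cache) vector("list", Tn)
  as <- if (need_cache) vector("list", Tn)
  brow <- seq_len(B)
  for (t in seq_len(Tn)) {
    a <- xp[(t - 1L) * B + brow, , drop = FALSE] + h %*% params$Wh
    hn <- tanh(a)
    m <- mask[, t]
    hnew <- hn * m + h * (1 - m)
    if (need_cache) { as[[t]] <- a; hs[[t]] <- hnew }
    h <- hnew
  }
  hd <- apply_mask(h, drop_mask)
  z <- hd %*% params$W + params$b
  list(z = as.vector(z),
       cache = list(x = x, mask = mask, hs = hs, as = as, hd = hd,
                    drop = drop_mask, B = B, Tn = Tn, D = D, H = H))
}

forward_lstm <- function(params, x, mask, drop_mask, need_cache = TRUE) {
  B <- dim(x)[1]; Tn <- dim(x)[2]; D <- dim(x)[3]
  H <- nrow(params$W)
  Wg_h <- params$Wg[(D + 1L):(D + H), , drop = FALSE]
  xp <- matrix(x, B * Tn, D) %*% params$Wg[seq_len(D), , drop = FALSE]
  xp <- xp + rep(params$bg, each = nrow(xp))  # bias folded in once per batch
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  idx <- function(k) ((k - 1L) * H + 1L):(k * H)
  cache <- if (need_cache) vector("list", Tn)
  brow <- seq_len(B)
  for (t in seq_len(Tn)) {
    a <- xp[(t - 1L) * B + brow, , drop = FALSE] + h %*% Wg_h
    gi <- sigmoid(a[, idx(1L), drop = FALSE])
    gf <- sigmoid(a[, idx(2L), drop = FALSE])
    go <- sigmoid(a[, idx(3L), drop = FALSE])
    gg <- tanh(a[, idx(4L), drop = FALSE])
    c_inner <- gf * cc + gi * gg
    tc <- tanh(c_inner)
    h_inner <- go * tc
    m <- mask[, t]
    if (need_cache) {
      cache[[t]] <- list(hprev = h, cprev = cc, gi = gi, gf = gf,
                         go = go, gg = gg, tc = tc, m = m)
    }
    cc <- c_inner * m + cc * (1 - m)
    h <- h_inner * m + h * (1 - m)
  }
  hd <- apply_mask(h, drop_mask)
  z <- hd %*% params$W + params$b
  list(z = as.vector(z),
       cache = list(x = x, steps = cache, hd = hd, drop = drop_mask,
                    B = B, Tn = Tn, D = D, H = H))
}

# ---- backward passes --------------------------------------------------------
# dz is dLoss/dlogit, a length-B vector. Each returns grads shaped like params.

backward_linear <- function(params, cache, dz) {
  list(W = crossprod(cache$xd, dz), b = sum(dz))
}

backward_mlp <- function(params, cache, dz) {
  dhd <- outer(dz, as.vector(params$W2))   # B x H
  dhd <- apply_mask(dhd, cache$drop)
  da1 <- dhd * (cache$a1 > 0)
  list(W1 = crossprod(cache$x, da1), b1 = colSums(da1),
       W2 = crossprod(cache$hd, dz), b2 = sum(dz))
}

backward_cnn <- function(params, cache, dz, spec) {
  B <- cache$B; L <- cache$L; P <- cache$P; Q <- cache$Q
  fl <- spec$filter_length; nf <- spec$conv_filters; pl <- spec$pool_length
  dW <- crossprod(cache$fd, dz)
  dflat <- outer(dz, as.vector(params$W))  # B x Q*nf
  dflat <- apply_mask(dflat, cache$drop)
  dpool <- array(dflat, c(B, Q, nf))
  dCarr <- array(0, c(B, P, nf))
  for (j in seq_len(pl)) {
    sel <- cache$argj == j
    tmp <- array(0, c(B, Q, nf))
    tmp[sel] <- dpool[sel]
    dCarr[, seq(j, by = pl, length.out = Q), ] <- tmp
  }
  dA <- matrix(dCarr, B * P, nf) * (cache$A > 0)
  dZ <- tcrossprod(dA, params$Wc)          # B*P x fl (unused for dX here:
  # the input is data, not a parameter, so dX is not propagated further)
  list(Wc = crossprod(cache$Z, dA), bc = colSums(dA), W = dW, b = sum(dz))
}

backward_rnn <- function(params, cache, dz) {
  B <- cache$B; Tn <- cache$Tn; D <- cache$D; H <- cache$H
  dhd <- outer(dz, as.vector(params$W))
  dW <- crossprod(cache$hd, dz)
  dh <- apply_mask(dhd, cache$drop)
  da_all <- matrix(0, B * Tn, H)
  hprev_all <- matrix(0, B * Tn, H)
  brow <- seq_len(B)
  for (t in rev(seq_len(Tn))) {
    m <- cache$mask[, t]
    hn <- tanh(cache$as[[t]])
    da <- (dh * m) * (1 - hn^2)
    rows <- (t - 1L) * B + brow
    da_all[rows, ] <- da
    if (t > 1L) hprev_all[rows, ] <- cache$hs[[t - 1L]]
    dh <- tcrossprod(da, params$Wh) + dh * (1 - m)
  }
  list(Wx = crossprod(matrix(cache$x, B * Tn, D), da_all),
       Wh = crossprod(hprev_all, da_all),
       bh = colSums(da_all), W = dW, b = sum(dz))
}

backward_lstm <- function(params, cache, dz) {
  B <- cache$B; Tn <- cache$Tn; D <- cache$D; H <- cache$H
  Wg_h <- params$Wg[(D + 1L):(D + H), , drop = FALSE]
  dhd <- outer(dz, as.vector(params$W))
  dW <- crossprod(cache$hd, dz)
  dh <- apply_mask(dhd, cache$drop)
  dc <- matrix(0, B, H)
  da_all <- matrix(0, B * Tn, 4L * H)
  hprev_all <- matrix(0, B * Tn, H)
  brow <- seq_len(B)
  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    m <- st$m
    dh_inner <- dh * m
    dc_inner <- dc * m
    dgo <- dh_inner * st$tc
    dci <- dc_inner + (dh_inner * st$go) * (1 - st$tc^2)
    dgf <- dci * st$cprev
    dgi <- dci * st$gg
    dgg <- dci * st$gi
    dc <- dci * st$gf + dc * (1 - m)
    da <- cbind(dgi * st$gi * (1 - st$gi),
                dgf * st$gf * (1 - st$gf),
                dgo * st$go * (1 - st$go),
                dgg * (1 - st$gg^2))
    rows <- (t - 1L) * B + brow
    da_all[rows, ] <- da
    hprev_all[rows, ] <- st$hprev
    dh <- tcrossprod(da, Wg_h) + dh * (1 - m)
  }
  dWg <- rbind(crossprod(matrix(cache$x, B * Tn, D), da_all),
               crossprod(hprev_all, da_all))
  list(Wg = dWg, bg = colSums(da_all), W = dW, b = sum(dz))
}

# ---- generic entry points ---------------------------------------------------

is_recurrent <- function(arch) arch %in% c("rnn", "lstm", "tb_lstm")

effective_arch <- function(spec) {
  if (spec$architecture == "mlp" && spec$hidden_size == 0L) "lr" else spec$architecture
}

nn_forward <- function(spec, params, batch, drop_mask = NULL, need_cache = TRUE) {
  switch(effective_arch(spec),
    lr = forward_linear(params, batch$x, drop_mask),
    mlp = forward_mlp(params, batch$x, drop_mask),
    cnn = forward_cnn(params, batch$x, spec, drop_mask),
    rnn = forward_rnn(params, batch$x, batch$mask, drop_mask, need_cache),
    lstm = ,
    tb_lstm = forward_lstm(params, batch$x, batch$mask, drop_mask, need_cache))
}

nn_backward <- function(spec, params, cache, dz) {
  switch(effective_arch(spec),
    lr = backward_linear(params, cache, dz),
    mlp = backward_mlp(params, cache, dz),
    cnn = backward_cnn(params, cache, dz, spec),
    rnn = backward_rnn(params, cache, dz),
    lstm = ,
    tb_lstm = backward_lstm(params, cache, dz))
}

# Mean binary cross-entropy and its logit gradient, clamped for stability.
bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

# Dropout mask dimensions for the pre-output feature vector of each arch.
feature_dim <- function(spec, batch_size) {
  switch(effective_arch(spec),
    lr = c(batch_size, spec$input_length),
    mlp = c(batch_size, spec$hidden_size),
    cnn = {
      q <- (spec$input_length - spec$filter_length + 1L) %/% spec$pool_length
      c(batch_size, q * spec$conv_filters)
    },
    c(batch_size, spec$hidden_size))
}

# One RMSprop step; state is mutated and returned alongside params.
rmsprop_step <- function(params, grads, state, lr, rho, eps) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

# Left-pad a list of [T_i x D] sequence matrices into a batch array + mask.
stack_sequences <- function(seqs) {
  B <- length(seqs)
  lens <- vapply(seqs, nrow, integer(1))
  D <- ncol(seqs[[1]])
  Tn <- max(lens)
  x <- array(0, c(B, Tn, D))
  mask <- matrix(0, B, Tn)
  for (i in seq_len(B)) {
    if (lens[i] > 0L) {
      x[i, (Tn - lens[i] + 1L):Tn, ] <- seqs[[i]]
      mask[i, (Tn - lens[i] + 1L):Tn] <- 1
    }
  }
  list(x = x, mask = mask)
}
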