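# Minimal LSTM + dense network used by the DQN recommender.
#
# Architecture: a single LSTM layer reads the selection-history window (one
# 3-course one-hot tag encoding per day), its final hidden state is
# concatenated with the one-hot action encoding (course (+) tag) and fed to
# a ReLU hidden layer and a linear scalar output (the Q value). Training is
# mean-squared-error regression on bootstrap targets with Adam.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

# Parameter container. input_dim: per-timestep input width; action_dim:
# action-encoding width; H: LSTM units; D: dense hidden units.
qnet_init <- function(input_dim, action_dim, H = 32L, D = 16L) {
  list(W_lstm = glorot(4L * H, input_dim + H),
       b_lstm = {
         b <- numeric(4L * H)
         b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
         b
       },
       W1 = glorot(D, H + action_dim), b1 = numeric(D),
       W2 = glorot(1L, D), b2 = numeric(1L),
       dims = list(input_dim = input_dim, action_dim = action_dim,
                   H = H, D = D))
}

# Forward pass. X: list over timesteps of (batch x input_dim) matrices;
# A: batch x action_dim. Returns q (batch vector); with cache = TRUE also
# every intermediate needed for backprop. drop_mask: optional inverted
# dropout mask applied to the dense hidden layer (training only).
qnet_forward <- function(par, X, A, cache = FALSE, drop_mask = NULL) {
  H <- par$dims$H
  n <- nrow(A)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps <- if (cache) vector("list", length(X)) else NULL
  for (t in seq_along(X)) {
    u <- cbind(X[[t]], h)
    z <- u %*% t(par$W_lstm) + matrix(par$b_lstm, n, 4L * H, byrow = TRUE)
    i_g <- sigmoid(z[, 1:H, drop = FALSE])
    f_g <- sigmoid(z[, (H + 1L):(2L * H), drop = FALSE])
    g_g <- tanh(z[, (2L * H + 1L):(3L * H), drop = FALSE])
    o_g <- sigmoid(z[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    if (cache)
      steps[[t]] <- list(u = u, i = i_g, f = f_g, g = g_g, o = o_g,
                         c_prev = cc, tc = tc)
    cc <- c_new; h <- h_new
  }
  ua <- cbind(h, A)
  pre1 <- ua %*% t(par$W1) + matrix(par$b1, n, par$dims$D, byrow = TRUE)
  h1 <- pmax(pre1, 0)
  if (!is.null(drop_mask)) h1 <- h1 * drop_mask
  q <- drop(h1 %*% t(par$W2)) + par$b2
  if (!cache) return(q)
  list(q = q, h_final = h, ua = ua, pre1 = pre1, h1 = h1, steps = steps,
       X = X)
}

# Backward pass for loss L = mean((q - target)^2)/2. Returns gradients with
# the same shapes as the parameters.
qnet_backward <- function(par, fw, target, drop_mask = NULL) {
  H <- par$dims$H
  n <- length(fw$q)
  dq <- matrix((fw$q - target) / n, n, 1L)
  gW2 <- t(dq) %*% fw$h1
  gb2 <- sum(dq)
  dh1 <- dq %*% par$W2
  if (!is.null(drop_mask)) dh1 <- dh1 * drop_mask
  dpre1 <- dh1 * (fw$pre1 > 0)
  gW1 <- t(dpre1) %*% fw$ua
  gb1 <- colSums(dpre1)
  dua <- dpre1 %*% par$W1
  dh <- dua[, 1:H, drop = FALSE]
  dc <- matrix(0, n, H)
  gW_lstm <- matrix(0, nrow(par$W_lstm), ncol(par$W_lstm))
  gb_lstm <- numeric(length(par$b_lstm))
  for (t in rev(seq_along(fw$steps))) {
    st <- fw$steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc <- dc * st$f
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    gW_lstm <- gW_lstm + t(dz) %*% st$u
    gb_lstm <- gb_lstm + colSums(dz)
    dh <- (dz %*% par$W_lstm)[, (par$dims$input_dim + 1L):
                                (par$dims$input_dim + H), drop = FALSE]
  }
  list(W_lstm = gW_lstm, b_lstm = gb_lstm, W1 = gW1, b1 = gb1,
       W2 = gW2, b2 = gb2)
}

adam_init <- function(par) {
  keep <- c("W_lstm", "b_lstm", "W1", "b1", "W2", "b2")
  list(m = lapply(par[keep], function(p) p * 0),
       v = lapply(par[keep], function(p) p * 0), t = 0L)
}

adam_step <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(opt$m)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, opt = opt)
}
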