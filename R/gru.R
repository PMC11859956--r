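# Gated recurrent unit regression engine.
#
# A single classic GRU layer (v1 formulation, one bias per gate) over a short
# input sequence, followed by one linear output unit, trained with mean
# absolute error and Adam. Dropout follows the inverted convention: masks are
# drawn once per sequence per batch and shared across time steps; `dropout`
# masks the inputs to all three gates, `recurrent_dropout` masks the previous
# hidden state as seen by the gates (the carry path is never masked).
#
# Gate equations (column-major batches; X_t is n x d, H is n x h):
#   Z = sigmoid(X_t Wz + H~ Uz + bz)        update gate
#   R = sigmoid(X_t Wr + H~ Ur + br)        reset gate
#   C = phi(X_t Wc + (R * H~) Uc + bc)      candidate, phi = relu or identity
#   H' = Z * H + (1 - Z) * C
# All gradients are derived by backpropagation through time and verified in
# the test suite against central finite differences.

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_activation <- function(name) {
  switch(name,
         relu = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
         none = list(f = identity, df = function(x) array(1, dim = dim(x))),
         abort_config(sprintf("unknown activation '%s'", name)))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Parameter initialisation. Must be called under a seeded RNG.
gru_init <- function(d, h) {
  list(Wz = glorot(d, h), Wr = glorot(d, h), Wc = glorot(d, h),
       Uz = glorot(h, h), Ur = glorot(h, h), Uc = glorot(h, h),
       bz = numeric(h), br = numeric(h), bc = numeric(h),
       w = glorot(h, 1), b = 0)
}

gru_param_count <- function(d, h) {
  3L * (d * h + h * h + h) + h + 1L
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Forward pass. X: n x T x d array. Returns predictions and, if keep_cache,
# the per-step quantities needed by the backward pass.
gru_forward <- function(params, X, act, mask_in = NULL, mask_rec = NULL,
                        keep_cache = FALSE) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  h <- length(params$bz)
  H <- matrix(0, n, h)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(n, dim(X)[3])
    if (!is.null(mask_in)) Xt <- Xt * mask_in
    Hd <- if (!is.null(mask_rec)) H * mask_rec else H
    Az <- add_bias(Xt %*% params$Wz + Hd %*% params$Uz, params$bz)
    Z <- sigmoid(Az)
    Ar <- add_bias(Xt %*% params$Wr + Hd %*% params$Ur, params$br)
    R <- sigmoid(Ar)
    RH <- R * Hd
    Ac <- add_bias(Xt %*% params$Wc + RH %*% params$Uc, params$bc)
    C <- act$f(Ac)
    Hnew <- Z * H + (1 - Z) * C
    if (keep_cache)
      cache[[t]] <- list(Xt = Xt, Hd = Hd, Hprev = H, Z = Z, R = R,
                         RH = RH, Ac = Ac, C = C)
    H <- Hnew
  }
  pred <- as.numeric(H %*% params$w + params$b)
  list(pred = pred, H_last = H, cache = cache)
}

# Backward pass for mean absolute error. Returns gradients with the same
# shapes as the parameters.
gru_backward <- function(params, fwd, X, y, act, mask_rec = NULL) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  h <- length(params$bz)
  g <- list(Wz = 0 * params$Wz, Wr = 0 * params$Wr, Wc = 0 * params$Wc,
            Uz = 0 * params$Uz, Ur = 0 * params$Ur, Uc = 0 * params$Uc,
            bz = numeric(h), br = numeric(h), bc = numeric(h),
            w = 0 * params$w, b = 0)
  dpred <- matrix(sign(fwd$pred - y) / n, n, 1)
  g$w <- t(fwd$H_last) %*% dpred
  g$b <- sum(dpred)
  dH <- dpred %*% t(params$w)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    dC <- dH * (1 - cc$Z)
    dAc <- dC * act$df(cc$Ac)
    dZ <- dH * (cc$Hprev - cc$C)
    dAz <- dZ * cc$Z * (1 - cc$Z)
    dRH <- dAc %*% t(params$Uc)
    dR <- dRH * cc$Hd
    dAr <- dR * cc$R * (1 - cc$R)
    g$Wz <- g$Wz + t(cc$Xt) %*% dAz
    g$Wr <- g$Wr + t(cc$Xt) %*% dAr
    g$Wc <- g$Wc + t(cc$Xt) %*% dAc
    g$Uz <- g$Uz + t(cc$Hd) %*% dAz
    g$Ur <- g$Ur + t(cc$Hd) %*% dAr
    g$Uc <- g$Uc + t(cc$RH) %*% dAc
    g$bz <- g$bz + colSums(dAz)
    g$br <- g$br + colSums(dAr)
    g$bc <- g$bc + colSums(dAc)
    dHd <- dAz %*% t(params$Uz) + dAr %*% t(params$Ur) + dRH * cc$R
    if (!is.null(mask_rec)) dHd <- dHd * mask_rec
    dH <- dH * cc$Z + dHd
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Full training loop, reference R implementation (kept as the slow
# cross-check for the compiled path; see gru_fit below). X: n x T x d,
# y: length-n numeric. Deterministic given seed (initialisation, shuffling
# and dropout masks all drawn from it).
gru_fit_r <- function(X, y, hidden_units, activation, dropout, recurrent_dropout,
                      learning_rate, batch_size, epochs, seed,
                      init_params = NULL) {
  n <- dim(X)[1]; d <- dim(X)[3]
  act <- gru_activation(activation)
  with_seed(seed, {
    params <- if (is.null(init_params)) gru_init(d, hidden_units) else init_params
    state <- adam_init(params)
    if (epochs > 0L) {
      for (ep in seq_len(epochs)) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = batch_size)
        for (s in starts) {
          idx <- perm[s:min(s + batch_size - 1L, n)]
          nb <- length(idx)
          Xb <- X[idx, , , drop = FALSE]
          yb <- y[idx]
          mi <- if (dropout > 0) {
            (matrix(stats::runif(nb * d), nb, d) >= dropout) / (1 - dropout)
          } else NULL
          mr <- if (recurrent_dropout > 0) {
            (matrix(stats::runif(nb * hidden_units), nb, hidden_units) >=
               recurrent_dropout) / (1 - recurrent_dropout)
          } else NULL
          fwd <- gru_forward(params, Xb, act, mask_in = mi, mask_rec = mr,
                             keep_cache = TRUE)
          grads <- gru_backward(params, fwd, Xb, yb, act, mask_rec = mr)
          upd <- adam_step(params, grads, state, learning_rate)
          params <- upd$params
          state <- upd$state
        }
      }
    }
    params
  })
}

# Production training loop: same algorithm in compiled form (src/gru.cpp),
# sharing R's RNG so a seed fully determines the fit.
gru_fit <- function(X, y, hidden_units, activation, dropout, recurrent_dropout,
                    learning_rate, batch_size, epochs, seed,
                    init_params = NULL) {
  act_code <- if (activation == "relu") 1L else 0L
  gru_activation(activation) # validates the name
  with_seed(seed, {
    params <- if (is.null(init_params)) gru_init(dim(X)[3], hidden_units) else init_params
    if (epochs > 0L) {
      params <- cpp_gru_fit(params, aperm(X, c(1, 3, 2)), y,
                            dropout, recurrent_dropout, learning_rate,
                            as.integer(batch_size), as.integer(epochs),
                            act_code)
      params$bz <- as.numeric(params$bz)
      params$br <- as.numeric(params$br)
      params$bc <- as.numeric(params$bc)
    }
    params
  })
}

gru_infer <- function(params, X, activation) {
  act_code <- if (activation == "relu") 1L else 0L
  as.numeric(cpp_gru_predict(params, aperm(X, c(1, 3, 2)), act_code))
}

# Reference inference path (pure R), used in equivalence tests.
gru_infer_r <- function(params, X, activation) {
  gru_forward(params, X, gru_activation(activation))$pred
}
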