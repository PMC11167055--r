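# Batched single-layer LSTM over flattened per-frame feature vectors, with
# manual backpropagation through time. Sequences in one call share a length
# (the preprocessing aligns every clip to a fixed length); batches are
# n x T x d arrays. Gate order in the packed weight matrices: input, forget,
# output, candidate. Forget-gate bias starts at +1.

lstmInit <- function(d_in, d_hidden, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- 1 / sqrt(d_hidden)
  b <- numeric(4L * d_hidden)
  b[d_hidden + seq_len(d_hidden)] <- 1
  list(Wx = uniformInit(d_in, 4L * d_hidden, s),
       Wh = uniformInit(d_hidden, 4L * d_hidden, s),
       b = b)
}

# forward pass; returns final hidden state and a cache for backprop
lstmForward <- function(params, X) {
  n <- dim(X)[1L]; T <- dim(X)[2L]
  h <- ncol(params$Wh)
  dh <- h / 4L
  H <- matrix(0, n, dh); C <- matrix(0, n, dh)
  cache <- vector("list", T)
  ix <- seq_len(dh)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], n, dim(X)[3L])
    z <- xt %*% params$Wx + H %*% params$Wh +
      matrix(params$b, n, h, byrow = TRUE)
    i <- 1 / (1 + exp(-z[, ix, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, dh + ix, drop = FALSE]))
    o <- 1 / (1 + exp(-z[, 2L * dh + ix, drop = FALSE]))
    g <- tanh(z[, 3L * dh + ix, drop = FALSE])
    Cprev <- C
    C <- f * Cprev + i * g
    tc <- tanh(C)
    Hprev <- H
    H <- o * tc
    cache[[t]] <- list(x = xt, i = i, f = f, o = o, g = g, C = C,
                       Cprev = Cprev, tc = tc, Hprev = Hprev)
  }
  list(H = H, cache = cache)
}

# backprop given dLoss/dH_final; returns gradients for Wx, Wh, b
lstmBackward <- function(params, fwd, dH) {
  cache <- fwd$cache
  T <- length(cache)
  dh <- ncol(dH)
  ix <- seq_len(dh)
  dWx <- params$Wx * 0; dWh <- params$Wh * 0; db <- params$b * 0
  dC <- dH * 0
  for (t in rev(seq_len(T))) {
    cc <- cache[[t]]
    dtc <- dH * cc$o
    dC <- dC + dtc * (1 - cc$tc^2)
    do <- dH * cc$tc
    di <- dC * cc$g
    dg <- dC * cc$i
    df <- dC * cc$Cprev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$Hprev, dz)
    db <- db + colSums(dz)
    dH <- tcrossprod(dz, params$Wh)
    dC <- dC * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}
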