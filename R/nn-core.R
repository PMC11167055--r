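# Minimal neural-network primitives shared by the stage-1 sequence model
# and the stage-2 graph-attention module: activations, two-class softmax
# cross-entropy, Adam, and seeded initializers. Everything operates on plain
# matrices so BLAS does the heavy lifting.

leakyRelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
leakyReluGrad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
eluGrad <- function(y) ifelse(y > 0, 1, y + 1)  # in terms of the output

# numerically stable two-class softmax probabilities from n x 2 logits
softmax2 <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - m); e2 <- exp(logits[, 2L] - m)
  cbind(e1, e2, deparse.level = 0) / (e1 + e2)
}

# mean cross-entropy of n x 2 logits against 0/1 labels (class 2 = label 1),
# plus gradient wrt logits (already divided by n)
softmaxCE <- function(logits, labels) {
  p <- softmax2(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  y <- matrix(0, n, 2L)
  y[idx] <- 1
  list(loss = loss, grad = (p - y) / n, prob = p[, 2L])
}

uniformInit <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# deterministic substream seed derived from a base seed and a stage name
# (FNV-1a over the name, folded into 31 bits so it stays a valid R integer)
substreamSeed <- function(seed, name) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(name)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((seed + h) %% 2147483647)
}
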