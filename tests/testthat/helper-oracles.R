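# Independent nested-loop oracle for the graph-attention forward pass:
# explicit per-node, per-neighbor iteration, no matrix batching.
gatOracle <- function(x6d, A, p, cfg) {
  h <- lapply(1:6, function(k) drop(x6d[k, ] %*% p$W))
  e <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) if (A[i, j] == 1) {
    z1 <- drop(c(h[[i]], h[[j]]) %*% p$Wa) + p$ba
    a1 <- ifelse(z1 > 0, z1, cfg$leaky_slope * z1)
    e[i, j] <- sum(a1 * p$va) + p$bva[1, 1]
  }
  alpha <- matrix(0, 6, 6)
  for (i in 1:6) {
    al <- which(A[i, ] == 1)
    if (cfg$use_attention) {
      ex <- exp(e[i, al] - max(e[i, al]))
      alpha[i, al] <- ex / sum(ex)
    } else alpha[i, al] <- 1
  }
  logits <- matrix(0, 6, 2)
  for (i in 1:6) {
    m <- rep(0, cfg$hidden)
    for (j in 1:6) if (A[i, j] == 1) m <- m + alpha[i, j] * h[[j]]
    g <- ifelse(m > 0, m, exp(pmin(m, 0)) - 1)
    z <- drop(g %*% p$Wo) + p$bo
    logits[i, ] <- drop(z %*% p[[paste0("Wh", i)]]) + p[[paste0("bh", i)]]
  }
  list(logits = logits, alpha = alpha)
}

# pairwise brute-force AUC with explicit tie handling
bruteForceAUC <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# helpers: quaternion to rotation matrix, applied rigid motion
quatToRot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

applyRigid <- function(log, q0, t0) {
  R0 <- quatToRot(q0)
  rot <- function(p) t(R0 %*% t(as.matrix(p))) +
    matrix(t0, nrow(p), 3, byrow = TRUE)
  hprod <- function(a, b) c(
    a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(a[3] * b[4] - a[4] * b[3],
                                      a[4] * b[2] - a[2] * b[4],
                                      a[2] * b[3] - a[3] * b[2]))
  out <- log
  for (pre in c(paste0("p", 1:10, "_"), "cam_")) {
    pc <- paste0(pre, c("x", "y", "z"))
    qc <- paste0(pre, c("qw", "qx", "qy", "qz"))
    out[, pc] <- rot(log[, pc])
    out[, qc] <- t(apply(log[, qc], 1, function(q) hprod(q0, q)))
  }
  out
}

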