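# Stage 2: the joint skill-assessment module. Each sub-skill is a node whose
# input is its stage-1 clip feature concatenated with its flattened aligned
# kinematics (128 + 70*24 = 1808 at defaults). A shared linear map lifts
# node inputs to the hidden space; a one-hidden-layer scorer on concatenated
# transformed pairs produces attention scores, masked to the prior graph and
# row-softmax-normalized; each node aggregates its allowed neighbors'
# transformed features with those weights, passes through ELU, a shared
# output projection, and a node-specific two-class head. Training minimizes
# the sum over the six heads of the cross-entropy. Gradients are derived by
# hand; parameters update with Adam.

#' Stage-2 (joint model) configuration
#'
#' @param hidden shared hidden dimension of the node transform (default 1024).
#' @param out output dimension after the projection (default 128).
#' @param attn_hidden hidden width of the one-layer attention scorer
#'   (default 1024).
#' @param use_attention learned masked attention (TRUE) or the "w/o
#'   attention" ablation where every allowed edge has fixed strength one.
#' @param attention_off_agg aggregation used by the w/o-attention ablation:
#'   \code{"sum"} (fixed unit weights, default) or \code{"mean"}.
#' @param use_kinematics include the kinematic block of the node input; when
#'   FALSE the block is zeroed (video-only ablation), keeping dimensions.
#' @param leaky_slope LeakyReLU slope inside the scorer (default 0.2).
#' @param dropout train-time inverted dropout rate on node inputs (default
#'   0.2), following the cited graph-attention training regime; prediction
#'   is deterministic (no dropout at inference).
#' @param attn_dropout train-time inverted dropout rate on the attention
#'   coefficients (edge dropout during aggregation; default 0 = off, made
#'   available because the cited graph-attention regime uses it); the
#'   attention maps the model reports are always the full softmax
#'   coefficients.
#' @param feature_dim width of the leading clip-feature block of the node
#'   input (default 128); used for block-balanced fusion.
#' @param balance_blocks after standardization, rescale the kinematic block
#'   so its total variance matches the clip-feature block's (default TRUE);
#'   otherwise the 1680-dim kinematic block outweighs the 128-dim feature
#'   block 13:1 in the shared linear map.
#' @param learning_rate,epochs,batch_size Adam settings (defaults 1e-3, 50, 32).
#' @param lr_decay multiplicative learning-rate decay applied after
#'   \code{lr_decay_at} of the epochs (default 1 = constant rate).
#' @param lr_decay_at fraction of epochs after which the decay applies.
#' @param seed integer seed for initialization and batch order.
#' @return a \code{jointConfig} list.
#' @export
jointConfig <- function(hidden = 1024L, out = 128L, attn_hidden = 1024L,
                        use_attention = TRUE, attention_off_agg = "sum",
                        use_kinematics = TRUE, leaky_slope = 0.2,
                        dropout = 0.2, attn_dropout = 0, feature_dim = 128L,
                        balance_blocks = TRUE,
                        learning_rate = 1e-3, epochs = 50L, batch_size = 32L,
                        lr_decay = 1, lr_decay_at = 0.7,
                        seed = 1L) {
  stopifnot(hidden > 0, out > 0, attn_hidden > 0, epochs >= 1,
            dropout >= 0, dropout < 1, attn_dropout >= 0, attn_dropout < 1)
  attention_off_agg <- match.arg(attention_off_agg, c("sum", "mean"))
  structure(list(hidden = as.integer(hidden), out = as.integer(out),
                 attn_hidden = as.integer(attn_hidden),
                 use_attention = use_attention,
                 attention_off_agg = attention_off_agg,
                 use_kinematics = use_kinematics, leaky_slope = leaky_slope,
                 dropout = dropout, attn_dropout = attn_dropout,
                 feature_dim = as.integer(feature_dim),
                 balance_blocks = balance_blocks,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_decay = lr_decay,
                 lr_decay_at = lr_decay_at, seed = as.integer(seed)),
            class = "jointConfig")
}

#' Initialize joint-model parameters
#'
#' W and the attention scorer are shared across the six nodes; only the
#' two-class heads are node-specific.
#'
#' @param input_dim per-node input dimension (1808 at package defaults).
#' @param config a \code{\link{jointConfig}}.
#' @param zero_attention initialize the scorer output weights at zero
#'   (uniform attention over each allowed set).
#' @return parameter list: \code{W} (input_dim x hidden), \code{Wa}
#'   (2*hidden x attn_hidden), \code{ba}, \code{va} (attn_hidden), \code{bva}
#'   (scalar), \code{Wo} (hidden x out), \code{bo}, and \code{Wh1..Wh6} /
#'   \code{bh1..bh6} head parameters (out x 2 each).
#' @export
jointModelInit <- function(input_dim, config = jointConfig(),
                           zero_attention = FALSE) {
  set.seed(substreamSeed(config$seed, "joint_init"))
  h <- config$hidden; o <- config$out; ha <- config$attn_hidden
  p <- list(
    W = uniformInit(input_dim, h, 1 / sqrt(input_dim)),
    Wa = uniformInit(2L * h, ha, 1 / sqrt(2 * h)),
    ba = numeric(ha),
    va = if (zero_attention) matrix(0, ha, 1L) else
      uniformInit(ha, 1L, 1 / sqrt(ha)),
    bva = matrix(0, 1L, 1L),
    Wo = uniformInit(h, o, 1 / sqrt(h)),
    bo = numeric(o))
  for (k in 1:6) {
    p[[paste0("Wh", k)]] <- uniformInit(o, 2L, 1 / sqrt(o))
    p[[paste0("bh", k)]] <- numeric(2L)
  }
  p
}

addRow <- function(M, v) M + matrix(v, nrow(M), length(v), byrow = TRUE)

#' Forward pass of the joint model
#'
#' @param inputs n x 6 x d array of node inputs (stitches x sub-skills x
#'   input dimension), or a 6 x d matrix for a single stitch.
#' @param graph a \code{\link{priorGraph}}.
#' @param params from \code{\link{jointModelInit}}.
#' @param config a \code{\link{jointConfig}}.
#' @param keep_cache retain intermediates for backpropagation.
#' @return list: \code{logits} (n x 6 x 2), \code{prob} (n x 6 matrix of
#'   ideal-skill probabilities), \code{attention} (n x 6 x 6; rows sum to 1
#'   over each allowed set when attention is on, exact zeros off-graph),
#'   \code{embeddings} (n x 6 x out), and (optionally) \code{cache}.
#' @export
gatForward <- function(inputs, graph, params, config = jointConfig(),
                       keep_cache = FALSE, alpha_mask = NULL) {
  if (is.matrix(inputs)) inputs <- array(inputs, c(1L, dim(inputs)))
  n <- dim(inputs)[1L]
  if (dim(inputs)[2L] != 6L)
    stop("node inputs must cover the six sub-skills", call. = FALSE)
  if (dim(inputs)[3L] != nrow(params$W))
    stop("node input dimension ", dim(inputs)[3L], " does not match model (",
         nrow(params$W), ")", call. = FALSE)
  A <- adjacency(graph)
  h <- config$hidden
  X <- do.call(rbind, lapply(1:6, function(k) matrix(inputs[, k, ], n)))
  H <- X %*% params$W
  Hk <- lapply(1:6, function(k) H[(k - 1L) * n + seq_len(n), , drop = FALSE])
  pairs <- which(A == 1, arr.ind = TRUE)   # (i = attender, j = attended)
  alpha <- array(0, c(n, 6L, 6L))
  paircache <- vector("list", nrow(pairs))
  if (config$use_attention) {
    E <- array(-Inf, c(n, 6L, 6L))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      C <- cbind(Hk[[i]], Hk[[j]])
      Z1 <- addRow(C %*% params$Wa, params$ba)
      A1 <- leakyRelu(Z1, config$leaky_slope)
      E[, i, j] <- A1 %*% params$va + params$bva[1L, 1L]
      if (keep_cache) paircache[[p]] <- list(Z1 = Z1)
    }
    for (i in 1:6) {
      allowed <- which(A[i, ] == 1)
      sub <- matrix(E[, i, allowed], n)
      sub <- exp(sub - apply(sub, 1L, max))
      alpha[, i, allowed] <- sub / rowSums(sub)
    }
  } else {
    w <- if (config$attention_off_agg == "sum") 1 else NA
    for (i in 1:6) {
      allowed <- which(A[i, ] == 1)
      alpha[, i, allowed] <- if (is.na(w)) 1 / length(allowed) else w
    }
  }
  am <- if (is.null(alpha_mask)) alpha else alpha * alpha_mask
  M <- vector("list", 6L)
  for (i in 1:6) {
    Mi <- matrix(0, n, h)
    for (j in which(A[i, ] == 1)) Mi <- Mi + am[, i, j] * Hk[[j]]
    M[[i]] <- Mi
  }
  G <- lapply(M, elu)
  Z <- lapply(G, function(g) addRow(g %*% params$Wo, params$bo))
  logits <- array(0, c(n, 6L, 2L))
  prob <- matrix(0, n, 6L, dimnames = list(NULL, subSkillCodes()))
  for (k in 1:6) {
    lg <- addRow(Z[[k]] %*% params[[paste0("Wh", k)]], params[[paste0("bh", k)]])
    logits[, k, ] <- lg
    prob[, k] <- softmax2(lg)[, 2L]
  }
  emb <- array(0, c(n, 6L, config$out))
  for (k in 1:6) emb[, k, ] <- Z[[k]]
  res <- list(logits = logits, prob = prob, attention = alpha,
              embeddings = emb)
  if (keep_cache)
    res$cache <- list(X = X, Hk = Hk, pairs = pairs, paircache = paircache,
                      alpha = alpha, am = am, G = G, Z = Z, n = n,
                      alpha_mask = alpha_mask)
  res
}

#' Joint training loss: summed per-sub-skill cross-entropy
#'
#' The loss is the sum over the six sub-skill heads of the cross-entropy
#' between the head's softmax and the binary label (averaged over stitches
#' within each head). Uniform logits give 6 log 2 per stitch.
#'
#' @param logits n x 6 x 2 array (or 6 x 2 matrix for one stitch).
#' @param labels n x 6 binary matrix (or length-6 vector).
#' @return scalar loss.
#' @export
jointLoss <- function(logits, labels) {
  if (is.matrix(logits) && is.null(dim(labels)))
    logits <- array(logits, c(1L, dim(logits)))
  if (is.null(dim(labels))) labels <- matrix(labels, 1L)
  sum(vapply(1:6, function(k) {
    softmaxCE(matrix(logits[, k, ], ncol = 2L), labels[, k])$loss
  }, numeric(1)))
}

# backward pass; returns gradients for every parameter
gatBackward <- function(labels, fwd, graph, params, config) {
  cc <- fwd$cache
  n <- cc$n; h <- config$hidden
  A <- adjacency(graph)
  grads <- lapply(params, function(p) p * 0)
  dZ <- vector("list", 6L)
  for (k in 1:6) {
    ce <- softmaxCE(matrix(fwd$logits[, k, ], ncol = 2L), labels[, k])
    Wh <- params[[paste0("Wh", k)]]
    grads[[paste0("Wh", k)]] <- crossprod(cc$Z[[k]], ce$grad)
    grads[[paste0("bh", k)]] <- colSums(ce$grad)
    dZ[[k]] <- tcrossprod(ce$grad, Wh)
  }
  dH <- lapply(1:6, function(k) matrix(0, n, h))
  dalpha <- array(0, c(n, 6L, 6L))
  for (k in 1:6) {
    grads$Wo <- grads$Wo + crossprod(cc$G[[k]], dZ[[k]])
    grads$bo <- grads$bo + colSums(dZ[[k]])
    dG <- tcrossprod(dZ[[k]], params$Wo)
    dM <- dG * eluGrad(cc$G[[k]])
    for (j in which(A[k, ] == 1)) {
      dam <- rowSums(dM * cc$Hk[[j]])
      dalpha[, k, j] <- if (is.null(cc$alpha_mask)) dam else
        dam * cc$alpha_mask[, k, j]
      dH[[j]] <- dH[[j]] + cc$am[, k, j] * dM
    }
  }
  if (config$use_attention) {
    dE <- array(0, c(n, 6L, 6L))
    for (i in 1:6) {
      allowed <- which(A[i, ] == 1)
      al <- matrix(cc$alpha[, i, allowed], n)
      da <- matrix(dalpha[, i, allowed], n)
      inner <- rowSums(al * da)
      dE[, i, allowed] <- al * (da - inner)
    }
    for (p in seq_len(nrow(cc$pairs))) {
      i <- cc$pairs[p, 1L]; j <- cc$pairs[p, 2L]
      de <- dE[, i, j]
      if (all(de == 0)) next
      Z1 <- cc$paircache[[p]]$Z1
      A1 <- leakyRelu(Z1, config$leaky_slope)
      grads$va <- grads$va + crossprod(A1, de)
      grads$bva <- grads$bva + sum(de)
      dZ1 <- (de %*% t(params$va)) * leakyReluGrad(Z1, config$leaky_slope)
      C <- cbind(cc$Hk[[i]], cc$Hk[[j]])
      grads$Wa <- grads$Wa + crossprod(C, dZ1)
      grads$ba <- grads$ba + colSums(dZ1)
      dC <- tcrossprod(dZ1, params$Wa)
      dH[[i]] <- dH[[i]] + dC[, seq_len(h), drop = FALSE]
      dH[[j]] <- dH[[j]] + dC[, h + seq_len(h), drop = FALSE]
    }
  }
  dHs <- do.call(rbind, dH)
  grads$W <- crossprod(cc$X, dHs)
  grads
}

#' Train the stage-2 joint model
#'
#' Stage-1 features are frozen inputs; this trains only the joint-module
#' parameters (shared transform, attention scorer, projection, six heads)
#' with minibatch Adam against \code{\link{jointLoss}}.
#'
#' @param inputs n x 6 x d node-input array (see \code{\link{buildNodeInputs}}).
#' @param labels n x 6 binary matrix, columns ordered \code{subSkillCodes()};
#'   every sub-skill needs both classes in the training data.
#' @param graph a \code{\link{priorGraph}}.
#' @param config a \code{\link{jointConfig}}.
#' @return a \code{jointModel} list: \code{params}, \code{config},
#'   \code{graph}, \code{loss_trace}.
#' @export
trainJoint <- function(inputs, labels, graph = priorGraph(),
                       config = jointConfig()) {
  labels <- as.matrix(labels)
  n <- dim(inputs)[1L]
  bad <- which(vapply(1:6, function(k) length(unique(labels[, k])) < 2L,
                      logical(1)))
  if (length(bad) > 0L)
    stop("single-class training labels for sub-skill(s): ",
         paste(subSkillCodes()[bad], collapse = ", "), call. = FALSE)
  # per-(node, dimension) train-set standardization; constant dims pass
  # through untouched (zeroed kinematic blocks stay zero)
  mu <- apply(inputs, c(2L, 3L), mean)
  sd <- apply(inputs, c(2L, 3L), stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  d <- dim(inputs)[3L]
  if (isTRUE(config$balance_blocks) && d > config$feature_dim) {
    kd <- d - config$feature_dim
    # fold the block rescale into the stored scale so prediction matches
    sd[, config$feature_dim + seq_len(kd)] <-
      sd[, config$feature_dim + seq_len(kd)] * sqrt(kd / config$feature_dim)
  }
  inputs <- standardizeInputs(inputs, mu, sd)
  params <- jointModelInit(d, config)
  st <- adamInit(params)
  set.seed(substreamSeed(config$seed, "joint_batches"))
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      if (ep > config$lr_decay_at * config$epochs) config$lr_decay else 1
    ord <- sample.int(n)
    eploss <- 0
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      xb <- inputs[idx, , , drop = FALSE]
      if (config$dropout > 0) {
        keep <- 1 - config$dropout
        mask <- array(stats::rbinom(length(xb), 1L, keep) / keep, dim(xb))
        xb <- xb * mask
      }
      amask <- NULL
      if (config$attn_dropout > 0) {
        keep <- 1 - config$attn_dropout
        amask <- array(stats::rbinom(length(idx) * 36L, 1L, keep) / keep,
                       c(length(idx), 6L, 6L))
      }
      fwd <- gatForward(xb, graph, params, config, keep_cache = TRUE,
                        alpha_mask = amask)
      eploss <- eploss + jointLoss(fwd$logits, labels[idx, , drop = FALSE]) *
        length(idx)
      grads <- gatBackward(labels[idx, , drop = FALSE], fwd, graph, params,
                           config)
      upd <- adamStep(params, grads, st, lr = lr)
      params <- upd$params; st <- upd$state
    }
    trace[ep] <- eploss / n
  }
  structure(list(params = params, config = config, graph = graph,
                 loss_trace = trace, center = mu, scale = sd),
            class = "jointModel")
}

standardizeInputs <- function(inputs, mu, sd) {
  for (k in 1:6) {
    inputs[, k, ] <- sweep(sweep(matrix(inputs[, k, ], dim(inputs)[1L]),
                                 2L, mu[k, ]), 2L, sd[k, ], "/")
  }
  inputs
}

#' Predict with a trained joint model
#'
#' Applies the training-set standardization stored in the model, then runs
#' the forward pass.
#'
#' @param model a \code{jointModel} from \code{\link{trainJoint}}.
#' @param inputs n x 6 x d node-input array.
#' @return as \code{\link{gatForward}} (no cache).
#' @export
predictJoint <- function(model, inputs) {
  if (is.matrix(inputs)) inputs <- array(inputs, c(1L, dim(inputs)))
  if (!is.null(model$center))
    inputs <- standardizeInputs(inputs, model$center, model$scale)
  gatForward(inputs, model$graph, model$params, model$config)
}

#' Dataset-averaged attention map
#'
#' Per-stitch attention maps averaged over a dataset. Entries off the prior
#' graph are exactly zero; with attention on, each row of the average still
#' sums to 1 over its allowed set.
#'
#' @param model a \code{jointModel}.
#' @param inputs nonempty n x 6 x d node-input array.
#' @return 6 x 6 matrix, rows/cols ordered \code{subSkillCodes()}.
#' @export
extractAttention <- function(model, inputs) {
  if (is.matrix(inputs)) inputs <- array(inputs, c(1L, dim(inputs)))
  if (dim(inputs)[1L] == 0L) stop("empty dataset", call. = FALSE)
  fwd <- predictJoint(model, inputs)
  m <- apply(fwd$attention, c(2L, 3L), mean)
  dimnames(m) <- list(subSkillCodes(), subSkillCodes())
  m
}

#' Assemble stage-2 node inputs from features and kinematics
#'
#' Concatenates, per (stitch, sub-skill), the stage-1 feature vector and the
#' flattened aligned kinematics. With \code{use_kinematics = FALSE} the
#' kinematic block is zeroed but kept, so the input dimension is unchanged
#' (feature_dim + 70 * target_len; 1808 at defaults).
#'
#' @param cohort a \code{SutureCohort}.
#' @param store a \code{FeatureStore} covering every (stitch, sub-skill).
#' @param kin optional precomputed array from \code{\link{cohortKinematics}};
#'   computed from the cohort when NULL.
#' @param target_len aligned kinematic length (default 24).
#' @param use_kinematics zero the kinematic block when FALSE.
#' @return n x 6 x (feature_dim + 70 * target_len) array.
#' @export
buildNodeInputs <- function(cohort, store, kin = NULL, target_len = 24L,
                            use_kinematics = TRUE) {
  st <- cohort@stitches
  codes <- subSkillCodes()
  fd <- featureDim(store)
  kd <- KIN_WIDTH * target_len
  if (use_kinematics && is.null(kin)) {
    if (length(cohort@kinematics) == 0L || is.null(cohort@kinematics[[1L]]))
      stop("use_kinematics = TRUE but the cohort has no kinematic logs",
           call. = FALSE)
    kin <- cohortKinematics(cohort, target_len)
  }
  out <- array(0, c(nrow(st), 6L, fd + kd),
               dimnames = list(st$stitch_id, codes, NULL))
  for (r in seq_len(nrow(st))) {
    for (ki in seq_along(codes)) {
      out[r, ki, seq_len(fd)] <- getFeature(store, st$stitch_id[r], codes[ki])
      if (use_kinematics) out[r, ki, fd + seq_len(kd)] <- kin[r, ki, ]
    }
  }
  out
}
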