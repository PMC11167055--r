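# Stage 1: independent per-sub-skill sequence models. A frozen convolutional
# frame featurizer (seeded random filters by default, standing in for a
# frozen pretrained backbone) turns appearance and optical-flow frames into
# flattened per-frame vectors; a trainable LSTM plus a linear head produces
# the clip feature (penultimate, fixed dimension, default 128) and the
# independent binary skill prediction.

#' Stage-1 configuration
#'
#' @param feature_dim clip-feature dimension exported to stage 2 (default 128,
#'   equal to the LSTM hidden size).
#' @param backbone frame featurizer: only \code{"small_conv_stub"} is bundled
#'   (frozen seeded random 5x5 convolutions + quadrant pooling).
#' @param frame_size expected square frame side after center crop (default 224).
#' @param use_flow include optical-flow features alongside appearance.
#' @param learning_rate,epochs,batch_size Adam settings (defaults 1e-3, 50, 16).
#' @param seed integer seed controlling initialization and batching.
#' @return a \code{stage1Config} list.
#' @export
stage1Config <- function(feature_dim = 128L, backbone = "small_conv_stub",
                         frame_size = 224L, use_flow = TRUE,
                         learning_rate = 1e-3, epochs = 50L,
                         batch_size = 16L, seed = 1L) {
  stopifnot(feature_dim > 0, frame_size > 0, epochs >= 1, batch_size >= 1)
  backbone <- match.arg(backbone, "small_conv_stub")
  structure(list(feature_dim = as.integer(feature_dim), backbone = backbone,
                 frame_size = as.integer(frame_size), use_flow = use_flow,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "stage1Config")
}

#' Dense optical flow between consecutive frames by block matching
#'
#' For every consecutive frame pair an integer displacement is estimated per
#' block (sum-of-squared-differences search over a square radius) and
#' broadcast to the block's pixels, yielding a dense block-constant
#' 2-channel displacement field. Channel 1 is horizontal (column)
#' displacement, channel 2 vertical (row), in pixels.
#'
#' @param frames T x H x W array (grayscale) or T x H x W x C (averaged to
#'   grayscale); T >= 2.
#' @param block block side in pixels (default 8).
#' @param radius maximum displacement searched (default 5 px).
#' @return (T-1) x H x W x 2 flow array.
#' @export
computeFlow <- function(frames, block = 8L, radius = 5L) {
  if (length(dim(frames)) == 4L) {
    frames <- apply(frames, c(1, 2, 3), mean)
  }
  T <- dim(frames)[1L]
  if (is.na(T) || T < 2L)
    stop("optical flow needs at least two frames", call. = FALSE)
  H <- dim(frames)[2L]; W <- dim(frames)[3L]
  shifts <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  out <- array(0, dim = c(T - 1L, H, W, 2L))
  rows0 <- seq(1L, H, by = block); cols0 <- seq(1L, W, by = block)
  for (t in seq_len(T - 1L)) {
    a <- frames[t, , ]; b <- frames[t + 1L, , ]
    for (r0 in rows0) for (c0 in cols0) {
      rr <- r0:min(r0 + block - 1L, H)
      cc <- c0:min(c0 + block - 1L, W)
      patch <- a[rr, cc]
      best <- Inf; bu <- 0L; bv <- 0L
      for (s in seq_len(nrow(shifts))) {
        dy <- shifts$dy[s]; dx <- shifts$dx[s]
        rr2 <- rr + dy; cc2 <- cc + dx
        if (rr2[1L] < 1L || cc2[1L] < 1L || rr2[length(rr2)] > H ||
            cc2[length(cc2)] > W) next
        ssd <- sum((b[rr2, cc2] - patch)^2)
        if (ssd < best) { best <- ssd; bu <- dx; bv <- dy }
      }
      out[t, rr, cc, 1L] <- bu
      out[t, rr, cc, 2L] <- bv
    }
  }
  out
}

# frozen random-filter conv featurizer: K 5x5 filters (seeded), valid
# convolution at stride 4, ReLU, mean-pooled over a 2x2 grid of quadrants
# -> 4K scalars per frame
convStubFilters <- function(k = 8L, seed = 99L) {
  set.seed(seed)
  lapply(seq_len(k), function(i) matrix(stats::rnorm(25, sd = 0.5), 5L, 5L))
}

convStubFrame <- function(img, filters, stride = 4L) {
  H <- nrow(img); W <- ncol(img)
  ri <- seq(1L, H - 4L, by = stride); ci <- seq(1L, W - 4L, by = stride)
  feats <- lapply(filters, function(f) {
    m <- matrix(0, length(ri), length(ci))
    for (a in seq_along(ri)) for (b in seq_along(ci)) {
      m[a, b] <- sum(img[ri[a] + 0:4, ci[b] + 0:4] * f)
    }
    pmax(m, 0)
  })
  unlist(lapply(feats, function(m) {
    hr <- nrow(m); hc <- ncol(m)
    h1 <- seq_len(ceiling(hr / 2)); c1 <- seq_len(ceiling(hc / 2))
    c(mean(m[h1, c1]), mean(m[h1, -c1, drop = FALSE]),
      mean(m[-h1, c1, drop = FALSE]), mean(m[-h1, -c1, drop = FALSE]))
  }))
}

#' Encode a clip into per-frame feature vectors
#'
#' Appearance frames (and, when requested, the magnitude of the block-match
#' optical flow, zero for the first frame so lengths agree) pass through the
#' frozen convolutional stub; appearance and flow features are concatenated
#' per frame before the sequence model.
#'
#' @param clip T x H x W (or T x H x W x C) frame array.
#' @param config a \code{\link{stage1Config}}.
#' @return T x d matrix of flattened per-frame features.
#' @export
encodeFrames <- function(clip, config = stage1Config()) {
  if (length(dim(clip)) == 4L) clip <- apply(clip, c(1, 2, 3), mean)
  T <- dim(clip)[1L]
  filters <- convStubFilters(seed = substreamSeed(config$seed, "conv_stub"))
  app <- t(vapply(seq_len(T), function(t) convStubFrame(clip[t, , ], filters),
                  numeric(4L * length(filters))))
  if (!config$use_flow || T < 2L) return(app)
  fl <- computeFlow(clip)
  mag <- sqrt(fl[, , , 1L, drop = FALSE]^2 + fl[, , , 2L, drop = FALSE]^2)
  flow <- t(vapply(seq_len(T - 1L), function(t)
    convStubFrame(matrix(mag[t, , , 1L], dim(mag)[2L], dim(mag)[3L]), filters),
    numeric(4L * length(filters))))
  cbind(app, rbind(0 * flow[1L, ], flow))
}

#' Train a stage-1 sequence model for one sub-skill
#'
#' Sequences (one per stitch: aligned per-frame feature matrices, all the
#' same length; length-1 sequences cover the precomputed-feature path) feed
#' a single-layer LSTM whose final hidden state is the clip feature; a
#' linear head on that state gives the two-class logits. Cross-entropy loss,
#' Adam, fixed epoch count; the per-epoch loss trace is returned.
#'
#' @param sequences list of T x d matrices (equal T) or an n x d matrix of
#'   precomputed per-clip vectors (treated as length-1 sequences).
#' @param labels binary vector, 1 = ideal skill; both classes required.
#' @param config a \code{\link{stage1Config}}.
#' @return a \code{stage1Model} list with elements \code{lstm}, \code{head},
#'   \code{loss_trace}, \code{config}, \code{trained}.
#' @export
trainStage1 <- function(sequences, labels, config = stage1Config()) {
  X <- stackSequences(sequences)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training split contains a single class", call. = FALSE)
  n <- dim(X)[1L]; d <- dim(X)[3L]; h <- config$feature_dim
  # per-dimension standardization over all training frames
  flat <- matrix(X, n * dim(X)[2L], d)
  mu <- colMeans(flat)
  sdv <- apply(flat, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  X <- standardizeFrames(X, mu, sdv)
  set.seed(substreamSeed(config$seed, "stage1_init"))
  params <- lstmInit(d, h)
  params$Wy <- uniformInit(h, 2L, 1 / sqrt(h))
  params$by <- numeric(2L)
  st <- adamInit(params)
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    bs <- config$batch_size
    eploss <- 0
    for (b0 in seq(1L, n, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1L, n)]
      fwd <- lstmForward(params, X[idx, , , drop = FALSE])
      logits <- fwd$H %*% params$Wy + matrix(params$by, length(idx), 2L,
                                             byrow = TRUE)
      ce <- softmaxCE(logits, labels[idx])
      eploss <- eploss + ce$loss * length(idx)
      gH <- tcrossprod(ce$grad, params$Wy)
      grads <- lstmBackward(params, fwd, gH)
      grads$Wy <- crossprod(fwd$H, ce$grad)
      grads$by <- colSums(ce$grad)
      upd <- adamStep(params, grads, st, lr = config$learning_rate)
      params <- upd$params; st <- upd$state
    }
    trace[ep] <- eploss / n
  }
  structure(list(lstm = params[c("Wx", "Wh", "b")],
                 head = params[c("Wy", "by")],
                 loss_trace = trace, config = config, trained = TRUE,
                 center = mu, scale = sdv),
            class = "stage1Model")
}

standardizeFrames <- function(X, mu, sdv) {
  n <- dim(X)[1L]; T <- dim(X)[2L]; d <- dim(X)[3L]
  flat <- sweep(sweep(matrix(X, n * T, d), 2L, mu), 2L, sdv, "/")
  array(flat, c(n, T, d))
}

stackSequences <- function(sequences) {
  if (is.matrix(sequences)) {
    X <- array(sequences, dim = c(nrow(sequences), 1L, ncol(sequences)))
    return(X)
  }
  Ts <- unique(vapply(sequences, nrow, integer(1)))
  if (length(Ts) != 1L)
    stop("sequences in one training call must share a length", call. = FALSE)
  d <- ncol(sequences[[1L]])
  X <- array(0, dim = c(length(sequences), Ts, d))
  for (i in seq_along(sequences)) X[i, , ] <- sequences[[i]]
  X
}

#' Extract the fixed-dimension clip feature
#'
#' @param model trained \code{stage1Model}.
#' @param sequences as in \code{\link{trainStage1}}.
#' @return n x feature_dim matrix (the LSTM final hidden states).
#' @export
extractClipFeature <- function(model, sequences) {
  X <- stackSequences(sequences)
  if (dim(X)[3L] != nrow(model$lstm$Wx))
    stop("frame-feature size mismatch: model expects ",
         nrow(model$lstm$Wx), ", got ", dim(X)[3L], call. = FALSE)
  if (!is.null(model$center))
    X <- standardizeFrames(X, model$center, model$scale)
  lstmForward(model$lstm, X)$H
}

#' Independent per-sub-skill prediction (the "Independent" ablation arm)
#'
#' @param model trained \code{stage1Model}.
#' @param sequences as in \code{\link{trainStage1}}.
#' @return numeric vector of probabilities of ideal skill, in [0, 1].
#' @export
predictIndependent <- function(model, sequences) {
  if (!isTRUE(model$trained)) stop("model is not trained", call. = FALSE)
  H <- extractClipFeature(model, sequences)
  logits <- H %*% model$head$Wy + matrix(model$head$by, nrow(H), 2L,
                                         byrow = TRUE)
  softmax2(logits)[, 2L]
}
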