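test_that("the default prior graph has the three known pairs plus self-loops", {
  g <- priorGraph()
  A <- adjacency(g)
  expect_equal(diag(A), setNames(rep(1, 6), subSkillCodes()))
  expect_equal(sum(A) - 6, 6)       # three undirected edges
  expect_equal(sum(A["HA", ]), 4)   # HR, DS, WR and itself
  expect_equal(A["HR", "HA"], 1)
  expect_equal(A["HA", "DS"], 1)
  expect_equal(A["HA", "WR"], 1)
  expect_equal(A["RP", "WRnw"], 0)
  expect_equal(A, t(A))
  # empty pair list: identity adjacency
  expect_equal(unname(adjacency(priorGraph(list()))), diag(6))
  expect_error(priorGraph(list(c("HA", "HA"))), "self-pair")
  expect_error(priorGraph(list(c("HA", "XX"))), "unknown sub-skill")
  expect_warning(g2 <- priorGraph(list(c("HR", "HA"), c("HA", "HR"))),
                 "duplicate")
  expect_equal(sum(adjacency(g2)) - 6, 2)
})

test_that("masked attention is a row softmax restricted to the allowed set", {
  g <- priorGraph()
  A <- adjacency(g)
  eq <- maskedAttention(matrix(0, 6, 6), g)
  expect_equal(unname(eq["HA", A["HA", ] == 1]), rep(0.25, 4))
  expect_true(all(eq[A == 0] == 0))
  expect_equal(unname(rowSums(eq)), rep(1, 6))
  # closed form on a degree-2 row: scores (0, log 2) -> (1/3, 2/3)
  sc <- matrix(0, 6, 6, dimnames = dimnames(A))
  sc["HR", "HA"] <- log(2)
  a <- maskedAttention(sc, g)
  expect_equal(unname(a["HR", c("HR", "HA")]), c(1 / 3, 2 / 3))
  bad <- matrix(0, 6, 6, dimnames = dimnames(A)); bad[2, 2] <- NA
  expect_error(maskedAttention(bad, g), "non-finite")
})

test_that("gatForward matches the nested-loop oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    d <- sample(5:12, 1)
    cfg <- jointConfig(hidden = sample(4:9, 1), out = sample(3:6, 1),
                       attn_hidden = sample(4:8, 1),
                       use_attention = rep %% 4 != 0, seed = rep)
    g <- if (rep %% 3 == 0) priorGraph(list(c("RP", "WRnw"), c("HR", "HA")))
         else priorGraph()
    p <- jointModelInit(d, cfg)
    n <- sample(1:3, 1)
    X <- array(rnorm(n * 6 * d), c(n, 6, d))
    fwd <- gatForward(X, g, p, cfg)
    for (i in seq_len(n)) {
      ora <- gatOracle(matrix(X[i, , ], 6, d), adjacency(g), p, cfg)
      expect_equal(matrix(fwd$logits[i, , ], 6, 2), ora$logits,
                   tolerance = 1e-6)
      expect_equal(matrix(fwd$attention[i, , ], 6, 6), ora$alpha,
                   tolerance = 1e-6)
    }
  }
})

test_that("attention maps conserve mass over allowed sets and mask non-edges", {
  set.seed(32)
  g <- priorGraph()
  A <- adjacency(g)
  cfg <- jointConfig(hidden = 8, out = 4, attn_hidden = 6, seed = 2)
  p <- jointModelInit(10, cfg)
  X <- array(rnorm(50 * 6 * 10), c(50, 6, 10))
  al <- gatForward(X, g, p, cfg)$attention
  for (i in 1:6) {
    expect_equal(unname(apply(al[, i, A[i, ] == 1, drop = FALSE], 1, sum)),
                 rep(1, 50), tolerance = 1e-6)
    if (any(A[i, ] == 0))
      expect_true(all(al[, i, A[i, ] == 0] == 0))
  }
  expect_true(all(al >= 0 & al <= 1 + 1e-9))
  # zero-initialized scorer: exactly uniform over each allowed set
  p0 <- jointModelInit(10, cfg, zero_attention = TRUE)
  mdl0 <- structure(list(params = p0, config = cfg, graph = g),
                    class = "jointModel")
  am <- extractAttention(mdl0, X)
  for (i in 1:6) {
    deg <- sum(A[i, ])
    expect_equal(unname(am[i, A[i, ] == 1]), rep(1 / deg, deg),
                 tolerance = 1e-12)
  }
  expect_error(extractAttention(mdl0, array(0, c(0, 6, 10))), "empty")
})

test_that("joint loss is the sum of six cross-entropies", {
  lab <- c(1, 0, 1, 1, 0, 0)
  expect_equal(jointLoss(matrix(0, 6, 2), lab), 6 * log(2))
  # margin to the correct class drives the loss to zero
  mk <- function(m) t(vapply(1:6, function(k)
    if (lab[k] == 1) c(-m, m) else c(m, -m), numeric(2)))
  l1 <- jointLoss(mk(1), lab); l5 <- jointLoss(mk(5), lab)
  expect_gt(l1, l5); expect_lt(l5, 1e-3)
  # additivity against per-node manual cross-entropy
  set.seed(33)
  lg <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  labs <- matrix(rbinom(24, 1, 0.5), 4, 6)
  manual <- 0
  for (k in 1:6) {
    p <- exp(lg[, k, ]) / rowSums(exp(lg[, k, ]))
    manual <- manual - mean(log(p[cbind(1:4, labs[, k] + 1)]))
  }
  expect_equal(jointLoss(lg, labs), manual, tolerance = 1e-10)
})

test_that("identity graph without attention reduces to isolated networks", {
  set.seed(34)
  d <- 14
  cfg <- jointConfig(hidden = 9, out = 5, attn_hidden = 6,
                     use_attention = FALSE, seed = 4)
  g <- priorGraph(list())
  p <- jointModelInit(d, cfg)
  X <- array(rnorm(8 * 6 * d), c(8, 6, d))
  fwd <- gatForward(X, g, p, cfg)
  for (i in 1:8) for (k in 1:6) {
    h <- drop(X[i, k, ] %*% p$W)
    gact <- ifelse(h > 0, h, exp(pmin(h, 0)) - 1)
    z <- drop(gact %*% p$Wo) + p$bo
    iso <- drop(z %*% p[[paste0("Wh", k)]]) + p[[paste0("bh", k)]]
    expect_equal(fwd$logits[i, k, ], iso, tolerance = 1e-6)
  }
})

test_that("backpropagation matches finite differences", {
  set.seed(35)
  cfg <- jointConfig(hidden = 6, out = 4, attn_hidden = 5, epochs = 1,
                     seed = 3)
  g <- priorGraph()
  d <- 8; n <- 3
  X <- array(rnorm(n * 6 * d), c(n, 6, d))
  Y <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  p <- jointModelInit(d, cfg)
  fwd <- gatForward(X, g, p, cfg, keep_cache = TRUE)
  gr <- sutureGAT:::gatBackward(Y, fwd, g, p, cfg)
  eps <- 1e-6
  for (nm in c("W", "Wa", "va", "Wo", "Wh3", "ba", "bo", "bva")) {
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      up <- p; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- p; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (jointLoss(gatForward(X, g, up, cfg)$logits, Y) -
              jointLoss(gatForward(X, g, dn, cfg)$logits, Y)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("joint training is seed-reproducible and guards labels", {
  set.seed(36)
  d <- 10; n <- 60
  X <- array(rnorm(n * 6 * d), c(n, 6, d))
  Y <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  cfg <- jointConfig(hidden = 6, out = 4, attn_hidden = 5, epochs = 3,
                     feature_dim = 10, seed = 9)
  m1 <- trainJoint(X, Y, priorGraph(), cfg)
  m2 <- trainJoint(X, Y, priorGraph(), cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params$W, m2$params$W)
  Ybad <- Y; Ybad[, 3] <- 1
  expect_error(trainJoint(X, Ybad, priorGraph(), cfg), "HA")
  expect_error(gatForward(array(0, c(2, 6, d + 1)), priorGraph(),
                          m1$params, cfg), "dimension")
})
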