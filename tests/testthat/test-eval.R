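test_that("leave-one-institution-out folds partition the cohort", {
  sim <- generateCohort(synthConfig(n_institutions = 5,
                                    surgeons_per_institution = 2,
                                    stitches_per_surgeon = 3,
                                    feature_dim = 2,
                                    kinematic_len = c(4L, 5L), seed = 41))
  folds <- loioSplits(sim$cohort)
  expect_length(folds, 5L)
  tested <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tested, seq_len(length(sim$cohort)))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), seq_len(length(sim$cohort)))
    expect_true(all(institutionOf(sim$cohort)[f$test] == f$institution))
  }
  expect_setequal(vapply(folds, `[[`, "", "institution"),
                  institutions(sim$cohort))
  two <- makeTinyCohort()
  expect_length(loioSplits(two), 2L)
  one <- makeTinyCohort()
  one@stitches$institution_id <- "INSTA"
  one@institutions <- "INSTA"
  expect_error(loioSplits(one), "at least two institutions")
})

test_that("AUC follows the midrank pairwise-probability definition", {
  expect_equal(computeAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(computeAUC(c(1, 2, 3, 10, 20, 30), rep(0:1, each = 3)), 1)
  expect_equal(computeAUC(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(computeAUC(1:4, rep(1, 4)), "one class")
  expect_error(computeAUC(1:3, c(0, 1)), "length")

  set.seed(42)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 2)   # coarse grid forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(computeAUC(s, y), bruteForceAUC(s, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (rep in 1:5) {
    s <- rnorm(80); y <- rbinom(80, 1, 0.5)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(computeAUC(s, y), ref, tolerance = 1e-10)
  }
})

test_that("fold summaries report mean and population sd with a MEAN row", {
  one <- list(joint = matrix(0.7, 1, 6,
                             dimnames = list(NULL, subSkillCodes())))
  s1 <- summarizeFolds(one)
  expect_equal(s1$joint_sd, rep(0, 7))
  two <- list(a = matrix(c(0.6, 0.8), 2, 6))
  s2 <- summarizeFolds(two)
  expect_equal(s2$a_mean, rep(0.7, 7))
  expect_equal(s2$a_sd[1], 0.1)   # population convention: sqrt(mean dev^2)
  set.seed(44)
  m <- matrix(runif(30, 0.4, 0.9), 5, 6)
  s3 <- summarizeFolds(list(x = m))
  expect_equal(s3$x_mean[1:6], colMeans(m))
  expect_equal(s3$x_mean[7], mean(colMeans(m)))
  expect_equal(s3$x_sd[3], sqrt(mean((m[, 3] - mean(m[, 3]))^2)))
  expect_error(summarizeFolds(list(a = m, b = m[1:3, ])), "different numbers")
  m2 <- m; m2[2, 2] <- NA
  expect_error(summarizeFolds(list(a = m2)), "missing fold")
})

test_that("PABAK equals twice the observed agreement minus one", {
  expect_equal(pabak(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)
  expect_equal(pabak(c(0, 0, 1, 1), c(0, 1, 1, 0)), 0)
  a <- c(rep(1, 50), rep(0, 50))
  b <- a; b[1:13] <- 1 - b[1:13]   # 87 agreements of 100
  expect_equal(pabak(a, b), 0.74)
  set.seed(45)
  for (rep in 1:20) {
    x <- rbinom(40, 1, 0.5); y <- rbinom(40, 1, 0.3)
    expect_equal(pabak(x, y), 2 * sum(x == y) / 40 - 1)
  }
  expect_error(pabak(c(0, 1), c(1, 1, 0)), "length")
})

test_that("calibration curves bin correctly and match simulated draws", {
  set.seed(46)
  p <- runif(10000)
  y <- rbinom(10000, 1, p)
  cc <- calibrationCurve(p, y, n_bins = 10)
  expect_equal(sum(cc$count), 10000L)
  expect_lt(max(abs(cc$observed - cc$mean_prob)), 0.05)
  one <- calibrationCurve(rep(1, 7), rep(1, 7), n_bins = 5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 7L)
  expect_equal(one$mean_prob, 1)
  expect_equal(one$observed, 1)
  expect_error(calibrationCurve(p, y, n_bins = 0), "n_bins")
})
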