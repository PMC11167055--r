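test_that("identical seeds reproduce the cohort bit for bit", {
  cfg <- fastSynth(seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(labelMatrix(a$cohort), labelMatrix(b$cohort))
  expect_identical(a$features@features, b$features@features)
  expect_identical(kinematicLog(a$cohort, "T00001"),
                   kinematicLog(b$cohort, "T00001"))
  expect_identical(a$truth$stitch_factors, b$truth$stitch_factors)
  c <- generateCohort(fastSynth(seed = 8))
  expect_false(identical(labelMatrix(a$cohort), labelMatrix(c$cohort)))
})

test_that("generated cohorts satisfy every data-model invariant", {
  sim <- generateCohort(fastSynth(seed = 3))
  expect_equal(nrow(validateCohort(sim$cohort)), 0L)
  expect_equal(featureDim(sim$features), 6L)
  expect_setequal(
    featureKeys(sim$features),
    as.vector(outer(stitchTable(sim$cohort)$stitch_id, subSkillCodes(),
                    featureKey)))
})

test_that("rho = 0, beta = 0 gives independent sub-skill labels", {
  # one stitch per surgeon so stitches are independent draws
  cfg <- synthConfig(n_institutions = 2, surgeons_per_institution = 1000,
                     stitches_per_surgeon = 1, feature_dim = 2,
                     kinematic_len = c(4L, 5L), edge_corr = 0,
                     cross_signal = 0, seed = 21)
  lab <- labelMatrix(generateCohort(cfg)$cohort)   # 2000 stitches
  for (a in 1:5) for (b in (a + 1):6) {
    expect_lt(abs(cor(lab[, a], lab[, b])), 0.1)
  }
})

test_that("edge correlation induces the orthant-probability phi on HR-HA", {
  # closed-form oracle: for jointly normal thresholded-at-zero latents with
  # correlation r, phi = 2 asin(r) / pi
  # correlation planted on the single HR-HA edge; independent stitches
  cfg <- synthConfig(n_institutions = 2, surgeons_per_institution = 1000,
                     stitches_per_surgeon = 1, feature_dim = 2,
                     kinematic_len = c(4L, 5L), edge_corr = 0.8,
                     pairs = list(c("HR", "HA")),
                     cross_signal = 0, own_signal = 1, noise_sd = 0.5,
                     stitch_sd = 0.5, seed = 22)
  lab <- labelMatrix(generateCohort(cfg)$cohort)
  # latent of label k: z_k + stitch noise + threshold noise
  r_eff <- 0.8 / (1 + 0.5^2 + 0.5^2)
  phi_expect <- 2 * asin(r_eff) / pi
  phi_obs <- cor(lab[, "HR"], lab[, "HA"])
  expect_gt(phi_obs, 0.1)            # significantly positive at n = 2000
  expect_lt(abs(phi_obs - phi_expect), 0.08)
  # non-edge pair stays near zero
  expect_lt(abs(cor(lab[, "RP"], lab[, "WRnw"])), 0.1)
})

test_that("kinematic streams have unit quaternions and configured lengths", {
  set.seed(5)
  cfg <- fastSynth()
  kin <- generateKinematics(numeric(6), cfg)
  qcols <- grep("_q", names(kin$log), value = TRUE)
  for (i in seq(1, length(qcols), by = 4)) {
    q <- as.matrix(kin$log[, qcols[i:(i + 3)]])
    expect_equal(rowSums(q^2), rep(1, nrow(q)), tolerance = 1e-9)
  }
  lens <- lengths(kin$clips)
  expect_true(all(lens >= 4 & lens <= 8))
  expect_equal(sum(lens), nrow(kin$log))
  # fixed length distribution: exactly 24 frames per phase
  cfg24 <- synthConfig(kinematic_len = c(24L, 24L))
  set.seed(9)
  kin24 <- generateKinematics(numeric(6), cfg24)
  expect_true(all(lengths(kin24$clips) == 24L))
  # determinism under a fixed RNG state
  set.seed(11); k1 <- generateKinematics(1:6 / 6, cfg)
  set.seed(11); k2 <- generateKinematics(1:6 / 6, cfg)
  expect_identical(k1, k2)
})

test_that("edge correlation beyond the graph-compatible range is rejected", {
  # with three edges meeting at HA, rho must stay below 1/sqrt(3)
  expect_error(synthConfig(edge_corr = 0.7), "positive-definite")
  expect_silent(synthConfig(edge_corr = 0.7, pairs = list(c("HR", "HA"))))
})

test_that("outcome tables follow the configured logistic model", {
  cfg <- synthConfig(n_institutions = 2, surgeons_per_institution = 5,
                     stitches_per_surgeon = 4, feature_dim = 2,
                     kinematic_len = c(4L, 5L), cases_per_surgeon = 100,
                     outcome_alpha = c(RP = 0, HR = 0, HA = 0, DS = 0,
                                       WR = 0, WRnw = 0),
                     covariate_coefs = c(age = 0, bmi = 0, psa = 0,
                                         prostate_volume = 0),
                     outcome_alpha0 = 1, seed = 31)
  sim <- generateCohort(cfg)
  out <- generateOutcomes(sim$cohort, sim$truth, cfg)   # 1000 cases
  p0 <- 1 / (1 + exp(-1))
  rate <- mean(out$continence_3mo)
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / nrow(out)))
  # determinism
  out2 <- generateOutcomes(sim$cohort, sim$truth, cfg)
  expect_identical(out, out2)
})

test_that("a planted positive skill effect is recovered as an OR above 1", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- synthConfig(n_institutions = 2, surgeons_per_institution = 12,
                       stitches_per_surgeon = 10, feature_dim = 2,
                       kinematic_len = c(4L, 5L), cases_per_surgeon = 30,
                       outcome_alpha = c(RP = 3, HR = 0, HA = 0, DS = 0,
                                         WR = 0, WRnw = 0),
                       seed = 100 + seed)
    sim <- generateCohort(cfg)
    out <- generateOutcomes(sim$cohort, sim$truth, cfg)
    row <- fitUnivariable(out$score_RP, out$continence_3mo, "RP")
    hits <- hits + (row$rate_ratio > 1)
  }
  expect_gte(hits, 4L)
})
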