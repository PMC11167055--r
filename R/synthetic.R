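# Multi-institution synthetic cohort generator. Surgeon abilities are
# multivariate normal with correlation placed exactly on the prior-graph
# edges; stitch-level realized factors add noise around the surgeon's
# ability; binary sub-skill labels threshold a linear combination of the
# stitch's own factor and its prior-graph neighbors' factors, so
# cross-sub-skill dependence follows the graph by construction. Per-sub-skill
# feature vectors encode the stitch's own factor along a fixed direction
# (plus an institution shift and noise), so neighbor features are informative
# about a target label exactly when the cross signal is planted. Kinematic
# streams are smooth random walks whose roughness within each sub-phase
# tracks that sub-skill's factor, making the kinematic block weakly
# informative too.

#' Synthetic-cohort configuration
#'
#' @param n_institutions number of institutions (default 5).
#' @param surgeons_per_institution surgeons nested per institution (default 8).
#' @param stitches_per_surgeon stitches per surgeon (default 25).
#' @param feature_dim per-sub-skill feature dimension (default 128).
#' @param edge_corr rho in [0, 1): latent ability correlation on prior-graph
#'   edges (default 0.3); the implied covariance must be positive definite.
#' @param cross_signal beta >= 0: strength with which neighbor factors drive
#'   a target sub-skill's label (default 0.5).
#' @param own_signal gamma >= 0: strength of the own factor in the label and
#'   the norm of the feature direction (default 1).
#' @param noise_sd sigma > 0: standard deviation of both the label threshold
#'   noise and the feature noise (default 0.5).
#' @param stitch_sd stitch-level factor noise around the surgeon ability
#'   (default 0.5).
#' @param institution_scale_jitter scale of the per-institution affine
#'   feature shift and of the lognormal jitter on beta (default 0.2).
#' @param prevalence_shift threshold shift; 0 gives roughly balanced labels.
#' @param kinematic_len integer range (min, max) of per-sub-phase frame
#'   counts (default 16..40, straddling the 24-frame alignment target).
#' @param kin_signal kappa: roughness-vs-factor coupling of the kinematic
#'   walk (default 0.5).
#' @param cross_weights optional named per-edge multipliers on the cross
#'   signal, names like \code{"HA-WR"} (sorted codes joined by "-").
#' @param pairs prior edge list (default \code{\link{defaultPriorPairs}}).
#' @param cases_per_surgeon outcome-table cases per surgeon (default 10).
#' @param outcome_alpha0 intercept of the outcome logit (default 1).
#' @param outcome_alpha named length-6 coefficient vector on centered
#'   per-surgeon skill scores.
#' @param covariate_coefs named coefficients for centered age, bmi, psa,
#'   prostate_volume.
#' @param seed integer master seed.
#' @return a validated \code{synthConfig} list.
#' @export
synthConfig <- function(n_institutions = 5L, surgeons_per_institution = 8L,
                        stitches_per_surgeon = 25L, feature_dim = 128L,
                        edge_corr = 0.3, cross_signal = 0.5, own_signal = 1,
                        noise_sd = 0.5, stitch_sd = 0.5,
                        institution_scale_jitter = 0.2, prevalence_shift = 0,
                        kinematic_len = c(16L, 40L), kin_signal = 0.5,
                        cross_weights = NULL, pairs = defaultPriorPairs(),
                        cases_per_surgeon = 10L, outcome_alpha0 = 1,
                        outcome_alpha = c(RP = 1, HR = 0, HA = 0, DS = 0.8,
                                          WR = 0, WRnw = 0.6),
                        covariate_coefs = c(age = -0.03, bmi = -0.03,
                                            psa = -0.02,
                                            prostate_volume = -0.01),
                        seed = 1L) {
  stopifnot(n_institutions >= 1, surgeons_per_institution >= 1,
            stitches_per_surgeon >= 1, feature_dim >= 1,
            edge_corr >= 0, edge_corr < 1, cross_signal >= 0, own_signal >= 0,
            noise_sd > 0, length(kinematic_len) == 2L,
            kinematic_len[1L] >= 2L, cases_per_surgeon >= 1)
  cfg <- structure(as.list(environment()), class = "synthConfig")
  cfg$graph <- priorGraph(pairs)
  # implied latent covariance must be positive definite
  S <- latentCovariance(cfg)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("edge_corr = ", edge_corr,
         " makes the implied latent covariance non-positive-definite",
         call. = FALSE)
  cfg
}

latentCovariance <- function(config) {
  S <- diag(6)
  A <- adjacency(config$graph)
  S[A == 1] <- config$edge_corr
  diag(S) <- 1
  dimnames(S) <- dimnames(A)
  S
}

edgeWeightMatrix <- function(config) {
  A <- adjacency(config$graph)
  W <- A
  diag(W) <- 0
  if (!is.null(config$cross_weights)) {
    codes <- subSkillCodes()
    for (nm in names(config$cross_weights)) {
      p <- strsplit(nm, "-", fixed = TRUE)[[1]]
      checkSubSkillCodes(p)
      W[p[1L], p[2L]] <- W[p[1L], p[2L]] * config$cross_weights[[nm]]
      W[p[2L], p[1L]] <- W[p[2L], p[1L]] * config$cross_weights[[nm]]
    }
  }
  W
}

#' Generate a synthetic kinematic stream for one stitch
#'
#' Six contiguous sub-phase spans; within each span the 10 pose positions
#' follow a random walk whose step size shrinks with the sub-skill's latent
#' factor, orientations are unit-normalized smooth walks on the quaternion
#' sphere, and a slowly drifting camera pose is included. Uses the current
#' RNG state; fix the seed for an identical stream.
#'
#' @param factors length-6 latent factors of the stitch (0 = average skill).
#' @param config a \code{\link{synthConfig}}.
#' @return list: \code{log} (kinematic-log data.frame), \code{clips} (named
#'   list of 0-based frame-id vectors, one contiguous span per sub-skill).
#' @export
generateKinematics <- function(factors = numeric(6), config = synthConfig()) {
  rng <- seq.int(config$kinematic_len[1L], config$kinematic_len[2L])
  lens <- rng[sample.int(length(rng), 6L, replace = TRUE)]
  T <- sum(lens)
  phase <- rep(seq_len(6L), lens)
  sdvec <- 0.05 * exp(-config$kin_signal * factors)[phase]
  smoothQuatWalk <- function(T, start = NULL) {
    q0 <- if (is.null(start)) stats::rnorm(4L) else start
    q <- matrix(q0, T, 4L, byrow = TRUE) +
      apply(matrix(stats::rnorm(T * 4L, sd = 0.05), T, 4L), 2L, cumsum)
    quatNormalizeRows(q)
  }
  log <- data.frame(frame_id = 0:(T - 1L))
  for (i in seq_len(N_POSES)) {
    steps <- matrix(stats::rnorm(T * 3L), T, 3L) * sdvec
    pos <- apply(steps, 2L, cumsum) +
      matrix(stats::rnorm(3L, sd = 0.5), T, 3L, byrow = TRUE)
    q <- smoothQuatWalk(T)
    log[paste0("p", i, "_", c("x", "y", "z"))] <- pos
    log[paste0("p", i, "_", c("qw", "qx", "qy", "qz"))] <- q
  }
  campos <- apply(matrix(stats::rnorm(T * 3L, sd = 0.01), T, 3L), 2L, cumsum) +
    matrix(c(0, 0, 2), T, 3L, byrow = TRUE)
  camq <- smoothQuatWalk(T, start = c(1, 0, 0, 0) * 20)
  log[paste0("cam_", c("x", "y", "z"))] <- campos
  log[paste0("cam_", c("qw", "qx", "qy", "qz"))] <- camq
  ends <- cumsum(lens)
  starts <- c(0L, ends[-6L])
  clips <- lapply(seq_len(6L), function(k) seq(starts[k], ends[k] - 1L))
  names(clips) <- subSkillCodes()
  list(log = log, clips = clips)
}

#' Generate a full synthetic cohort
#'
#' @param config a \code{\link{synthConfig}}.
#' @return list: \code{cohort} (validated \code{SutureCohort}),
#'   \code{features} (\code{FeatureStore}, encoder \code{"synthetic"}),
#'   \code{truth} (latent ground truth: per-surgeon abilities, per-stitch
#'   factors, per-institution beta and feature shifts, feature directions).
#' @export
generateCohort <- function(config = synthConfig()) {
  set.seed(substreamSeed(config$seed, "synthetic_cohort"))
  codes <- subSkillCodes()
  R <- chol(latentCovariance(config))
  EW <- edgeWeightMatrix(config)
  insts <- sprintf("INST%d", seq_len(config$n_institutions))
  inst_shift <- lapply(insts, function(i)
    stats::rnorm(config$feature_dim, sd = config$institution_scale_jitter))
  names(inst_shift) <- insts
  beta_inst <- config$cross_signal *
    exp(stats::rnorm(length(insts), sd = config$institution_scale_jitter))
  names(beta_inst) <- insts
  # fixed feature directions, norm = own_signal
  Wdir <- vapply(seq_len(6L), function(k) {
    v <- stats::rnorm(config$feature_dim)
    v / sqrt(sum(v^2)) * config$own_signal
  }, numeric(config$feature_dim))
  n <- config$n_institutions * config$surgeons_per_institution *
    config$stitches_per_surgeon
  stitch_ids <- sprintf("T%05d", seq_len(n))
  rows <- vector("list", n)
  clips <- vector("list", n)
  kins <- vector("list", n)
  feats <- matrix(0, n * 6L, config$feature_dim)
  fkeys <- character(n * 6L)
  Smat <- matrix(0, n, 6L, dimnames = list(stitch_ids, codes))
  surgeon_z <- list()
  r <- 0L
  for (inst in insts) {
    for (sg in seq_len(config$surgeons_per_institution)) {
      sid <- sprintf("%s_S%02d", inst, sg)
      z <- drop(crossprod(R, stats::rnorm(6L)))
      surgeon_z[[sid]] <- stats::setNames(z, codes)
      for (stt in seq_len(config$stitches_per_surgeon)) {
        r <- r + 1L
        id <- stitch_ids[r]
        s <- z + stats::rnorm(6L, sd = config$stitch_sd)
        Smat[r, ] <- s
        lin <- config$own_signal * s + beta_inst[inst] * drop(EW %*% s) +
          stats::rnorm(6L, sd = config$noise_sd)
        y <- as.integer(lin > config$prevalence_shift)
        lab <- as.list(y)
        names(lab) <- labelColumns()
        rows[[r]] <- data.frame(stitch_id = id, surgeon_id = sid,
                                institution_id = inst, lab,
                                stringsAsFactors = FALSE)
        kin <- generateKinematics(s, config)
        clips[[r]] <- kin$clips
        kins[[r]] <- kin$log
        for (k in seq_len(6L)) {
          fr <- (r - 1L) * 6L + k
          feats[fr, ] <- s[k] * Wdir[, k] + inst_shift[[inst]] +
            stats::rnorm(config$feature_dim, sd = config$noise_sd)
          fkeys[fr] <- featureKey(id, codes[k])
        }
      }
    }
  }
  st <- do.call(rbind, rows)
  names(clips) <- stitch_ids
  names(kins) <- stitch_ids
  rownames(feats) <- fkeys
  cohort <- sutureCohort(st, clips, kins, insts)
  truth <- list(surgeon_z = surgeon_z, stitch_factors = Smat,
                beta_inst = beta_inst, inst_shift = inst_shift,
                feature_dirs = Wdir, edge_weights = EW,
                config = config)
  list(cohort = cohort, features = featureStore(feats, "synthetic"),
       truth = truth)
}

#' Generate a synthetic patient-outcome table
#'
#' One block of cases per surgeon with chart-review covariates (age, BMI,
#' PSA, prostate volume) and a binary 3-month continence recovery outcome
#' whose logit is the configured intercept plus coefficients on the
#' surgeon's centered per-domain skill scores (empirical ideal-label
#' proportions from the cohort) plus centered covariate terms. The
#' generating coefficients are attached as attribute \code{coefficients}.
#'
#' @param cohort a \code{SutureCohort}.
#' @param truth latent truth from \code{\link{generateCohort}} (reserved for
#'   score definitions; the default uses observed label proportions).
#' @param config a \code{\link{synthConfig}}.
#' @return data.frame: \code{surgeon_id}, \code{age}, \code{bmi}, \code{psa},
#'   \code{prostate_volume}, \code{continence_3mo}, \code{score_RP} ...
#'   \code{score_WRnw}.
#' @export
generateOutcomes <- function(cohort, truth, config = synthConfig()) {
  set.seed(substreamSeed(config$seed, "outcomes"))
  lab <- labelMatrix(cohort)
  sid <- stitchTable(cohort)$surgeon_id
  surgeons <- unique(sid)
  score <- vapply(subSkillCodes(), function(k)
    as.numeric(tapply(lab[, k], sid, mean)[surgeons]), numeric(length(surgeons)))
  nc <- length(surgeons) * config$cases_per_surgeon
  who <- rep(seq_along(surgeons), each = config$cases_per_surgeon)
  age <- stats::rnorm(nc, 64, 7)
  bmi <- stats::rnorm(nc, 27.5, 4)
  psa <- exp(stats::rnorm(nc, log(7), 0.5))
  vol <- pmax(stats::rnorm(nc, 45, 12), 10)
  a <- config$outcome_alpha[subSkillCodes()]
  cv <- config$covariate_coefs
  logit <- config$outcome_alpha0 +
    drop((score[who, , drop = FALSE] - 0.5) %*% a) +
    cv[["age"]] * (age - 64) + cv[["bmi"]] * (bmi - 27.5) +
    cv[["psa"]] * (psa - 8) + cv[["prostate_volume"]] * (vol - 45)
  p <- 1 / (1 + exp(-logit))
  out <- data.frame(surgeon_id = surgeons[who], age = age, bmi = bmi,
                    psa = psa, prostate_volume = vol,
                    continence_3mo = stats::rbinom(nc, 1L, p),
                    stringsAsFactors = FALSE)
  sc <- as.data.frame(score[who, , drop = FALSE])
  names(sc) <- paste0("score_", subSkillCodes())
  out <- cbind(out, sc)
  attr(out, "coefficients") <- list(alpha0 = config$outcome_alpha0,
                                    alpha = a, covariates = cv)
  out
}
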