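# Leave-one-institution-out evaluation: fold construction, AUC, summary
# tables across ablation arms, inter-rater PABAK and calibration curves.

#' Leave-one-institution-out splits
#'
#' One fold per institution: the fold's test set is every stitch from that
#' institution, its training set everything else. Test sets partition the
#' cohort.
#'
#' @param cohort a \code{SutureCohort} with at least two institutions.
#' @return list of folds, each \code{list(institution, train, test)} with
#'   integer stitch indices.
#' @export
loioSplits <- function(cohort) {
  inst <- institutions(cohort)
  if (length(inst) < 2L)
    stop("leave-one-institution-out needs at least two institutions",
         call. = FALSE)
  of <- institutionOf(cohort)
  lapply(inst, function(i) {
    test <- which(of == i)
    list(institution = i, train = setdiff(seq_along(of), test), test = test)
  })
}

#' Area under the ROC curve (midrank / Mann-Whitney form)
#'
#' Equals the probability that a random positive scores above a random
#' negative, counting ties as one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive); both classes required.
#' @return AUC in [0, 1].
#' @export
computeAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: only one class present", call. = FALSE)
  r <- rank(scores)   # midranks for ties
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Summarize fold AUCs across arms
#'
#' @param fold_aucs named list, one element per arm, each a folds x 6 matrix
#'   of AUCs (columns \code{subSkillCodes()}); all arms must cover the same
#'   folds.
#' @param na.rm drop undefined fold AUCs (single-class held-out sets) from
#'   the means; with the default FALSE a missing fold is an error.
#' @return data.frame with one row per sub-skill plus a MEAN row (arithmetic
#'   mean over the six sub-skills), and per arm columns \code{<arm>_mean}
#'   and \code{<arm>_sd} (population standard deviation across folds).
#' @export
summarizeFolds <- function(fold_aucs, na.rm = FALSE) {
  nf <- unique(vapply(fold_aucs, nrow, integer(1)))
  if (length(nf) != 1L)
    stop("arms cover different numbers of folds", call. = FALSE)
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- data.frame(subskill = c(subSkillCodes(), "MEAN"),
                    stringsAsFactors = FALSE)
  for (arm in names(fold_aucs)) {
    m <- fold_aucs[[arm]]
    if (!na.rm && any(!is.finite(m)))
      stop("arm ", arm, " has missing fold results", call. = FALSE)
    permean <- apply(m, 2L, mean, na.rm = TRUE)
    persd <- apply(m, 2L, function(x) popSd(x[is.finite(x)]))
    meanrow <- rowMeans(m, na.rm = TRUE)   # per-fold mean over sub-skills
    out[[paste0(arm, "_mean")]] <- c(permean, mean(permean))
    out[[paste0(arm, "_sd")]] <- c(persd, popSd(meanrow))
  }
  out
}

#' Prevalence-adjusted bias-adjusted kappa for binary ratings
#'
#' PABAK = 2 p_o - 1, with p_o the observed agreement proportion.
#'
#' @param ratings_a,ratings_b equal-length binary rating vectors.
#' @return PABAK in [-1, 1].
#' @export
pabak <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors differ in length", call. = FALSE)
  stopifnot(all(ratings_a %in% c(0, 1)), all(ratings_b %in% c(0, 1)))
  2 * mean(ratings_a == ratings_b) - 1
}

#' Reliability (calibration) curve over equal-width probability bins
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels binary outcomes.
#' @param n_bins number of equal-width bins over [0, 1] (default 10).
#' @return data.frame with one row per nonempty bin: \code{mean_prob},
#'   \code{observed}, \code{count}; counts sum to \code{length(probs)}.
#' @export
calibrationCurve <- function(probs, labels, n_bins = 10L) {
  if (n_bins < 1L) stop("n_bins must be at least 1", call. = FALSE)
  stopifnot(all(probs >= 0 & probs <= 1))
  bin <- pmin(floor(probs * n_bins) + 1L, n_bins)
  rows <- lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(mean_prob = mean(probs[i]), observed = mean(labels[i]),
               count = sum(i))
  })
  do.call(rbind, rows)
}

#' Run the four-arm leave-one-institution-out experiment
#'
#' For each fold trains the independent arm (per-sub-skill stage-1 models on
#' the stored clip features) and the requested joint arms (full, without
#' attention, without kinematics), then scores the held-out institution.
#'
#' @param cohort a \code{SutureCohort}.
#' @param store a \code{FeatureStore} covering the cohort.
#' @param graph a \code{\link{priorGraph}}.
#' @param arms subset of \code{c("independent", "joint", "no_attention",
#'   "no_kinematics")}.
#' @param joint_config base \code{\link{jointConfig}} for the joint arms.
#' @param stage1_config \code{\link{stage1Config}} for the independent arm.
#' @param target_len aligned kinematic length.
#' @param folds optional subset of folds (indices into
#'   \code{\link{loioSplits}}); default all.
#' @return list: \code{fold_aucs} (per arm: folds x 6 AUC matrix),
#'   \code{summary} (from \code{\link{summarizeFolds}}), \code{attention}
#'   (per fold, dataset-averaged 6 x 6 map from the full joint arm, when
#'   trained), \code{predictions} (per arm: n x 6 out-of-fold probability
#'   matrix), \code{folds}.
#' @export
runLOIO <- function(cohort, store, graph = priorGraph(),
                    arms = c("independent", "joint", "no_attention",
                             "no_kinematics"),
                    joint_config = jointConfig(),
                    stage1_config = stage1Config(),
                    target_len = 24L, folds = NULL) {
  arms <- match.arg(arms, several.ok = TRUE,
                    c("independent", "joint", "no_attention", "no_kinematics"))
  allfolds <- loioSplits(cohort)
  if (!is.null(folds)) allfolds <- allfolds[folds]
  lab <- labelMatrix(cohort)
  n <- nrow(lab)
  codes <- subSkillCodes()
  need_kin <- any(arms %in% c("joint", "no_attention"))
  kin <- if (need_kin) cohortKinematics(cohort, target_len) else NULL
  # feature matrix per sub-skill for the independent arm
  fmat <- lapply(codes, function(k) {
    t(vapply(stitchTable(cohort)$stitch_id,
             function(id) getFeature(store, id, k),
             numeric(featureDim(store))))
  })
  names(fmat) <- codes
  armCfg <- function(arm) {
    cfg <- joint_config
    if (arm == "no_attention") cfg$use_attention <- FALSE
    if (arm == "no_kinematics") cfg$use_kinematics <- FALSE
    cfg
  }
  fold_aucs <- lapply(arms, function(a)
    matrix(NA_real_, length(allfolds), 6L, dimnames = list(NULL, codes)))
  names(fold_aucs) <- arms
  preds <- lapply(arms, function(a) matrix(NA_real_, n, 6L,
                                           dimnames = list(rownames(lab), codes)))
  names(preds) <- arms
  attention <- list()
  inputs_kin <- if (need_kin)
    buildNodeInputs(cohort, store, kin, target_len, TRUE) else NULL
  inputs_nokin <- if ("no_kinematics" %in% arms)
    buildNodeInputs(cohort, store, kin, target_len, FALSE) else NULL
  for (f in seq_along(allfolds)) {
    fold <- allfolds[[f]]
    tr <- fold$train; te <- fold$test
    for (arm in arms) {
      if (arm == "independent") {
        for (ki in seq_along(codes)) {
          m <- trainStage1(fmat[[ki]][tr, , drop = FALSE], lab[tr, ki],
                           stage1_config)
          p <- predictIndependent(m, fmat[[ki]][te, , drop = FALSE])
          preds[[arm]][te, ki] <- p
          fold_aucs[[arm]][f, ki] <- foldAUC(p, lab[te, ki])
        }
      } else {
        inp <- if (arm == "no_kinematics") inputs_nokin else inputs_kin
        mdl <- trainJoint(inp[tr, , , drop = FALSE],
                          lab[tr, , drop = FALSE], graph, armCfg(arm))
        fw <- predictJoint(mdl, inp[te, , , drop = FALSE])
        preds[[arm]][te, ] <- fw$prob
        for (ki in seq_along(codes))
          fold_aucs[[arm]][f, ki] <- foldAUC(fw$prob[, ki], lab[te, ki])
        if (arm == "joint")
          attention[[fold$institution]] <-
            extractAttention(mdl, inp[te, , , drop = FALSE])
      }
    }
  }
  list(fold_aucs = fold_aucs,
       summary = summarizeFolds(fold_aucs, na.rm = TRUE),
       attention = attention, predictions = preds, folds = allfolds)
}

# AUC for a held-out fold; NA when the fold has a single class
foldAUC <- function(scores, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  computeAUC(scores, labels)
}
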