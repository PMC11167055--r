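# End-to-end experiment driver: simulate -> stage-1 features -> kinematic
# prep -> joint training over leave-one-institution-out folds for all four
# arms -> summary tables, attention maps, and (optionally) the skill-outcome
# association, all under one master seed. Every run writes a manifest with
# the config hash and seed so it can be reproduced exactly.

#' Seed every stochastic component
#'
#' All randomness in the package derives from one master seed through named
#' substreams (\code{substream}), so different stages draw from different
#' but reproducible streams.
#'
#' @param seed integer master seed; when NULL one is drawn and reported.
#' @param substream optional stream name mixed into the seed.
#' @return the (possibly drawn) master seed, invisibly.
#' @export
seedEverything <- function(seed = NULL, substream = "global") {
  if (is.null(seed)) {
    seed <- as.integer(sample.int(2147483646L, 1L))
    message("seedEverything: drew master seed ", seed)
  }
  set.seed(substreamSeed(as.integer(seed), substream))
  invisible(as.integer(seed))
}

# 32-bit FNV-1a over a string, hex-encoded; used to fingerprint configs
configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Experiment configuration
#'
#' Nested per-stage sections; unknown keys (top-level or per-section) are
#' rejected before any compute. Can be read from a YAML file.
#'
#' @param synth arguments for \code{\link{synthConfig}} (without seed).
#' @param stage1 arguments for \code{\link{stage1Config}} (without seed).
#' @param joint arguments for \code{\link{jointConfig}} (without seed).
#' @param arms evaluation arms for \code{\link{runLOIO}}.
#' @param target_len aligned kinematic length (default 24).
#' @param outcomes logical: generate and associate the outcome table.
#' @param seed master seed.
#' @param output_dir where \code{\link{runExperiment}} writes reports.
#' @return a validated \code{runConfig} list.
#' @export
runConfig <- function(synth = list(), stage1 = list(), joint = list(),
                      arms = c("independent", "joint", "no_attention",
                               "no_kinematics"),
                      target_len = 24L, outcomes = TRUE, seed = 1L,
                      output_dir = tempfile("sutureGAT_run_")) {
  checkKeys <- function(given, fn, what) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad) > 0L)
      stop("unknown ", what, " config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  checkKeys(synth, synthConfig, "synth")
  checkKeys(stage1, stage1Config, "stage1")
  checkKeys(joint, jointConfig, "joint")
  arms <- match.arg(arms, several.ok = TRUE,
                    c("independent", "joint", "no_attention", "no_kinematics"))
  structure(list(synth = synth, stage1 = stage1, joint = joint, arms = arms,
                 target_len = as.integer(target_len), outcomes = outcomes,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "runConfig")
}

#' @rdname runConfig
#' @param path YAML file with the same nested sections.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(runConfig, y)
}

#' Run the full synthetic experiment end to end
#'
#' Generates a cohort, runs the leave-one-institution-out evaluation for the
#' requested arms, writes the summary table, per-fold AUCs, per-institution
#' attention maps (6 x 6 CSVs, rows and columns ordered RP, HR, HA, DS, WR,
#' WRnw), the metrics JSON, and, when outcomes are enabled, the
#' association tables and ROC points computed from out-of-fold predicted
#' skill probabilities aggregated per surgeon. A \code{manifest.json}
#' records the config hash and seed for exact rerun. On a stage failure a
#' \code{FAILED} marker naming the stage and cause is left in the output
#' directory and the error is rethrown.
#'
#' @param config a \code{\link{runConfig}} (or YAML path).
#' @return list: \code{summary}, \code{fold_aucs}, \code{attention},
#'   \code{association} (or NULL), \code{metrics}, \code{output_dir}.
#' @export
runExperiment <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  # the hash fingerprints the scientific configuration, not where it is written
  hash <- configHash(unclass(config)[setdiff(names(config), "output_dir")])
  stage <- "setup"
  res <- tryCatch({
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed),
      file.path(config$output_dir, "manifest.json"), auto_unbox = TRUE)
    stage <- "simulate"
    scfg <- do.call(synthConfig, c(config$synth, list(seed = config$seed)))
    sim <- generateCohort(scfg)
    stage <- "evaluate"
    s1 <- do.call(stage1Config, c(config$stage1, list(seed = config$seed)))
    jc <- do.call(jointConfig, c(config$joint, list(seed = config$seed)))
    ev <- runLOIO(sim$cohort, sim$features, scfg$graph, arms = config$arms,
                  joint_config = jc, stage1_config = s1,
                  target_len = config$target_len)
    utils::write.csv(ev$summary, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    for (arm in names(ev$fold_aucs))
      utils::write.csv(ev$fold_aucs[[arm]],
                       file.path(config$output_dir,
                                 paste0("fold_auc_", arm, ".csv")),
                       row.names = FALSE)
    for (inst in names(ev$attention))
      utils::write.csv(ev$attention[[inst]],
                       file.path(config$output_dir,
                                 paste0("attention_", inst, ".csv")))
    assoc <- NULL
    if (isTRUE(config$outcomes)) {
      stage <- "associate"
      outcome_tab <- generateOutcomes(sim$cohort, sim$truth, scfg)
      parm <- intersect(c("joint", "independent"), config$arms)[1L]
      tab <- if (!is.na(parm))
        attachSkillScores(outcome_tab, sim$cohort,
                          ev$predictions[[parm]], mean)
      else outcome_tab
      uni <- do.call(rbind, lapply(subSkillCodes(), function(k)
        fitUnivariable(tab[[paste0("score_", k)]], tab$continence_3mo, k)))
      multi <- fitMultivariable(
        as.matrix(tab[, paste0("score_", subSkillCodes())]),
        tab[, c("age", "bmi", "psa", "prostate_volume")],
        tab$continence_3mo)
      roc <- rocFromPredictions(multi$predicted, tab$continence_3mo)
      utils::write.csv(uni, file.path(config$output_dir, "association_univariable.csv"),
                       row.names = FALSE)
      utils::write.csv(multi$rows,
                       file.path(config$output_dir, "association_multivariable.csv"),
                       row.names = FALSE)
      utils::write.csv(roc$curve, file.path(config$output_dir, "roc_points.csv"),
                       row.names = FALSE)
      assoc <- list(univariable = uni, multivariable = multi$rows,
                    roc_auc = roc$auc)
    }
    stage <- "report"
    metrics <- list(
      config_hash = hash, seed = config$seed,
      mean_auc = as.list(stats::setNames(
        ev$summary[ev$summary$subskill == "MEAN",
                   grep("_mean$", names(ev$summary))],
        sub("_mean$", "", grep("_mean$", names(ev$summary), value = TRUE)))),
      outcome_auc = if (!is.null(assoc)) assoc$roc_auc else NULL)
    jsonlite::write_json(metrics, file.path(config$output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(summary = ev$summary, fold_aucs = ev$fold_aucs,
         attention = ev$attention, association = assoc, metrics = metrics,
         output_dir = config$output_dir)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$output_dir, "FAILED"))
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
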