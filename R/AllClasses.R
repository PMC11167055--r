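#' @import methods
NULL

# column schema of a kinematic log: frame_id, 70 pose scalars, 7 camera scalars
kinColumns <- function() {
  pose <- as.vector(vapply(seq_len(N_POSES), function(i) {
    paste0("p", i, "_", c("x", "y", "z", "qw", "qx", "qy", "qz"))
  }, character(POSE_SCALARS)))
  c("frame_id", pose, paste0("cam_", c("x", "y", "z", "qw", "qx", "qy", "qz")))
}

poseColumnIndex <- function() {
  # list per pose: columns of the 70-wide block (excluding frame_id/camera)
  lapply(seq_len(N_POSES), function(i) (i - 1L) * POSE_SCALARS + seq_len(POSE_SCALARS))
}

#' SutureCohort: stitches, labels, clips and kinematic logs
#'
#' A cohort is the unit every stage of the pipeline consumes: one row per
#' stitch carrying surgeon and institution ids and the six binary sub-skill
#' labels (1 = ideal performance, 0 = non-ideal), plus, per stitch, the six
#' sub-phase clips (ordered frame-id lists that index into the stitch's
#' kinematic log by the \code{frame_id} column) and one kinematic log
#' (per frame: 10 tracked poses of 3 position + 4 quaternion scalars, and a
#' camera pose).
#'
#' @slot stitches data.frame with columns \code{stitch_id}, \code{surgeon_id},
#'   \code{institution_id} and \code{label_RP} ... \code{label_WRnw}.
#' @slot clips named list (by stitch id) of named lists (by sub-skill code) of
#'   strictly increasing integer frame-id vectors; each clip entry may carry a
#'   \code{media_path} attribute pointing at raw frame arrays (optional — the
#'   pipeline runs from precomputed features when absent).
#' @slot kinematics named list (by stitch id) of kinematic-log data.frames
#'   with the \code{kinColumns()} schema.
#' @slot institutions character vector of institution ids.
#' @export
setClass("SutureCohort",
  representation(stitches = "data.frame", clips = "list",
                 kinematics = "list", institutions = "character"))

setValidity("SutureCohort", function(object) {
  rep <- validateCohort(object)
  if (nrow(rep) == 0L) return(TRUE)
  msgs <- utils::head(paste0(rep$stitch_id, ": ", rep$message), 5L)
  paste0(nrow(rep), " invariant violation(s), e.g. ",
         paste(msgs, collapse = "; "))
})

#' Construct a SutureCohort
#'
#' @param stitches,clips,kinematics,institutions see the class slots.
#' @param validate run the full invariant check (default TRUE).
#' @return a validated \code{SutureCohort}.
#' @export
sutureCohort <- function(stitches, clips, kinematics, institutions,
                         validate = TRUE) {
  obj <- new("SutureCohort", stitches = stitches, clips = clips,
             kinematics = kinematics, institutions = as.character(institutions))
  if (validate) methods::validObject(obj)
  obj
}

#' @describeIn sutureCohort number of stitches
#' @param x,object a \code{SutureCohort}
#' @export
setMethod("length", "SutureCohort", function(x) nrow(x@stitches))

setMethod("show", "SutureCohort", function(object) {
  st <- object@stitches
  cat("SutureCohort:", nrow(st), "stitches,",
      length(unique(st$surgeon_id)), "surgeons,",
      length(object@institutions), "institutions\n")
  lab <- as.matrix(st[, labelColumns()])
  cat("  ideal-label prevalence:",
      paste(sprintf("%s=%.2f", subSkillCodes(), colMeans(lab)), collapse = " "),
      "\n")
})

#' Accessors for SutureCohort
#'
#' @param cohort a \code{SutureCohort}.
#' @param stitch_id a stitch identifier.
#' @param subskill a sub-skill code.
#' @return \code{stitchTable}: the stitch-level data.frame; \code{labelMatrix}:
#'   n x 6 binary matrix; \code{institutionOf}: institution per stitch;
#'   \code{clipFrames}: the clip's frame ids; \code{kinematicLog}: the
#'   stitch's kinematic log.
#' @export
stitchTable <- function(cohort) cohort@stitches

#' @rdname stitchTable
#' @export
labelMatrix <- function(cohort) {
  m <- as.matrix(cohort@stitches[, labelColumns()])
  colnames(m) <- subSkillCodes()
  rownames(m) <- cohort@stitches$stitch_id
  m
}

#' @rdname stitchTable
#' @export
institutions <- function(cohort) cohort@institutions

#' @rdname stitchTable
#' @export
institutionOf <- function(cohort) cohort@stitches$institution_id

#' @rdname stitchTable
#' @export
clipFrames <- function(cohort, stitch_id, subskill) {
  cohort@clips[[as.character(stitch_id)]][[subskill]]
}

#' @rdname stitchTable
#' @export
kinematicLog <- function(cohort, stitch_id) {
  cohort@kinematics[[as.character(stitch_id)]]
}

#' Validate a cohort and report every invariant violation
#'
#' Checks, per stitch: all six sub-skill clips and labels present, labels
#' binary, clip frame ids non-empty / non-negative / strictly increasing and
#' present in the stitch's kinematic log, the log matching the 78-column
#' schema with finite quaternions, and the institution id being listed in the
#' cohort's institutions.
#'
#' @param cohort a \code{SutureCohort} (possibly invalid).
#' @return data.frame with columns \code{stitch_id}, \code{check},
#'   \code{message}; zero rows iff the cohort satisfies every invariant.
#' @export
validateCohort <- function(cohort) {
  st <- cohort@stitches
  out <- list()
  bad <- function(id, check, message) {
    out[[length(out) + 1L]] <<- data.frame(
      stitch_id = as.character(id), check = check, message = message,
      stringsAsFactors = FALSE)
  }
  need <- c("stitch_id", "surgeon_id", "institution_id", labelColumns())
  miss <- setdiff(need, names(st))
  if (length(miss) > 0L) {
    bad("<table>", "schema", paste("missing columns:", paste(miss, collapse = ",")))
    return(do.call(rbind, out))
  }
  if (length(cohort@institutions) == 0L)
    bad("<cohort>", "institutions", "institution list empty")
  if (anyDuplicated(st$stitch_id))
    bad("<table>", "schema", "duplicated stitch ids")
  kc <- kinColumns()
  for (r in seq_len(nrow(st))) {
    id <- as.character(st$stitch_id[r])
    if (!(st$institution_id[r] %in% cohort@institutions))
      bad(id, "institution", paste("unknown institution", st$institution_id[r]))
    labs <- unlist(st[r, labelColumns()])
    if (!all(labs %in% c(0, 1)))
      bad(id, "labels", "non-binary sub-skill label")
    clips <- cohort@clips[[id]]
    log <- cohort@kinematics[[id]]
    if (is.null(clips)) { bad(id, "clips", "no clip entry"); next }
    missk <- setdiff(subSkillCodes(), names(clips))
    if (length(missk) > 0L)
      bad(id, "clips", paste("missing sub-skill clip(s):",
                             paste(missk, collapse = ",")))
    logok <- !is.null(log) && identical(names(log), kc)
    if (!logok) {
      bad(id, "kinematics", "kinematic log missing or schema mismatch")
    } else {
      qcols <- grep("_q", kc, fixed = TRUE)
      if (!all(is.finite(as.matrix(log[, qcols]))))
        bad(id, "kinematics", "non-finite quaternion entries")
    }
    for (k in intersect(subSkillCodes(), names(clips))) {
      fid <- clips[[k]]
      if (length(fid) == 0L) {
        bad(id, "frame_ids", paste0(k, ": empty frame-id list")); next
      }
      if (any(fid < 0))
        bad(id, "frame_ids", paste0(k, ": negative frame id"))
      if (any(diff(fid) <= 0))
        bad(id, "frame_ids", paste0(k, ": frame ids not strictly increasing"))
      if (logok && !all(fid %in% log$frame_id))
        bad(id, "frame_ids", paste0(k, ": frame id absent from kinematic log"))
    }
  }
  if (length(out) == 0L)
    return(data.frame(stitch_id = character(0), check = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' FeatureStore: fixed-dimension clip features keyed by stitch/sub-skill
#'
#' Stage 1 exports one feature vector per (stitch, sub-skill); stage 2
#' consumes them frozen. Keys are \code{"<stitch_id>/<subskill>"}.
#'
#' @slot features numeric matrix, one row per key (rownames are keys).
#' @slot encoder identifier of the encoder that produced the features.
#' @export
setClass("FeatureStore",
  representation(features = "matrix", encoder = "character"))

setValidity("FeatureStore", function(object) {
  if (!is.numeric(object@features)) return("features must be numeric")
  if (nrow(object@features) > 0L && is.null(rownames(object@features)))
    return("features must have key rownames")
  if (anyDuplicated(rownames(object@features))) return("duplicate keys")
  TRUE
})

#' Construct / access a FeatureStore
#'
#' @param features numeric matrix with \code{"stitch/subskill"} rownames.
#' @param encoder encoder identifier string.
#' @export
featureStore <- function(features, encoder = "unknown") {
  new("FeatureStore", features = as.matrix(features), encoder = encoder)
}

#' @rdname featureStore
#' @param store a \code{FeatureStore}.
#' @export
featureDim <- function(store) ncol(store@features)

#' @rdname featureStore
#' @export
featureKeys <- function(store) rownames(store@features)

#' @rdname featureStore
#' @param stitch_id,subskill key components.
#' @export
featureKey <- function(stitch_id, subskill) paste0(stitch_id, "/", subskill)

#' @rdname featureStore
#' @export
getFeature <- function(store, stitch_id, subskill) {
  key <- featureKey(stitch_id, subskill)
  if (!key %in% rownames(store@features))
    stop("no feature stored for key ", key, call. = FALSE)
  store@features[key, ]
}

#' @rdname featureStore
#' @param a,b stores to merge; dimensions must agree.
#' @export
mergeFeatureStores <- function(a, b) {
  if (featureDim(a) != featureDim(b))
    stop("feature dimension mismatch on merge: ", featureDim(a), " vs ",
         featureDim(b), call. = FALSE)
  featureStore(rbind(a@features, b@features), encoder = a@encoder)
}

setMethod("show", "FeatureStore", function(object) {
  cat("FeatureStore:", nrow(object@features), "vectors of dimension",
      ncol(object@features), "(encoder:", object@encoder, ")\n")
})
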