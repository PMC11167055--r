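#' The six assessed suturing sub-skills
#'
#' The assessment rubric scores one stitch on six binary sub-skills grouped
#' into three domains: needle handling (needle repositioning \code{RP},
#' needle hold ratio \code{HR}, needle hold angle \code{HA}), needle driving
#' (driving smoothness \code{DS}, wrist rotation \code{WR}) and needle
#' withdrawal (wrist rotation at needle withdrawal \code{WRnw}). All
#' per-sub-skill containers in the package are ordered and keyed by
#' \code{subSkillCodes()}.
#'
#' @return \code{subSkillCodes()}: character vector of the six codes in
#'   canonical order. \code{subSkillTable()}: data.frame with columns
#'   \code{code}, \code{domain}, \code{description}.
#' @examples
#' subSkillCodes()
#' subSkillTable()
#' @export
subSkillCodes <- function() {
  c("RP", "HR", "HA", "DS", "WR", "WRnw")
}

#' @rdname subSkillCodes
#' @export
subSkillTable <- function() {
  data.frame(
    code = subSkillCodes(),
    domain = c("needle_handling", "needle_handling", "needle_handling",
               "needle_driving", "needle_driving", "needle_withdrawal"),
    description = c(
      "needle repositioning: number of hand exchanges of the needle",
      "needle hold ratio: hold between 1/2 and 1/4 of the needle",
      "needle hold angle: needle angle with respect to tissue",
      "driving smoothness: smoothness of the drive through tissue",
      "wrist rotation: smooth wrist rotation during entry",
      "wrist rotation needle withdrawal: smooth wrist rotation during exit"),
    stringsAsFactors = FALSE
  )
}

#' @rdname subSkillCodes
#' @param codes character vector to check against the sub-skill vocabulary.
#' @export
checkSubSkillCodes <- function(codes) {
  bad <- setdiff(codes, subSkillCodes())
  if (length(bad) > 0L) {
    stop("unknown sub-skill code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# number of tracked instrument poses and scalars per kinematic frame
N_POSES <- 10L
POSE_SCALARS <- 7L          # 3 position + 4 quaternion
KIN_WIDTH <- N_POSES * POSE_SCALARS   # 70

labelColumns <- function() paste0("label_", subSkillCodes())
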