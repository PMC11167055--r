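# Kinematic preprocessing: camera-relative re-expression, per-clip
# normalization, alignment of the raw sensor log to each sub-phase clip at a
# fixed sequence length, and flattening for fusion with clip features.

posCols <- function() {
  as.vector(vapply(seq_len(N_POSES),
                   function(i) (i - 1L) * POSE_SCALARS + 1:3, integer(3)))
}
quatColsOf <- function(i) (i - 1L) * POSE_SCALARS + 4:7
posColsOf <- function(i) (i - 1L) * POSE_SCALARS + 1:3

#' Re-express every pose relative to the camera
#'
#' Positions are centered by subtracting the camera position and rotated by
#' the camera's inverse orientation; orientations are composed with the
#' inverse camera quaternion (Hamilton convention, unit-normalized after
#' composition). The camera pose itself maps to the origin and the identity
#' quaternion.
#'
#' @param log kinematic-log data.frame (\code{kinColumns()} schema).
#' @return the transformed log.
#' @export
cameraFrameTransform <- function(log) {
  qc <- as.matrix(log[, paste0("cam_", c("qw", "qx", "qy", "qz"))])
  if (any(rowSums(qc^2) == 0))
    stop("zero-norm camera quaternion in kinematic log", call. = FALSE)
  qc <- quatNormalizeRows(qc)
  qinv <- quatConjugateRows(qc)
  pc <- as.matrix(log[, paste0("cam_", c("x", "y", "z"))])
  out <- log
  off <- 1L  # frame_id column precedes the pose block
  for (i in seq_len(N_POSES)) {
    p <- as.matrix(log[, off + posColsOf(i)])
    q <- as.matrix(log[, off + quatColsOf(i)])
    out[, off + posColsOf(i)] <- quatRotateRows(qinv, p - pc)
    out[, off + quatColsOf(i)] <- quatNormalizeRows(quatMultiplyRows(qinv, q))
  }
  out[, paste0("cam_", c("x", "y", "z"))] <- 0
  out[, paste0("cam_", c("qw", "qx", "qy", "qz"))] <-
    matrix(rep(c(1, 0, 0, 0), each = nrow(log)), nrow(log), 4L)
  out
}

#' Normalize positions by the maximum distance from the origin
#'
#' Divides every pose position by the largest Euclidean position norm found
#' across frames and poses, so the maximum norm becomes exactly 1. Applied
#' per clip, after \code{\link{cameraFrameTransform}}. An all-zero input is
#' returned unchanged with attribute \code{degenerate = TRUE} rather than
#' erroring, so pathological synthetic inputs pass through flagged.
#'
#' @param x either a kinematic-log data.frame or an aligned T x 70 matrix.
#' @return \code{x} with positions scaled; attribute \code{degenerate} set.
#' @export
normalizePositions <- function(x) {
  if (is.data.frame(x)) {
    block <- as.matrix(x[, 1L + seq_len(KIN_WIDTH)])
  } else block <- x
  pc <- posCols()
  m <- sqrt(max(vapply(seq_len(N_POSES), function(i) {
    max(rowSums(block[, posColsOf(i), drop = FALSE]^2))
  }, numeric(1))))
  degenerate <- (m == 0)
  if (!degenerate) block[, pc] <- block[, pc] / m
  if (is.data.frame(x)) {
    x[, 1L + seq_len(KIN_WIDTH)] <- block
    out <- x
  } else {
    out <- block
    attributes(out)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <-
      attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))]
  }
  attr(out, "degenerate") <- degenerate
  out
}

# uniform index subsampling: first and last retained, strictly increasing
# whenever n > target; repetition of the last index pads short clips
alignIndices <- function(n, target_len) {
  if (n >= target_len) {
    floor(seq(0, n - 1, length.out = target_len)) + 1L
  } else {
    c(seq_len(n), rep(n, target_len - n))
  }
}

#' Align a kinematic log to a sub-phase clip at fixed length
#'
#' Selects log rows whose \code{frame_id} occurs in the clip's frame-id list
#' (log order preserved), then uniform-index subsamples to
#' \code{target_len} frames when longer (first and last frame retained, no
#' interpolation) or pads by repeating the last frame when shorter.
#'
#' @param log kinematic-log data.frame.
#' @param clip integer vector of clip frame ids (strictly increasing).
#' @param target_len output sequence length; default 24 frames.
#' @param subskill optional code recorded on the result.
#' @param stitch_id optional id used in error messages.
#' @return T x 70 numeric matrix (T = \code{target_len}) with attributes
#'   \code{source_frame_ids} and \code{subskill}.
#' @export
alignToClip <- function(log, clip, target_len = 24L, subskill = NA_character_,
                        stitch_id = "<stitch>") {
  sel <- which(log$frame_id %in% clip)
  if (length(sel) == 0L)
    stop("no kinematic frames match clip frame ids for stitch ", stitch_id,
         call. = FALSE)
  idx <- sel[alignIndices(length(sel), as.integer(target_len))]
  out <- as.matrix(log[idx, 1L + seq_len(KIN_WIDTH), drop = FALSE])
  dimnames(out) <- NULL
  attr(out, "source_frame_ids") <- log$frame_id[idx]
  attr(out, "subskill") <- subskill
  out
}

#' Flatten an aligned kinematic sequence frame-major
#'
#' Frame 0's 70 scalars first, then frame 1's, giving a vector of length
#' \code{70 * target_len} (1680 at the default 24 frames), the kinematic
#' block of a stage-2 node input.
#'
#' @param ak aligned T x 70 matrix from \code{\link{alignToClip}}.
#' @return numeric vector of length \code{70 * nrow(ak)}.
#' @export
flattenKinematics <- function(ak) as.vector(t(ak))

#' @rdname flattenKinematics
#' @param v flattened vector; inverse of \code{flattenKinematics}.
#' @export
unflattenKinematics <- function(v) {
  matrix(v, ncol = KIN_WIDTH, byrow = TRUE)
}

#' Full per-clip kinematic pipeline
#'
#' Camera-frame transform, clip alignment, per-clip max-norm normalization.
#'
#' @inheritParams alignToClip
#' @return aligned, normalized T x 70 matrix.
#' @export
prepareKinematics <- function(log, clip, target_len = 24L,
                              subskill = NA_character_,
                              stitch_id = "<stitch>") {
  normalizePositions(cameraFrameTransform(log) |>
                       alignToClip(clip, target_len, subskill, stitch_id))
}

#' Flattened kinematics for every (stitch, sub-skill) of a cohort
#'
#' @param cohort a \code{SutureCohort}.
#' @param target_len aligned sequence length (default 24).
#' @return numeric array n_stitches x 6 x (70 * target_len), dimnames stitch
#'   ids and sub-skill codes.
#' @export
cohortKinematics <- function(cohort, target_len = 24L) {
  st <- cohort@stitches
  codes <- subSkillCodes()
  out <- array(0, dim = c(nrow(st), length(codes), KIN_WIDTH * target_len),
               dimnames = list(st$stitch_id, codes, NULL))
  for (r in seq_len(nrow(st))) {
    id <- st$stitch_id[r]
    tlog <- cameraFrameTransform(cohort@kinematics[[id]])
    for (k in codes) {
      ak <- normalizePositions(
        alignToClip(tlog, cohort@clips[[id]][[k]], target_len, k, id))
      out[r, k, ] <- flattenKinematics(ak)
    }
  }
  out
}
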