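# Cohort and feature-store I/O. Everything is plain text on purpose: a
# cohort directory holds cohort.csv (stitch table), clips.csv (frame-id
# lists) and kinematics/<stitch_id>.csv sidecar logs, all diffable and
# inspectable with no tooling.

#' Read a cohort from a manifest directory
#'
#' Expects \code{cohort.csv} (columns \code{stitch_id}, \code{surgeon_id},
#' \code{institution_id}, \code{label_RP} ... \code{label_WRnw}),
#' \code{clips.csv} (columns \code{stitch_id}, \code{subskill},
#' \code{frame_ids} as a space-separated list, optional \code{media_path}),
#' and one kinematic log CSV per stitch under \code{kinematics/}. Frame ids
#' are 0-based and join against the log's \code{frame_id} column.
#'
#' @param manifest_path a cohort directory, or its \code{cohort.csv}.
#' @return validated \code{\link{sutureCohort}}; invariant violations raise
#'   an error naming the offending stitch and check.
#' @export
loadCohort <- function(manifest_path) {
  dir <- if (dir.exists(manifest_path)) manifest_path else dirname(manifest_path)
  cfile <- file.path(dir, "cohort.csv")
  if (!file.exists(cfile)) stop("no cohort.csv under ", dir, call. = FALSE)
  st <- utils::read.csv(cfile, stringsAsFactors = FALSE)
  st$stitch_id <- as.character(st$stitch_id)
  cl <- utils::read.csv(file.path(dir, "clips.csv"), stringsAsFactors = FALSE)
  cl$stitch_id <- as.character(cl$stitch_id)
  clips <- lapply(split(cl, cl$stitch_id), function(d) {
    entry <- lapply(seq_len(nrow(d)), function(i) {
      fid <- as.integer(strsplit(trimws(d$frame_ids[i]), "[[:space:]]+")[[1]])
      if (!is.null(d$media_path) && !is.na(d$media_path[i]) &&
          nzchar(d$media_path[i]))
        attr(fid, "media_path") <- d$media_path[i]
      fid
    })
    names(entry) <- d$subskill
    entry
  })
  clips <- clips[st$stitch_id]
  names(clips) <- st$stitch_id
  kin <- lapply(st$stitch_id, function(id) {
    f <- file.path(dir, "kinematics", paste0(id, ".csv"))
    if (!file.exists(f)) return(NULL)
    utils::read.csv(f, stringsAsFactors = FALSE)
  })
  names(kin) <- st$stitch_id
  sutureCohort(st, clips, kin, institutions = sort(unique(st$institution_id)))
}

#' Write a cohort to a manifest directory
#'
#' @param cohort a \code{SutureCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
saveCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "kinematics"), recursive = TRUE, showWarnings = FALSE)
  st <- cohort@stitches
  utils::write.csv(st, file.path(dir, "cohort.csv"), row.names = FALSE)
  rows <- list()
  for (id in st$stitch_id) {
    for (k in names(cohort@clips[[id]])) {
      fid <- cohort@clips[[id]][[k]]
      mp <- attr(fid, "media_path")
      rows[[length(rows) + 1L]] <- data.frame(
        stitch_id = id, subskill = k,
        frame_ids = paste(as.integer(fid), collapse = " "),
        media_path = if (is.null(mp)) "" else mp, stringsAsFactors = FALSE)
    }
    utils::write.csv(cohort@kinematics[[id]],
                     file.path(dir, "kinematics", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "clips.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Save / load a FeatureStore as CSV
#'
#' One row per \code{"stitch/subskill"} key; the encoder id and dimension
#' travel in commented header lines, so \code{loadFeatures(saveFeatures(x))}
#' reproduces metadata exactly and values to within read/write precision
#' (17 significant digits, i.e. lossless for doubles).
#'
#' @param store a non-empty \code{FeatureStore}.
#' @param path output CSV path.
#' @return \code{saveFeatures}: \code{path}; \code{loadFeatures}: the store.
#' @export
saveFeatures <- function(store, path) {
  if (nrow(store@features) == 0L)
    stop("refusing to save an empty FeatureStore", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#encoder=", store@encoder),
               paste0("#dim=", ncol(store@features))), con)
  m <- store@features
  header <- paste(c("key", paste0("V", seq_len(ncol(m)))), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), con)
  invisible(path)
}

#' @rdname saveFeatures
#' @export
loadFeatures <- function(path) {
  head <- readLines(path, n = 2L)
  enc <- sub("^#encoder=", "", head[1L])
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  dimnames(m) <- list(d$key, NULL)
  featureStore(m, encoder = enc)
}
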