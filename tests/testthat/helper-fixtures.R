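# In-code fixtures: a tiny hand-built cohort and small random kinematic logs.

# kinematic log with given frame ids; positions/quaternions random but valid
randomLog <- function(frame_ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- length(frame_ids)
  log <- data.frame(frame_id = as.integer(frame_ids))
  for (i in 1:10) {
    log[paste0("p", i, "_", c("x", "y", "z"))] <- matrix(rnorm(T * 3), T, 3)
    q <- matrix(rnorm(T * 4), T, 4)
    log[paste0("p", i, "_", c("qw", "qx", "qy", "qz"))] <-
      q / sqrt(rowSums(q^2))
  }
  log[paste0("cam_", c("x", "y", "z"))] <- matrix(rnorm(T * 3, sd = 0.2), T, 3)
  q <- matrix(rnorm(T * 4), T, 4)
  log[paste0("cam_", c("qw", "qx", "qy", "qz"))] <- q / sqrt(rowSums(q^2))
  log
}

# three stitches, two institutions, full clips over a shared 30-frame log
makeTinyCohort <- function(seed = 42) {
  set.seed(seed)
  ids <- c("ST1", "ST2", "ST3")
  st <- data.frame(
    stitch_id = ids,
    surgeon_id = c("A_S1", "A_S1", "B_S1"),
    institution_id = c("INSTA", "INSTA", "INSTB"),
    stringsAsFactors = FALSE)
  labs <- matrix(rbinom(18, 1, 0.5), 3, 6)
  colnames(labs) <- paste0("label_", subSkillCodes())
  st <- cbind(st, as.data.frame(labs))
  spans <- list(0:4, 5:9, 10:14, 15:19, 20:24, 25:29)
  clips <- lapply(ids, function(id) {
    cl <- lapply(spans, as.integer)
    names(cl) <- subSkillCodes()
    cl
  })
  names(clips) <- ids
  kins <- lapply(ids, function(id) randomLog(0:29))
  names(kins) <- ids
  sutureCohort(st, clips, kins, c("INSTA", "INSTB"))
}

# small synthetic generation settings reused across tests
fastSynth <- function(...) {
  synthConfig(n_institutions = 2, surgeons_per_institution = 2,
              stitches_per_surgeon = 4, feature_dim = 6,
              kinematic_len = c(4L, 8L), ...)
}

# feature store aligned to a cohort, random values
randomStoreFor <- function(cohort, dim = 6, seed = 1) {
  set.seed(seed)
  ids <- stitchTable(cohort)$stitch_id
  keys <- as.vector(outer(ids, subSkillCodes(), featureKey))
  m <- matrix(rnorm(length(keys) * dim), length(keys), dim)
  rownames(m) <- keys
  featureStore(m, "test")
}
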