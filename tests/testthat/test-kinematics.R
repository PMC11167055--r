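test_that("camera-frame transform maps the camera pose to origin/identity", {
  log <- randomLog(0:9, seed = 1)
  # plant pose 3 exactly at the camera pose in every frame
  log[, paste0("p3_", c("x", "y", "z"))] <- log[, paste0("cam_", c("x", "y", "z"))]
  log[, paste0("p3_", c("qw", "qx", "qy", "qz"))] <-
    log[, paste0("cam_", c("qw", "qx", "qy", "qz"))]
  out <- cameraFrameTransform(log)
  expect_lt(max(abs(as.matrix(out[, paste0("p3_", c("x", "y", "z"))]))), 1e-9)
  q <- as.matrix(out[, paste0("p3_", c("qw", "qx", "qy", "qz"))])
  # identity up to quaternion sign
  expect_lt(max(abs(abs(q[, 1]) - 1)), 1e-9)
  expect_lt(max(abs(q[, 2:4])), 1e-9)
  expect_equal(max(abs(as.matrix(out[, paste0("cam_", c("x", "y", "z"))]))), 0)
})

test_that("identity camera leaves poses unchanged", {
  log <- randomLog(0:9, seed = 2)
  log[, paste0("cam_", c("x", "y", "z"))] <- 0
  log[, paste0("cam_", c("qw", "qx", "qy", "qz"))] <-
    matrix(rep(c(1, 0, 0, 0), each = 10), 10, 4)
  out <- cameraFrameTransform(log)
  cols <- setdiff(names(log), grep("^cam_", names(log), value = TRUE))
  expect_equal(as.matrix(out[, cols]), as.matrix(log[, cols]),
               tolerance = 1e-12)
})

test_that("camera transform round-trips through the inverse camera", {
  log <- randomLog(0:19, seed = 3)
  out <- cameraFrameTransform(log)
  # re-apply the original camera pose as a rigid motion: recovers the input
  for (r in seq_len(nrow(log))) {
    q0 <- as.numeric(log[r, paste0("cam_", c("qw", "qx", "qy", "qz"))])
    t0 <- as.numeric(log[r, paste0("cam_", c("x", "y", "z"))])
    back <- applyRigid(out[r, , drop = FALSE], q0, t0)
    for (i in 1:10) {
      pc <- paste0("p", i, "_", c("x", "y", "z"))
      expect_equal(as.numeric(back[, pc]), as.numeric(log[r, pc]),
                   tolerance = 1e-9)
    }
  }
})

test_that("zero-norm camera quaternion is rejected", {
  log <- randomLog(0:4, seed = 4)
  log[2, paste0("cam_", c("qw", "qx", "qy", "qz"))] <- 0
  expect_error(cameraFrameTransform(log), "zero-norm camera quaternion")
})

test_that("position normalization yields max norm exactly 1 or flags zero", {
  log <- cameraFrameTransform(randomLog(0:14, seed = 5))
  ak <- alignToClip(log, 0:14, target_len = 15)
  nm <- function(block) max(vapply(1:10, function(i) {
    sqrt(max(rowSums(block[, (i - 1) * 7 + 1:3, drop = FALSE]^2)))
  }, numeric(1)))
  scaled <- ak * 5 / nm(ak)   # max norm exactly 5
  out <- normalizePositions(scaled)
  expect_equal(nm(out), 1, tolerance = 1e-12)
  expect_false(attr(out, "degenerate"))
  # property: any random input normalizes to max norm in {0, 1}
  for (s in 1:20) {
    ak2 <- alignToClip(cameraFrameTransform(randomLog(0:9, seed = 100 + s)),
                       0:9, target_len = 10)
    expect_equal(nm(normalizePositions(ak2)), 1, tolerance = 1e-12)
  }
  zero <- ak
  for (i in 1:10) zero[, (i - 1) * 7 + 1:3] <- 0
  outz <- normalizePositions(zero)
  expect_true(attr(outz, "degenerate"))
  expect_equal(nm(outz), 0)
})

test_that("alignment selects, subsamples and pads to the target length", {
  log <- randomLog(0:47, seed = 6)
  # exact length: identity selection
  ak <- alignToClip(log, 0:23, target_len = 24)
  expect_equal(attr(ak, "source_frame_ids"), 0:23)
  # longer clip: uniform stride keeping first and last
  ak2 <- alignToClip(log, 0:47, target_len = 24)
  expected_idx <- floor(seq(0, 47, length.out = 24)) + 1L
  expect_equal(attr(ak2, "source_frame_ids"), (0:47)[expected_idx])
  expect_equal(attr(ak2, "source_frame_ids")[c(1, 24)], c(0L, 47L))
  expect_true(all(diff(attr(ak2, "source_frame_ids")) > 0))
  # shorter clip: last frame repeated
  ak3 <- alignToClip(log, 0:9, target_len = 24)
  expect_equal(attr(ak3, "source_frame_ids"), c(0:9, rep(9L, 14)))
  expect_equal(nrow(ak3), 24L)
  expect_equal(unname(ak3[24, ]), unname(ak3[10, ]))
  # clips index by frame id, not by row position
  log2 <- randomLog(seq(0, 94, by = 2), seed = 7)
  ak4 <- alignToClip(log2, c(4L, 8L, 12L), target_len = 3)
  expect_equal(attr(ak4, "source_frame_ids"), c(4L, 8L, 12L))
  expect_error(alignToClip(log, 1000:1010, stitch_id = "STX"), "STX")
})

test_that("flattening is frame-major, 70 x target_len, and invertible", {
  log <- randomLog(0:23, seed = 8)
  ak <- alignToClip(log, 0:23, target_len = 24)
  v <- flattenKinematics(ak)
  expect_length(v, 1680L)
  expect_equal(v[1:70], unname(ak[1, ]))
  expect_equal(v[71:140], unname(ak[2, ]))
  expect_equal(unflattenKinematics(v), unname(ak), ignore_attr = TRUE)
  ak1 <- alignToClip(log, 0:23, target_len = 1)
  expect_length(flattenKinematics(ak1), 70L)
})

test_that("pipeline is invariant to a global rigid motion", {
  log <- randomLog(0:11, seed = 9)
  base <- normalizePositions(cameraFrameTransform(log))
  poscols <- as.vector(sapply(1:10, function(i) paste0("p", i, "_", c("x", "y", "z"))))
  set.seed(10)
  for (rep in 1:25) {
    q0 <- rnorm(4); q0 <- q0 / sqrt(sum(q0^2))
    t0 <- rnorm(3, sd = 3)
    moved <- normalizePositions(cameraFrameTransform(applyRigid(log, q0, t0)))
    expect_equal(as.matrix(moved[, poscols]), as.matrix(base[, poscols]),
                 tolerance = 1e-6)
  }
})

test_that("the same log and clip always produce identical output", {
  log <- randomLog(0:30, seed = 11)
  a <- prepareKinematics(log, 3:27, 24, "HA")
  b <- prepareKinematics(log, 3:27, 24, "HA")
  expect_identical(a, b)
})
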