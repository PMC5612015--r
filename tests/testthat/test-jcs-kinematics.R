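test_that("semantic labels map axes to anatomical motions", {
  cv <- semantic_labels("costovertebral")
  expect_identical(cv[["Z"]], "bucket handle")
  expect_identical(cv[["Y"]], "calliper")
  expect_identical(cv[["X"]], "pump handle")
  di <- semantic_labels("dorsal_intracostal")
  expect_identical(di[["X"]], "long-axis rotation")
  expect_identical(di[["Z"]], "abduction-adduction")
  expect_error(semantic_labels("elbow"), "unknown")
})

test_that("costovertebral JCS equals the body-plane axes at zero pose", {
  defn <- joint_definition("cv", "costovertebral", "vert", "rib",
                           anchor = c(1, 2, 3), zero_pose_frame = 1L)
  expect_equal(ribxromm:::jcs_zero_orientation(defn), diag(3))
})

test_that("intracostal JCS follows the Gram-Schmidt hand construction", {
  defn <- joint_definition(
    "di", "dorsal_intracostal", "vrib", "irib", anchor = c(0, 0, 0),
    zero_pose_frame = 1L,
    distal_axis_points = rbind(c(0, 0, 0), c(1, 0, 0)),
    proximal_plane_points = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  Q <- ribxromm:::jcs_zero_orientation(defn)
  expect_equal(Q[, "X"], c(1, 0, 0))
  # Z lies in the xy-plane, orthogonal to X; Y = Z x X
  expect_equal(Q[, "Z"][3], 0)
  expect_equal(sum(Q[, "Z"] * Q[, "X"]), 0)
  expect_equal(Q[, "Y"], ribxromm:::crossprod3(Q[, "Z"], Q[, "X"]))
  expect_equal(det(Q), 1, tolerance = 1e-12)
  # collinear plane points are rejected
  bad <- joint_definition(
    "di", "dorsal_intracostal", "a", "b", anchor = c(0, 0, 0),
    zero_pose_frame = 1L,
    distal_axis_points = rbind(c(0, 0, 0), c(1, 0, 0)),
    proximal_plane_points = rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)))
  expect_error(ribxromm:::jcs_zero_orientation(bad), "collinear")
})

test_that("a distal body rigidly following the proximal yields zero angles", {
  nf <- 20
  set.seed(55)
  rot <- array(0, c(3, 3, nf))
  for (f in 1:nf) rot[, , f] <- random_rotation()
  prox <- pose_series_about("prox", rot, c(5, 5, 5))
  dist <- prox; dist$body_id <- "dist"
  defn <- joint_definition("j", "costovertebral", "prox", "dist",
                           anchor = c(1, 0, 2), zero_pose_frame = 1L)
  jc <- build_jcs(defn, prox, dist)
  ang <- extract_joint_angles(jc, prox, dist)
  expect_lt(max(abs(ang[, c("z_deg", "y_deg", "x_deg")])), 1e-9)
  expect_lt(max(abs(ang[, c("tx", "ty", "tz")])), 1e-9)
})

test_that("prescribed JCS rotations are recovered exactly", {
  nf <- 50
  anchor <- c(3, -1, 2)
  prox <- static_pose_series("prox", nf)
  # pure 12-degree Z rotation ramp
  rot <- array(0, c(3, 3, nf))
  zs <- seq(0, 12, length.out = nf)
  for (f in 1:nf) rot[, , f] <- euler_to_matrix(c(zs[f], 0, 0))
  dist <- pose_series_about("dist", rot, anchor)
  defn <- joint_definition("j", "costovertebral", "prox", "dist",
                           anchor = anchor, zero_pose_frame = 1L)
  jc <- build_jcs(defn, prox, dist)
  ang <- extract_joint_angles(jc, prox, dist)
  expect_equal(ang$z_deg, zs, tolerance = 1e-9)
  expect_lt(max(abs(ang$y_deg), abs(ang$x_deg)), 1e-9)
  # simultaneous (Z, Y, X) = (10, 5, 3) applied in ZYX order
  rot2 <- array(rep(euler_to_matrix(c(10, 5, 3)), nf), c(3, 3, nf))
  rot2[, , 1] <- diag(3)
  dist2 <- pose_series_about("dist", rot2, anchor)
  ang2 <- extract_joint_angles(build_jcs(defn, prox, dist2), prox, dist2)
  expect_equal(as.numeric(ang2[nf, c("z_deg", "y_deg", "x_deg")]),
               c(10, 5, 3), tolerance = 1e-9)
})

test_that("joint angles are invariant under a global rigid transform", {
  set.seed(56)
  nf <- 30
  anchor <- c(2, 1, 0)
  prox_rot <- array(0, c(3, 3, nf))
  dist_rot <- array(0, c(3, 3, nf))
  for (f in 1:nf) {
    prox_rot[, , f] <- axis_angle_to_matrix(c(1, 0, 0), (f - 1) * 0.3)
    dist_rot[, , f] <- prox_rot[, , f] %*%
      axis_angle_to_matrix(c(0.2, 0.5, 0.84), (f - 1) * 0.7)
  }
  prox <- pose_series_about("p", prox_rot, anchor)
  dist <- pose_series_about("d", dist_rot, anchor)
  defn <- joint_definition("j", "costovertebral", "p", "d",
                           anchor = anchor, zero_pose_frame = 1L)
  jc <- build_jcs(defn, prox, dist)
  ang <- extract_joint_angles(jc, prox, dist)
  # move the whole world: the body-attached JCS frames move with it, so
  # every angle and translation is unchanged
  G <- random_rotation(); gt <- c(10, -4, 7)
  mv <- function(ps) {
    for (f in 1:nf) {
      ps$translations[f, ] <- as.numeric(G %*% ps$translations[f, ] + gt)
      ps$rotations[, , f] <- G %*% ps$rotations[, , f]
    }
    ps
  }
  ang2 <- extract_joint_angles(jc, mv(prox), mv(dist))
  expect_equal(as.matrix(ang[, -1]), as.matrix(ang2[, -1]), tolerance = 1e-9)
})

test_that("hinge motion about an arbitrary axis is recomposed to that axis", {
  nf <- 200
  axis <- c(0.5, 0.5, 1 / sqrt(2)); axis <- axis / sqrt(sum(axis^2))
  anchor <- c(4, 0, -2)
  th <- 18 * (1 - cos(2 * pi * seq(0, 1, length.out = nf))) / 2
  rot <- array(0, c(3, 3, nf))
  for (f in 1:nf) rot[, , f] <- axis_angle_to_matrix(axis, th[f])
  prox <- static_pose_series("p", nf)
  dist <- pose_series_about("d", rot, anchor)
  defn <- joint_definition("j", "costovertebral", "p", "d",
                           anchor = anchor, zero_pose_frame = 1L)
  ang <- extract_joint_angles(build_jcs(defn, prox, dist), prox, dist)
  cyc <- resample_cycle(as.matrix(ang[, c("z_deg", "y_deg", "x_deg")]))
  iv <- total_rotation_axis(average_cycles(list(cyc)))
  expect_lt(axis_line_angle(iv$axis, axis), 0.5)
  expect_equal(iv$theta_deg, 18, tolerance = 0.05)
})

test_that("missing pose frames propagate as missing angles", {
  nf <- 10
  prox <- static_pose_series("p", nf)
  dist <- static_pose_series("d", nf)
  dist$present[4] <- FALSE
  defn <- joint_definition("j", "sternocostal", "p", "d",
                           anchor = c(0, 0, 0), zero_pose_frame = 1L)
  ang <- extract_joint_angles(build_jcs(defn, prox, dist), prox, dist)
  expect_true(is.na(ang$z_deg[4]))
  expect_false(anyNA(ang$z_deg[-4]))
})
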