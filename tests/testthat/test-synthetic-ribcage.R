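test_that("default ribcage has the documented structure and landmark pattern", {
  m <- build_ribcage()
  expect_equal(m$config$n_ribs, 8L)
  expect_length(m$bodies, 28L)          # 8 x 3 rib segments + 3 sections + sternum
  expect_length(m$joints, 32L)          # 4 joints per rib
  expect_s3_class(m$bodies[["rib1_vertebral"]], "marker_set")
  # parapophysis sits medially (centrum) on V1-V2, then migrates laterally
  para <- m$landmarks[m$landmarks$landmark == "parapophysis", ]
  para <- para[order(para$vertebra_id), ]
  expect_true(all(diff(para$x[3:8]) >= 0))
  expect_lt(max(para$x[1:2]), min(para$x[3:8]))
  expect_error(build_ribcage(list(parapophysis_lateral_mm = c(8, 6, 7, 9, 10, 11))),
               "monotone")
})

test_that("noiseless trajectories are exactly consistent with ground-truth poses", {
  sim <- small_sim(seed = 5, n_breaths = 2, frame_rate = 60, noise_sd_mm = 0)
  m <- sim$model
  for (b in c("rib3_intermediate", "vcol2", "sternum")) {
    ps <- sim$truth$poses[[b]]
    refp <- m$bodies[[b]]$positions
    for (f in c(1L, 50L, 400L)) {
      world <- sweep(refp %*% t(ps$rotations[, , f]), 2,
                     ps$translations[f, ], `+`)
      obs <- t(sim$trajectories$positions[f, , rownames(refp)])
      expect_lt(max(abs(world - obs)), 1e-12)
    }
  }
})

test_that("zero amplitudes freeze the ribcage at the rest pose", {
  m <- build_ribcage()
  sc <- motion_script(list(cv1 = list(mode = "hinge", axis = c(0, 0, 1),
                                      amplitude_deg = 0)),
                      n_breaths = 1, frame_rate = 60, noise_sd_mm = 0,
                      seed = 9)
  sim <- simulate_breathing(m, sc)
  p0 <- sim$trajectories$positions[1, , ]
  for (f in c(100, 300)) {
    expect_equal(sim$trajectories$positions[f, , ], p0, tolerance = 1e-12)
  }
})

test_that("simulations are deterministic in the script, noise-varying in the seed", {
  m <- build_ribcage()
  sc <- default_motion_script(m, seed = 13, n_breaths = 2, frame_rate = 60)
  a <- simulate_breathing(m, sc)
  b <- simulate_breathing(m, sc)
  expect_identical(a$trajectories$positions, b$trajectories$positions)
  c_ <- simulate_breathing(m, sc, seed = 14)
  # same ground truth, different noise
  expect_identical(a$truth$poses[["rib2_sternal"]]$rotations,
                   c_$truth$poses[["rib2_sternal"]]$rotations)
  expect_identical(a$trajectories_clean$positions,
                   c_$trajectories_clean$positions)
  expect_false(identical(a$trajectories$positions,
                         c_$trajectories$positions))
})

test_that("breath bookkeeping matches the scripted periods", {
  m <- build_ribcage()
  sc <- default_motion_script(m, seed = 17, n_breaths = 5, frame_rate = 100,
                              period_s = 10, period_jitter_s = 1)
  expect_length(sc$periods_s, 5L)
  expect_true(all(abs(sc$periods_s - 10) <= 1))
  sim <- simulate_breathing(m, sc)
  expect_length(sim$truth$breath_frames, 6L)
  expect_equal(sim$truth$breath_frames[1], 1L)
  expect_equal(diff(sim$truth$breath_frames) / 100, sc$periods_s,
               tolerance = 0.02)
  # ground-truth joint angles are zero at every breath boundary
  ang <- sim$truth$joint_angles[["cv4"]]
  expect_lt(max(abs(ang$z_deg[sim$truth$breath_frames])), 0.02)
})

test_that("scripted hinge joints record their axis as ground truth", {
  m <- build_ribcage()
  sc <- default_motion_script(m, seed = 19, n_breaths = 2, frame_rate = 60)
  sim <- simulate_breathing(m, sc)
  tru <- sim$truth$axes
  for (j in 1:8) {
    scripted <- sc$joints[[paste0("cv", j)]]$axis
    rec <- as.numeric(tru[tru$joint_id == paste0("cv", j),
                          c("axis_x", "axis_y", "axis_z")])
    expect_lt(axis_line_angle(scripted, rec), 1e-6)
  }
})

test_that("noiseless end-to-end hinge recovery stays under half a degree", {
  sim <- small_sim(seed = 23, n_breaths = 3, frame_rate = 60, noise_sd_mm = 0)
  m <- sim$model
  jid <- "cv5"
  jd <- m$joints[[jid]]
  bodies <- m$bodies[c(jd$proximal_body_id, jd$distal_body_id)]
  res <- run_pipeline(sim$trajectories, bodies, m$joints[jid],
                      predicted_axes = m$predicted_axes)
  rec <- as.numeric(res$invivo_axes[1, c("axis_x", "axis_y", "axis_z")])
  tru <- as.numeric(sim$truth$axes[sim$truth$axes$joint_id == jid,
                                   c("axis_x", "axis_y", "axis_z")])
  expect_lt(axis_line_angle(rec, tru), 0.5)
})

test_that("mobile intracostal joints separate cross-joint from co-osseous pairs", {
  sim <- small_sim(seed = 29, n_breaths = 3, frame_rate = 60,
                   noise_sd_mm = 0.12)
  traj <- sim$trajectories
  prec <- tracking_precision(traj, list(c("rib4_vertebral_m1",
                                          "rib4_vertebral_m2")))
  cross <- classify_rigidity(
    intermarker_distance(traj, "rib4_vertebral_m1", "rib4_intermediate_m3",
                         filter_cutoff_hz = 1.5),
    prec$mean_sd, co_osseous = FALSE)
  expect_identical(cross$verdict, "mobile-joint")
  co <- classify_rigidity(
    intermarker_distance(traj, "rib4_sternal_m1", "rib4_sternal_m3",
                         filter_cutoff_hz = 1.5),
    prec$mean_sd, co_osseous = TRUE)
  expect_identical(co$verdict, "same-rigid-body")
})
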