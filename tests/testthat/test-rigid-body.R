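test_that("pose fit is exact on noiseless rigid motion", {
  ref <- tetra_markers()
  ms <- marker_set("bone", ref)
  R <- euler_to_matrix(c(25, 0, 0))
  tr <- c(1, 2, 3)
  frames <- list(ref, sweep(ref %*% t(R), 2, tr, `+`))
  traj <- traj_from_frames(frames, 100)
  expect_error(fit_pose_series(ms, traj), NA)
  ps <- fit_pose_series(ms, traj)
  expect_equal(ps$rotations[, , 1], diag(3), tolerance = 1e-12)
  expect_lt(ps$rms[1], 1e-9)
  expect_equal(ps$rotations[, , 2], R, tolerance = 1e-9)
  expect_equal(ps$translations[2, ], tr, tolerance = 1e-9)
  expect_lt(ps$rms[2], 1e-9)
})

test_that("collinear marker sets are rejected; sparse frames go missing", {
  line <- cbind(0:3 * 5, 0, 0)
  rownames(line) <- paste0("m", 1:4)
  expect_error(marker_set("straight", line), "collinear")
  # a frame with only 2 visible markers has no pose
  ref <- tetra_markers()
  obs <- ref
  obs[3:4, ] <- NA
  traj <- traj_from_frames(list(ref, obs), 100)
  ps <- fit_pose_series(marker_set("bone", ref), traj)
  expect_true(ps$present[1])
  expect_false(ps$present[2])
  expect_true(all(is.na(ps$rotations[, , 2])))
})

test_that("orientation error under noise shrinks with marker count and span", {
  # seeded grid: mean orientation error must decrease monotonically as the
  # marker cloud doubles in span and as markers are added
  err <- function(pos, sigma, n_rep = 60, seed = 7) {
    set.seed(seed)
    ms <- marker_set("b", pos)
    mean(vapply(seq_len(n_rep), function(i) {
      R <- random_rotation()
      obs <- pos %*% t(R) + matrix(stats::rnorm(length(pos), 0, sigma),
                                   ncol = 3)
      fit <- fit_rigid_transform(pos, obs)
      rotation_angle_deg(fit$rotation, R)
    }, numeric(1)))
  }
  base <- tetra_markers(15)
  e_small <- err(base, 0.12)
  e_wide <- err(tetra_markers(30), 0.12)
  more <- rbind(base, c(0, 0, 9), c(5, 5, -4))
  rownames(more) <- paste0("m", 1:6)
  e_more <- err(more, 0.12)
  expect_lt(e_wide, e_small)
  expect_lt(e_more, e_small)
})

test_that("intermarker distance is constant for a static pair and tracks motion", {
  p <- rbind(a = c(0, 0, 0), b = c(10, 0, 0), c = c(0, 10, 0))
  traj <- traj_from_frames(rep(list(p), 50), 100)
  d <- intermarker_distance(traj, "a", "b")
  expect_equal(d, rep(10, 50))
  # markers on two bodies articulating about a joint: distance fluctuates
  # at the driving frequency (forward-geometry oracle)
  nf <- 600; fr <- 60
  th <- 15 * sin(2 * pi * 0.1 * (0:(nf - 1)) / fr)
  frames <- lapply(th, function(a) {
    R <- axis_angle_to_matrix(c(0, 0, 1), a)
    rbind(a = c(-5, 0, 0), b = as.numeric(R %*% c(20, 0, 0)),
          c = c(0, 5, 0))
  })
  traj2 <- traj_from_frames(frames, fr)
  d2 <- intermarker_distance(traj2, "a", "b")
  expected <- vapply(th, function(a) {
    sqrt(sum((axis_angle_to_matrix(c(0, 0, 1), a) %*% c(20, 0, 0) -
                c(-5, 0, 0))^2))
  }, numeric(1))
  expect_equal(d2, expected, tolerance = 1e-12)
  # dominant frequency of the fluctuation = driving frequency
  sp <- Mod(stats::fft(d2 - mean(d2)))[2:30]
  expect_equal(which.max(sp), 2L)  # 0.1 Hz bin for 10 s record? 600/60=10s -> bin index 2
})

test_that("filtered co-osseous distance noise stays below the marker noise", {
  set.seed(77)
  p <- tetra_markers(20)
  nf <- 1200
  frames <- lapply(seq_len(nf), function(f) {
    p + matrix(stats::rnorm(length(p), 0, 0.12), ncol = 3)
  })
  traj <- traj_from_frames(frames, 100)
  d <- intermarker_distance(traj, "m1", "m2", filter_cutoff_hz = 1.5)
  expect_lt(sd(d), 0.12)
})

test_that("tracking precision matches the closed-form distance-noise SD", {
  # two markers with isotropic noise sigma: the distance SD is
  # sigma * sqrt(2) (projection of two independent noises on the
  # separation direction); Monte Carlo across 200 seeded pairs
  set.seed(88)
  sigma <- 0.12
  nf <- 400
  ids <- paste0("m", 1:2)
  per_pair <- vapply(1:200, function(k) {
    base <- rbind(c(0, 0, 0), c(12, 0, 0), c(0, 9, 0))
    rownames(base) <- c(ids, "m3")
    frames <- lapply(seq_len(nf), function(f) {
      base + matrix(stats::rnorm(length(base), 0, sigma), ncol = 3)
    })
    traj <- traj_from_frames(frames, 100)
    tracking_precision(traj, list(ids))$mean_sd
  }, numeric(1))
  expect_equal(mean(per_pair), sigma * sqrt(2), tolerance = 0.15)
  # noiseless rigid body -> precision 0
  p <- tetra_markers()
  traj0 <- traj_from_frames(rep(list(p), 10), 100)
  expect_equal(tracking_precision(traj0, list(c("m1", "m2")))$mean_sd, 0)
})

test_that("rigidity verdicts follow the k-times-precision band", {
  prec <- 0.17
  flat <- rep(10, 200) + seq(-0.05, 0.05, length.out = 200)
  expect_identical(classify_rigidity(flat, prec, co_osseous = TRUE)$verdict,
                   "same-rigid-body")
  wav <- 10 + 2 * sin(seq(0, 6 * pi, length.out = 400))
  expect_identical(classify_rigidity(wav, prec, co_osseous = FALSE)$verdict,
                   "mobile-joint")
  # co-osseous pair on a body with 2 mm flexural oscillation
  expect_identical(classify_rigidity(wav, prec, co_osseous = TRUE)$verdict,
                   "bending-suspected")
})

test_that("pose-series filtering removes tracking noise without bias", {
  set.seed(99)
  sim <- small_sim(seed = 99, n_breaths = 2, frame_rate = 60,
                   noise_sd_mm = 0.12)
  b <- "rib4_vertebral"
  ps <- fit_pose_series(sim$model$bodies[[b]], sim$trajectories)
  pf <- filter_pose_series(ps, 1.5)
  tp <- sim$truth$poses[[b]]
  sub <- seq(60, length(ps$present) - 60, by = 11)
  e_raw <- vapply(sub, function(f) {
    rotation_angle_deg(ps$rotations[, , f], tp$rotations[, , f])
  }, numeric(1))
  e_fil <- vapply(sub, function(f) {
    rotation_angle_deg(pf$rotations[, , f], tp$rotations[, , f])
  }, numeric(1))
  expect_lt(mean(e_fil), 0.5 * mean(e_raw))
  for (f in sub) expect_no_error(assert_rotation_matrix(pf$rotations[, , f]))
})
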