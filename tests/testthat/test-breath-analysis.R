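test_that("zero-phase filter: unit DC gain, transparent passband, strong stopband", {
  expect_equal(lowpass_filter(rep(3.3, 500), 1, 100), rep(3.3, 500),
               tolerance = 1e-9)
  t <- seq(0, 60, by = 0.01)
  slow <- sin(2 * pi * 0.1 * t)
  out <- lowpass_filter(slow, 1, 100)
  mid <- 1000:5000
  expect_lt(max(abs(out[mid] - slow[mid])), 0.01)     # within 1%
  fast <- sin(2 * pi * 5 * t)
  expect_lt(max(abs(lowpass_filter(fast, 1, 100)[mid])), 0.1)  # >= 90% attenuated
  expect_error(lowpass_filter(1:10, 1, 100), "too short")
  expect_error(lowpass_filter(slow, 60, 100), "Nyquist")
})

test_that("breath segmentation finds inhalation-to-inhalation cycles", {
  t <- seq(0, 60, by = 1 / 60)
  x <- sin(2 * pi * 0.1 * t)
  br <- segment_breaths(x, 60)
  expect_equal(nrow(br), 5L)
  expect_equal(br$start[1] / 60, 2.5, tolerance = 0.02)
  expect_warning(empty <- segment_breaths(rep(1, 600), 60), "flat")
  expect_equal(nrow(empty), 0L)
})

test_that("segmentation matches generator truth under variable cycle lengths", {
  set.seed(21)
  periods <- c(8.6, 11.3, 9.4, 12.0, 8.1)
  fr <- 100
  breaks <- c(0, cumsum(periods))
  tt <- seq(0, sum(periods), by = 1 / fr)
  b <- pmin(findInterval(tt, breaks, rightmost.closed = TRUE), 5)
  phase <- (b - 1) + (tt - breaks[b]) / periods[b]
  x <- cos(2 * pi * phase)          # maxima at the true boundaries
  br <- segment_breaths(x, fr)
  truth <- round(breaks * fr) + 1
  found <- sort(unique(c(br$start, br$end)))
  interior <- truth[truth > 1 & truth < length(x)]
  expect_true(all(vapply(interior, function(p) {
    any(abs(found - p) <= 2)
  }, logical(1))))
})

test_that("cycle resampling is phase-normalizing, zero-mean and idempotent", {
  ramp <- seq(0, 10, length.out = 200)
  rc <- resample_cycle(ramp)
  expect_length(rc, 100)
  expect_equal(mean(rc), 0, tolerance = 1e-12)
  expect_equal(diff(range(rc)), 10, tolerance = 1e-9)
  expect_equal(max(abs(diff(diff(rc)))), 0, tolerance = 1e-9)  # equal spacing
  expect_equal(as.numeric(resample_cycle(rep(2, 50))), rep(0, 100))
  # two cycles of different durations sampling one phase-locked waveform
  wave <- function(ph) cbind(5 * sin(2 * pi * ph), 2 * cos(2 * pi * ph),
                             ph * 0)
  c1 <- resample_cycle(wave(seq(0, 1, length.out = 163)))
  c2 <- resample_cycle(wave(seq(0, 1, length.out = 977)))
  expect_lt(max(abs(unclass(c1) - unclass(c2))), 0.1)
  # idempotence: resampling an already-resampled cycle is the identity
  again <- resample_cycle(unclass(c1))
  expect_equal(unclass(again), unclass(c1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(resample_cycle(1:5), "too short")
})

test_that("cycle averaging is a pointwise mean and sd", {
  m <- matrix(stats::rnorm(300), 100, 3)
  one <- average_cycles(list(m))
  expect_equal(one$mean, m, ignore_attr = TRUE)
  expect_true(all(one$sd == 0))
  mirrored <- average_cycles(list(m, -m))
  expect_equal(max(abs(mirrored$mean)), 0)
  # 5 noisy replicates of a known waveform: mean close to truth pointwise
  set.seed(61)
  truthw <- cbind(10 * sin(2 * pi * (0:99) / 99), 0, 0)
  reps <- lapply(1:5, function(i) truthw + matrix(stats::rnorm(300, 0, 0.5),
                                                  100, 3))
  avg <- average_cycles(reps)
  bound <- 2 * pmax(avg$sd, 1e-6) / sqrt(5)
  frac_in <- mean(abs(avg$mean - truthw) <= bound)
  # with n = 5 the sd is itself noisy; t-distribution coverage of a
  # +/- 2 sd/sqrt(5) band is ~88%
  expect_gt(frac_in, 0.8)
  expect_error(average_cycles(list(m, m[1:50, ])), "same shape")
})

test_that("total rotation axis reads pure and mixed oscillations correctly", {
  ph <- seq(0, 1, length.out = 100)
  # pure bucket (Z) oscillation, 20 deg amplitude
  z <- 20 * (1 - cos(2 * pi * ph)) / 2
  cyc <- resample_cycle(cbind(z, 0, 0))
  iv <- total_rotation_axis(average_cycles(list(cyc)))
  expect_equal(abs(iv$axis[3]), 1, tolerance = 1e-9)
  expect_equal(iv$theta_deg, 20, tolerance = 0.01)
  expect_equal(as.numeric(iv$plane_angles), c(0, 0, 90), tolerance = 1e-3)
  # equal 10-degree amplitudes on all three Euler components: expected
  # values from a brute-force composition oracle
  s <- 10 * (1 - cos(2 * pi * ph)) / 2
  cyc3 <- resample_cycle(cbind(s, s, s))
  iv3 <- total_rotation_axis(average_cycles(list(cyc3)))
  oracle <- matrix_to_axis_angle(relative_rotation(
    euler_to_matrix(c(0, 0, 0)), euler_to_matrix(c(10, 10, 10))))
  expect_lt(axis_line_angle(iv3$axis, oracle$axis), 0.1)
  expect_equal(iv3$theta_deg, oracle$theta_deg, tolerance = 0.02)
  expect_lt(diff(range(iv3$plane_angles)), 12)  # near-equal components
  # sign alignment against a reference axis
  ivr <- total_rotation_axis(average_cycles(list(cyc)),
                             reference_axis = c(0, 0, -1))
  expect_lte(ivr$axis[3], 0)
  # sub-threshold rotation flags a degenerate axis
  tiny <- resample_cycle(cbind(0.2 * (1 - cos(2 * pi * ph)) / 2, 0, 0))
  expect_warning(ivd <- total_rotation_axis(average_cycles(list(tiny))),
                 "unreliable")
  expect_true(ivd$degenerate)
})

test_that("predicted-vs-measured regression matches the OLS closed form", {
  d <- data.frame(plane = "sagittal", predicted = c(10, 20, 30, 40),
                  measured = c(10, 20, 30, 40))
  # lm warns about an essentially perfect fit on exact data; that is the
  # point of the example
  r <- suppressWarnings(regress_predicted_vs_measured(d))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # seeded noisy line y = 0.8 x + 10, sigma = 2, n = 12: estimates within
  # their own 95% CI of truth, and equal to an independent closed-form fit
  set.seed(71)
  x <- seq(5, 60, length.out = 12)
  y <- 0.8 * x + 10 + stats::rnorm(12, 0, 2)
  r2 <- regress_predicted_vs_measured(
    data.frame(plane = "coronal", predicted = x, measured = y))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r2$slope, beta, tolerance = 1e-12)
  expect_equal(r2$intercept, mean(y) - beta * mean(x), tolerance = 1e-10)
  se <- sqrt(sum((y - (r2$intercept + r2$slope * x))^2) / 10 /
               sum((x - mean(x))^2))
  expect_lt(abs(r2$slope - 0.8), stats::qt(0.975, 10) * se)
  expect_error(regress_predicted_vs_measured(
    data.frame(plane = "a", predicted = rep(3, 5), measured = 1:5)),
    "degenerate")
  expect_error(regress_predicted_vs_measured(
    data.frame(plane = "a", predicted = 1:2, measured = 1:2)), "3 pairs")
})
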