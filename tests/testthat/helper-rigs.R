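# Shared fixtures, built in code.

# Uniform-ish random rotation: random axis, random angle.
random_rotation <- function() {
  ax <- stats::rnorm(3)
  axis_angle_to_matrix(ax / sqrt(sum(ax^2)), stats::runif(1, 0, 180))
}

random_euler <- function() {
  c(stats::runif(1, -179, 179), stats::runif(1, -89, 89),
    stats::runif(1, -179, 179))
}

# Acute angle between two axis lines (sign-ambiguous), degrees.
axis_line_angle <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}

# A well-conditioned 4-marker reference cloud spanning ~15 mm
# (regular tetrahedron, edge 15 mm).
tetra_markers <- function(edge = 15) {
  pos <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    edge / (2 * sqrt(2))
  rownames(pos) <- paste0("m", 1:4)
  pos
}

# Trajectory set from a list of per-frame marker matrices.
traj_from_frames <- function(frames, frame_rate) {
  ids <- rownames(frames[[1L]])
  arr <- array(NA_real_, c(length(frames), 3L, length(ids)),
               dimnames = list(NULL, c("x", "y", "z"), ids))
  for (f in seq_along(frames)) arr[f, , ] <- t(frames[[f]])
  trajectory_set(arr, frame_rate)
}

# Synthetic pose series following prescribed per-frame rotations about an
# anchor (translation consistent with rotation about that point).
pose_series_about <- function(body_id, rotations, anchor, frame_rate = 100) {
  nf <- dim(rotations)[3L]
  tra <- t(vapply(seq_len(nf), function(f) {
    as.numeric(anchor - rotations[, , f] %*% anchor)
  }, numeric(3)))
  structure(list(body_id = body_id, rotations = rotations,
                 translations = tra, rms = rep(0, nf),
                 present = rep(TRUE, nf), frame_rate = frame_rate),
            class = "pose_series")
}

static_pose_series <- function(body_id, nf, frame_rate = 100) {
  rot <- array(rep(diag(3), nf), c(3L, 3L, nf))
  pose_series_about(body_id, rot, c(0, 0, 0), frame_rate)
}

# Small simulation used by several tests: default model, hinge
# costovertebral joints about the anatomical axes.
small_sim <- function(seed = 11, n_breaths = 3L, frame_rate = 60,
                      noise_sd_mm = 0, model = build_ribcage()) {
  sc <- default_motion_script(model, seed = seed, n_breaths = n_breaths,
                              frame_rate = frame_rate,
                              noise_sd_mm = noise_sd_mm)
  simulate_breathing(model, sc)
}
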