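JOINT_ARCHETYPES <- c("costovertebral", "sternocostal",
                      "dorsal_intracostal", "ventral_intracostal")

#' Define a joint for kinematic analysis
#'
#' Binds a proximal and a distal body with one of the four ribcage joint
#' archetypes, an anchor (joint center) and the data needed to construct
#' the joint coordinate system (JCS) at the zero pose. The zero pose is the
#' configuration at maximum inhalation: all joint angles are zero there.
#'
#' @param joint_id character scalar.
#' @param archetype one of `"costovertebral"`, `"sternocostal"`,
#'   `"dorsal_intracostal"`, `"ventral_intracostal"`.
#' @param proximal_body_id,distal_body_id body ids (must differ).
#' @param anchor numeric 3-vector: joint center in world coordinates at the
#'   zero pose (mm). For costovertebral joints the documented default is the
#'   midpoint of the parapophysis and diapophysis.
#' @param zero_pose_frame frame index (1-based) of the zero pose, or `NA`
#'   to resolve later (to the detected inhalation peaks). A vector of
#'   frames anchors the zero pose on the average pose across them.
#' @param distal_axis_points intracostal archetypes only: 2 x 3 matrix, two
#'   points along the distal rib's long axis (world, zero pose).
#' @param proximal_plane_points intracostal archetypes only: 3 x 3 matrix,
#'   three non-collinear points spanning the proximal rib's plane (world,
#'   zero pose).
#' @return object of class `joint_definition`.
#' @export
joint_definition <- function(joint_id, archetype, proximal_body_id,
                             distal_body_id, anchor, zero_pose_frame = NA,
                             distal_axis_points = NULL,
                             proximal_plane_points = NULL) {
  archetype <- match.arg(archetype, JOINT_ARCHETYPES)
  stopifnot(is.character(joint_id), length(joint_id) == 1L,
            proximal_body_id != distal_body_id,
            is.numeric(anchor), length(anchor) == 3L, all(is.finite(anchor)))
  if (archetype %in% c("dorsal_intracostal", "ventral_intracostal")) {
    if (is.null(distal_axis_points) || is.null(proximal_plane_points)) {
      stop("intracostal joints need distal_axis_points and proximal_plane_points")
    }
    distal_axis_points <- as.matrix(distal_axis_points)
    proximal_plane_points <- as.matrix(proximal_plane_points)
    stopifnot(all(dim(distal_axis_points) == c(2L, 3L)),
              all(dim(proximal_plane_points) == c(3L, 3L)))
  }
  structure(list(joint_id = joint_id, archetype = archetype,
                 proximal_body_id = proximal_body_id,
                 distal_body_id = distal_body_id,
                 anchor = as.numeric(anchor),
                 zero_pose_frame = zero_pose_frame,
                 distal_axis_points = distal_axis_points,
                 proximal_plane_points = proximal_plane_points),
            class = "joint_definition")
}

# World-frame JCS orientation (columns X, Y, Z) at the zero pose.
jcs_zero_orientation <- function(defn) {
  if (defn$archetype %in% c("costovertebral", "sternocostal")) {
    # Body-plane axes of the column-aligned frame: X medio-lateral (left
    # positive), Y cranio-caudal (caudal positive), Z dorso-ventral (dorsal
    # positive). Z-rotation is then bucket handle, Y calliper, X pump handle.
    return(diag(3))
  }
  p <- defn$distal_axis_points
  X <- p[2L, ] - p[1L, ]
  if (sqrt(sum(X^2)) < 1e-9) stop("degenerate distal long axis")
  X <- normalize3(X)
  q <- defn$proximal_plane_points
  n <- crossprod3(q[2L, ] - q[1L, ], q[3L, ] - q[1L, ])
  if (sqrt(sum(n^2)) < 1e-9) {
    stop("joint '", defn$joint_id, "': proximal plane points are collinear")
  }
  n <- normalize3(n)
  if (abs(sum(n * X)) > 1 - 1e-9) {
    stop("joint '", defn$joint_id,
         "': distal axis is normal to the proximal plane; Z is undefined")
  }
  # Z must lie in the proximal rib plane and be orthogonal to X: n x X is
  # orthogonal to both n (hence in-plane) and X. Orient Z dorsally.
  Z <- normalize3(crossprod3(n, X))
  if (Z[3L] < 0) Z <- -Z
  Y <- crossprod3(Z, X)
  Q <- cbind(X = X, Y = Y, Z = Z)
  assert_rotation_matrix(Q, tol = 1e-9)
  Q
}

pose_at <- function(ps, frames) {
  ok <- frames >= 1L & frames <= length(ps$present) & ps$present[frames]
  if (!all(ok)) {
    stop("body '", ps$body_id, "': no pose at frame ",
         paste(frames[!ok], collapse = ", "))
  }
  if (length(frames) == 1L) {
    return(list(R = ps$rotations[, , frames], t = ps$translations[frames, ]))
  }
  # Average pose over several frames: chordal mean of the rotations
  # (entrywise mean projected onto the nearest proper rotation) and the
  # mean translation. Used to anchor a zero pose on a recurring posture
  # (every inhalation peak) instead of one noisy instant.
  M <- apply(ps$rotations[, , frames, drop = FALSE], c(1L, 2L), mean)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  list(R = s$u %*% diag(c(1, 1, d)) %*% t(s$v),
       t = colMeans(ps$translations[frames, , drop = FALSE]))
}

#' Build and attach a joint coordinate system
#'
#' Constructs the JCS axes in world coordinates at the zero pose
#' (archetype-specific rules, right-handed), then rigidly attaches one copy
#' of the frame to the proximal body and one congruent copy to the distal
#' body, both coincident at the anchor. At all other frames the joint
#' rotation is the relative orientation of these two attached frames.
#'
#' Archetype rules at the zero pose: costovertebral and sternocostal JCSs
#' use the body-plane axes (Z dorso-ventral, Y cranio-caudal, X
#' medio-lateral); intracostal JCSs align X along the distal rib's long
#' axis, place Z in the proximal rib's plane orthogonal to X (dorsal
#' positive), and take Y = Z x X.
#'
#' @param defn a [joint_definition()] with a resolved `zero_pose_frame`.
#' @param prox,dist [fit_pose_series()] results for the proximal and distal
#'   bodies.
#' @return object of class `jcs`: the definition plus local-frame
#'   attachments of axes and anchor for both bodies.
#' @export
build_jcs <- function(defn, prox, dist) {
  stopifnot(inherits(defn, "joint_definition"),
            inherits(prox, "pose_series"), inherits(dist, "pose_series"))
  f0 <- defn$zero_pose_frame
  if (any(is.na(f0))) stop("zero_pose_frame is unresolved for joint '",
                           defn$joint_id, "'")
  Q0 <- jcs_zero_orientation(defn)
  Pp <- pose_at(prox, f0)
  Pd <- pose_at(dist, f0)
  structure(list(defn = defn,
                 Q_prox = crossprod(Pp$R, Q0),
                 Q_dist = crossprod(Pd$R, Q0),
                 anchor_prox = as.numeric(crossprod(Pp$R, defn$anchor - Pp$t)),
                 anchor_dist = as.numeric(crossprod(Pd$R, defn$anchor - Pd$t))),
            class = "jcs")
}

#' Extract per-frame joint angles and translations
#'
#' For each frame where both bodies have a pose, computes the rotation of
#' the distal-attached JCS frame relative to the proximal-attached one,
#' decomposed as intrinsic ZYX Euler angles, and the displacement of the
#' distal anchor expressed in the proximal JCS frame. Both are exactly zero
#' at the zero pose by construction. Frames where either pose is missing
#' yield `NA` rows.
#'
#' @param jcs a [build_jcs()] result.
#' @param prox,dist the two bodies' [fit_pose_series()] results.
#' @return data.frame of class `joint_angle_series` with columns `frame`,
#'   `z_deg`, `y_deg`, `x_deg`, `tx`, `ty`, `tz`; attributes `joint_id`,
#'   `labels` (semantic motion names per axis) and `frame_rate`.
#' @export
extract_joint_angles <- function(jcs, prox, dist) {
  stopifnot(inherits(jcs, "jcs"))
  nf <- min(length(prox$present), length(dist$present))
  ang <- matrix(NA_real_, nf, 3L)
  tra <- matrix(NA_real_, nf, 3L)
  for (f in seq_len(nf)) {
    if (!prox$present[f] || !dist$present[f]) next
    Rp <- prox$rotations[, , f] %*% jcs$Q_prox
    Rd <- dist$rotations[, , f] %*% jcs$Q_dist
    ang[f, ] <- matrix_to_euler(crossprod(Rp, Rd))
    ad <- dist$rotations[, , f] %*% jcs$anchor_dist + dist$translations[f, ]
    ap <- prox$rotations[, , f] %*% jcs$anchor_prox + prox$translations[f, ]
    tra[f, ] <- as.numeric(crossprod(Rp, ad - ap))
  }
  out <- data.frame(frame = seq_len(nf),
                    z_deg = ang[, 1L], y_deg = ang[, 2L], x_deg = ang[, 3L],
                    tx = tra[, 1L], ty = tra[, 2L], tz = tra[, 3L])
  attr(out, "joint_id") <- jcs$defn$joint_id
  attr(out, "labels") <- semantic_labels(jcs$defn$archetype)
  attr(out, "frame_rate") <- prox$frame_rate
  class(out) <- c("joint_angle_series", class(out))
  out
}

#' Semantic motion labels for a joint archetype
#'
#' Maps the Z, Y and X rotation axes of a JCS onto anatomical motion names:
#' for costovertebral and sternocostal joints, Z-rotation is bucket handle,
#' Y-rotation calliper and X-rotation pump handle motion; for the
#' intracostal joints, Z measures abduction-adduction and Y
#' depression-elevation of the distal rib, and X its long-axis rotation.
#'
#' @param archetype joint archetype string.
#' @return named character vector with elements `Z`, `Y`, `X`.
#' @export
semantic_labels <- function(archetype) {
  if (!is.character(archetype) || length(archetype) != 1L ||
      !archetype %in% JOINT_ARCHETYPES) {
    stop("unknown joint archetype: ", paste(archetype, collapse = ", "))
  }
  if (archetype %in% c("costovertebral", "sternocostal")) {
    c(Z = "bucket handle", Y = "calliper", X = "pump handle")
  } else {
    c(Z = "abduction-adduction", Y = "depression-elevation",
      X = "long-axis rotation")
  }
}
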