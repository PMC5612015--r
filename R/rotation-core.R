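# Angle unit helpers. All public interfaces speak degrees (the convention of
# the motion-analysis literature); radians are confined to function bodies.
deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

# Wrap an angle in degrees into (-180, 180].
wrap_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

normalize3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

#' Validate a rotation matrix
#'
#' Checks that `R` is a proper rotation: 3x3, orthonormal and with
#' determinant +1.
#'
#' @param R numeric 3x3 matrix.
#' @param tol numeric tolerance on orthonormality and determinant.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
assert_rotation_matrix <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    stop("R must be a finite 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("R is not orthonormal within tolerance ", tol)
  }
  if (abs(det(R) - 1) > tol) {
    stop("R is not a proper rotation (det != +1)")
  }
  invisible(TRUE)
}

elemental_rotation <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- deg2rad(angle_deg)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Intrinsic ZYX Euler angles to rotation matrix
#'
#' Composes the rotation `R = Rz %*% Ry %*% Rx` acting on column vectors:
#' first a rotation about the body z-axis, then about the once-rotated
#' y-axis, then about the twice-rotated x-axis. This is the intrinsic
#' z-y'-x'' convention used throughout the package for joint coordinate
#' systems: at a costovertebral joint the Z angle is bucket handle motion,
#' Y is calliper motion and X is pump handle motion.
#'
#' @param angles numeric length 3, `c(z_deg, y_deg, x_deg)` in degrees.
#' @return 3x3 rotation matrix.
#' @seealso [matrix_to_euler()] for the inverse.
#' @examples
#' euler_to_matrix(c(90, 0, 0))  # maps +x to +y
#' @export
euler_to_matrix <- function(angles) {
  if (!is.numeric(angles) || length(angles) != 3L || !all(is.finite(angles))) {
    stop("angles must be three finite numbers c(z_deg, y_deg, x_deg)")
  }
  elemental_rotation("z", angles[[1L]]) %*%
    elemental_rotation("y", angles[[2L]]) %*%
    elemental_rotation("x", angles[[3L]])
}

#' Rotation matrix to intrinsic ZYX Euler angles
#'
#' Inverts [euler_to_matrix()]. The returned triple is canonical:
#' `y_deg` in \[-90, 90\] and `z_deg`, `x_deg` in (-180, 180\]. At gimbal
#' lock (`|y_deg| = 90`, where z and x become degenerate) the x angle is set
#' to 0, the full degeneracy is absorbed into z, and the result carries the
#' attribute `gimbal_lock = TRUE`.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric `c(z_deg, y_deg, x_deg)`, possibly with attribute
#'   `gimbal_lock`.
#' @export
matrix_to_euler <- function(R) {
  assert_rotation_matrix(R)
  sy <- -R[3L, 1L]
  sy <- max(-1, min(1, sy))
  cy <- sqrt(max(0, 1 - sy * sy))
  if (cy < 1e-9) {
    # |y| = 90 deg: only (z -/+ x) is determined; convention x = 0.
    out <- c(
      z_deg = rad2deg(atan2(-R[1L, 2L], R[2L, 2L])),
      y_deg = rad2deg(asin(sy)),
      x_deg = 0
    )
    out[c("z_deg", "x_deg")] <- wrap_deg(out[c("z_deg", "x_deg")])
    attr(out, "gimbal_lock") <- TRUE
    return(out)
  }
  out <- c(
    z_deg = rad2deg(atan2(R[2L, 1L], R[1L, 1L])),
    y_deg = rad2deg(asin(sy)),
    x_deg = rad2deg(atan2(R[3L, 2L], R[3L, 3L]))
  )
  out[c("z_deg", "x_deg")] <- wrap_deg(out[c("z_deg", "x_deg")])
  out
}

#' Axis-angle to rotation matrix (Rodrigues' formula)
#'
#' @param axis numeric length 3; normalized internally.
#' @param theta_deg rotation magnitude in degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_to_matrix <- function(axis, theta_deg) {
  if (!is.numeric(axis) || length(axis) != 3L || !all(is.finite(axis))) {
    stop("axis must be a finite 3-vector")
  }
  u <- normalize3(axis)
  th <- deg2rad(theta_deg)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to axis-angle
#'
#' Decomposes a rotation into a magnitude `theta_deg` in \[0, 180\] about a
#' unit axis, via quaternion extraction (well-conditioned at all angles).
#' Without a `reference`, the returned pair is faithful: rotating by
#' `theta_deg` about `axis` reproduces `R` (the axis sign is only
#' canonicalized at the 0- and 180-degree ambiguities, where both signs
#' describe the same rotation). Supplying `reference` instead treats the
#' axis as an unsigned line and flips it so its dot product with that
#' vector is non-negative — the form used to compare in vivo axes against
#' anatomical axes; the flipped pair may then describe the reversed
#' rotation sense.
#'
#' @param R 3x3 rotation matrix.
#' @param reference optional 3-vector used to fix the axis sign.
#' @return list with `axis` (unit 3-vector), `theta_deg`, and `degenerate`
#'   (`TRUE` when `R` is the identity and the axis is conventional).
#' @export
matrix_to_axis_angle <- function(R, reference = NULL) {
  assert_rotation_matrix(R)
  # Shepperd's method: extract the unit quaternion via the largest of
  # (trace, R11, R22, R33), which is well-conditioned for every rotation,
  # including near 0 and near 180 degrees.
  tr <- sum(diag(R))
  if (tr >= max(diag(R))) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4,
           (R[3L, 2L] - R[2L, 3L]) / s,
           (R[1L, 3L] - R[3L, 1L]) / s,
           (R[2L, 1L] - R[1L, 2L]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3L + 1L
    k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1L] <- (R[k, j] - R[j, k]) / s
    q[i + 1L] <- s / 4
    q[j + 1L] <- (R[j, i] + R[i, j]) / s
    q[k + 1L] <- (R[k, i] + R[i, k]) / s
  }
  q <- q / sqrt(sum(q * q))
  if (q[1L] < 0) q <- -q                   # theta in [0, 180]
  vn <- sqrt(sum(q[2:4]^2))
  theta <- 2 * atan2(vn, q[1L])
  degenerate <- vn < 1e-12
  axis <- if (degenerate) c(1, 0, 0) else q[2:4] / vn
  if (!is.null(reference)) {
    # Axis treated as an unsigned line for comparison against an
    # anatomical reference; the flipped pair may describe the reversed
    # rotation sense.
    if (sum(axis * reference) < 0) axis <- -axis
  } else if ((degenerate || theta > pi - 1e-9) &&
             axis[which.max(abs(axis))] < 0) {
    # Only at 0 and 180 degrees are both signs the same rotation; pick
    # the canonical one there.
    axis <- -axis
  }
  list(axis = axis, theta_deg = rad2deg(theta), degenerate = degenerate)
}

#' Relative rotation between two orientations
#'
#' Returns the rotation that carries orientation `Ra` onto `Rb`, i.e.
#' `Ra^-1 %*% Rb`, so that `Ra %*% relative_rotation(Ra, Rb) == Rb`.
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return 3x3 rotation matrix.
#' @export
relative_rotation <- function(Ra, Rb) {
  assert_rotation_matrix(Ra)
  assert_rotation_matrix(Rb)
  crossprod(Ra, Rb)
}

#' Angular distance between two rotations
#'
#' The magnitude, in degrees, of the relative rotation `Ra^-1 Rb`;
#' a metric on SO(3) used to quantify orientation error.
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return angle in degrees in \[0, 180\].
#' @export
rotation_angle_deg <- function(Ra, Rb) {
  # ||Ra - Rb||_F^2 = 8 sin^2(theta/2): the asin form keeps full precision
  # for small angles, where acos(trace) loses half the significant digits.
  d <- sqrt(sum((Ra - Rb)^2))
  rad2deg(2 * asin(min(1, d / (2 * sqrt(2)))))
}

#' Angles between a unit vector and the three anatomical body planes
#'
#' In the column-aligned anatomical frame (x left-lateral, y caudal,
#' z dorsal) the sagittal plane is YZ (normal x), the coronal plane is XZ
#' (normal y) and the transverse plane is XY (normal z). The angle between a
#' line and a plane is `asin(|component along the plane normal|)`, in
#' \[0, 90\] degrees. For any unit vector the squared sines of the three
#' plane angles sum to 1.
#'
#' @param v unit 3-vector (checked to 1e-6).
#' @return named numeric `c(sagittal, coronal, transverse)` in degrees.
#' @export
vector_plane_angles <- function(v) {
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v))) {
    stop("v must be a finite 3-vector")
  }
  if (abs(sqrt(sum(v * v)) - 1) > 1e-6) {
    stop("v must be a unit vector (|v| = 1 to 1e-6)")
  }
  a <- rad2deg(asin(pmin(1, abs(v))))
  c(sagittal = a[[1L]], coronal = a[[2L]], transverse = a[[3L]])
}
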