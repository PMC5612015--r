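#' Ternary composition of a rotation axis
#'
#' Expresses a 3D axis as relative percentages of its absolute x, y and z
#' components, `100 * |a_i| / sum(|a|)`. In the column-aligned anatomical
#' frame these map onto the expected relative contributions of pump handle
#' (x), calliper (y) and bucket handle (z) motion. Absolute values are used
#' because a composition must be non-negative; sign only encodes axis
#' polarity, which is fixed separately.
#'
#' @param axis numeric 3-vector (not necessarily unit length).
#' @return named numeric `c(x, y, z)` summing to 100.
#' @export
ternary_composition <- function(axis) {
  stopifnot(is.numeric(axis), length(axis) == 3L, all(is.finite(axis)))
  a <- abs(axis)
  s <- sum(a)
  if (s == 0) stop("zero axis has no ternary composition")
  setNames(100 * a / s, c("x", "y", "z"))
}

#' Predicted costovertebral hinge axis from vertebral landmarks
#'
#' The bicondylar costovertebral joint is hypothesized to act as a hinge
#' whose axis runs through the two vertebral facets that receive the rib
#' head: the parapophysis (capitulum) and diapophysis (tuberculum). The
#' predicted axis is simply the normalized landmark difference
#' `A = (D - P) / |D - P|`, expressed in the column-aligned frame
#' (x left-lateral, y caudal, z dorsal). The result is invariant to global
#' translation and uniform scaling of the landmarks.
#'
#' @param P,D numeric 3-vectors: parapophysis and diapophysis coordinates
#'   (mm) in the column-aligned frame.
#' @param vertebra_id optional identifier used in error messages and output.
#' @param side `"left"` or `"right"`; right-side landmarks are mirrored to
#'   the left convention (x negated) before the axis is computed, so one
#'   sign convention holds across animals.
#' @param guard_mm minimum landmark separation (default 0.5 mm) below which
#'   the axis is considered degenerate.
#' @return list of class `predicted_axis`: `vertebra_id`, `axis` (unit
#'   3-vector), `ternary` (percent), `plane_angles` (degrees).
#' @export
compute_axis <- function(P, D, vertebra_id = NA, side = c("left", "right"),
                         guard_mm = 0.5) {
  side <- match.arg(side)
  stopifnot(is.numeric(P), length(P) == 3L, is.numeric(D), length(D) == 3L,
            all(is.finite(c(P, D))))
  if (side == "right") {
    P[1L] <- -P[1L]
    D[1L] <- -D[1L]
  }
  v <- D - P
  if (sqrt(sum(v^2)) <= guard_mm) {
    stop("vertebra ", vertebra_id, ": parapophysis and diapophysis are ",
         "closer than ", guard_mm, " mm; axis is degenerate")
  }
  axis <- normalize3(v)
  structure(list(vertebra_id = vertebra_id, axis = axis,
                 ternary = ternary_composition(axis),
                 plane_angles = vector_plane_angles(axis)),
            class = "predicted_axis")
}

#' Predicted axes for a table of vertebral landmarks
#'
#' @param landmarks data.frame with columns `vertebra_id`, `side`,
#'   `landmark` (`"parapophysis"` / `"diapophysis"`), `x`, `y`, `z` (mm, in
#'   the column-aligned frame).
#' @return data.frame, one row per vertebra: axis components, ternary
#'   percentages and body-plane angles.
#' @export
compute_axes <- function(landmarks) {
  need <- c("vertebra_id", "side", "landmark", "x", "y", "z")
  stopifnot(all(need %in% names(landmarks)))
  rows <- lapply(split(landmarks, landmarks$vertebra_id), function(d) {
    p <- d[d$landmark == "parapophysis", , drop = FALSE]
    q <- d[d$landmark == "diapophysis", , drop = FALSE]
    if (nrow(p) != 1L || nrow(q) != 1L) {
      stop("vertebra ", d$vertebra_id[1L],
           ": exactly one parapophysis and one diapophysis are required")
    }
    ax <- compute_axis(as.numeric(p[, c("x", "y", "z")]),
                       as.numeric(q[, c("x", "y", "z")]),
                       vertebra_id = d$vertebra_id[1L],
                       side = as.character(p$side))
    data.frame(vertebra_id = ax$vertebra_id,
               axis_x = ax$axis[1L], axis_y = ax$axis[2L], axis_z = ax$axis[3L],
               ternary_x = ax$ternary[["x"]], ternary_y = ax$ternary[["y"]],
               ternary_z = ax$ternary[["z"]],
               sagittal_deg = ax$plane_angles[["sagittal"]],
               coronal_deg = ax$plane_angles[["coronal"]],
               transverse_deg = ax$plane_angles[["transverse"]])
  })
  out <- do.call(rbind, rows)
  out[order(out$vertebra_id), , drop = FALSE]
}

#' Summarize ternary compositions across individuals
#'
#' Component-wise mean and standard deviation of the ternary axis
#' composition per joint across individuals (the per-joint error bars of a
#' multi-animal ternary plot).
#'
#' @param axes data.frame with columns `individual`, `vertebra_id`,
#'   `ternary_x`, `ternary_y`, `ternary_z` (e.g. stacked [compute_axes()]
#'   outputs with an `individual` column added).
#' @return data.frame per vertebra: `n`, means and SDs of the three
#'   components; mean compositions are checked to still sum to 100.
#' @export
summarize_axes <- function(axes) {
  need <- c("individual", "vertebra_id", "ternary_x", "ternary_y", "ternary_z")
  stopifnot(all(need %in% names(axes)))
  if (nrow(axes) == 0L) stop("empty axis table")
  rows <- lapply(split(axes, axes$vertebra_id), function(d) {
    m <- colMeans(d[, c("ternary_x", "ternary_y", "ternary_z")])
    s <- if (nrow(d) > 1L) {
      apply(d[, c("ternary_x", "ternary_y", "ternary_z")], 2L, sd)
    } else c(0, 0, 0)
    if (abs(sum(m) - 100) > 1e-6) {
      warning("vertebra ", d$vertebra_id[1L],
              ": mean composition drifted from 100")
    }
    data.frame(vertebra_id = d$vertebra_id[1L], n = nrow(d),
               mean_x = m[[1L]], mean_y = m[[2L]], mean_z = m[[3L]],
               sd_x = s[[1L]], sd_y = s[[2L]], sd_z = s[[3L]])
  })
  out <- do.call(rbind, rows)
  out[order(out$vertebra_id), , drop = FALSE]
}

#' Align a landmark cloud to the column frame by principal axes
#'
#' Rotates (and centers) a vertebral landmark cloud so that its first
#' principal axis lies along +y (the cranio-caudal column direction), its
#' third along +x, and the remaining axis along +z, mimicking a
#' principal-axes registration of the rib-bearing vertebral column. Signs
#' are disambiguated with user-supplied approximate caudal and dorsal
#' directions in the input frame.
#'
#' @param points numeric N x 3 matrix of landmark coordinates (mm).
#' @param caudal_hint,dorsal_hint approximate directions of +y (caudal) and
#'   +z (dorsal) in the input frame; defaults assume the input is already
#'   roughly column-aligned.
#' @return list with `points` (aligned, centered N x 3), `rotation`
#'   (3x3, maps centered input coordinates to aligned ones).
#' @export
align_column_frame <- function(points, caudal_hint = c(0, 1, 0),
                               dorsal_hint = c(0, 0, 1)) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 3L)
  ctr <- colMeans(points)
  pc <- prcomp(points, center = TRUE, scale. = FALSE)
  ey <- pc$rotation[, 1L]                       # column direction
  if (sum(ey * caudal_hint) < 0) ey <- -ey
  ez <- pc$rotation[, 3L]
  ez <- normalize3(ez - ey * sum(ez * ey))
  if (sum(ez * dorsal_hint) < 0) ez <- -ez
  ex <- crossprod3(ey, ez)
  Rw <- rbind(x = ex, y = ey, z = ez)           # rows = new basis
  aligned <- sweep(points, 2L, ctr) %*% t(Rw)
  colnames(aligned) <- c("x", "y", "z")
  list(points = aligned, rotation = Rw)
}

# 3-vector cross product.
crossprod3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
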