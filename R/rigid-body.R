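#' Reference marker set for one rigid body
#'
#' Bundles the CT/model-frame coordinates of the radio-opaque markers
#' implanted in one bone (or one declared group of bones, e.g. a section of
#' two or three vertebrae animated as a single rigid body).
#'
#' @param body_id character scalar.
#' @param positions numeric M x 3 matrix of marker coordinates (mm) with
#'   unique rownames giving marker ids. At least 3 non-collinear markers are
#'   required (collinearity test: second singular value of the centered
#'   positions must exceed 1e-6 mm).
#' @return object of class `marker_set`.
#' @export
marker_set <- function(body_id, positions) {
  stopifnot(is.character(body_id), length(body_id) == 1L)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !all(is.finite(positions))) {
    stop("positions must be a finite M x 3 matrix")
  }
  ids <- rownames(positions)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("positions must have unique rownames (marker ids)")
  }
  if (nrow(positions) < 3L) {
    stop("body '", body_id, "': at least 3 markers are required")
  }
  colnames(positions) <- c("x", "y", "z")
  sv <- svd(scale(positions, scale = FALSE))$d
  if (sv[2L] <= 1e-6) {
    stop("body '", body_id, "': markers are collinear, pose is unobservable")
  }
  structure(list(body_id = body_id, positions = positions),
            class = "marker_set")
}

#' Per-frame 3D marker trajectories
#'
#' Container for reconstructed 3D marker positions over time, as exported by
#' XMALab (frame rate 60 or 100 Hz in the original recordings). Missing
#' observations are encoded as `NA`, never as zeros.
#'
#' @param positions numeric array `frames x 3 x markers` with marker ids as
#'   the third dimnames, or a named list of `frames x 3` matrices.
#' @param frame_rate sampling rate, Hz.
#' @return object of class `trajectory_set`.
#' @export
trajectory_set <- function(positions, frame_rate) {
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1L, frame_rate > 0)
  if (is.list(positions)) {
    ids <- names(positions)
    if (is.null(ids)) stop("positions list must be named by marker id")
    nf <- nrow(positions[[1L]])
    arr <- array(NA_real_, c(nf, 3L, length(positions)),
                 dimnames = list(NULL, c("x", "y", "z"), ids))
    for (i in seq_along(positions)) arr[, , i] <- as.matrix(positions[[i]])
    positions <- arr
  }
  if (length(dim(positions)) != 3L || dim(positions)[2L] != 3L) {
    stop("positions must be a frames x 3 x markers array")
  }
  if (is.null(dimnames(positions)[[3L]])) {
    stop("positions must carry marker ids as third dimnames")
  }
  structure(list(positions = positions, frame_rate = frame_rate),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trajectory_set> %d frames x %d markers @ %g Hz\n",
              d[1L], d[3L], x$frame_rate))
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[1L]
marker_ids <- function(traj) dimnames(traj$positions)[[3L]]

# Marker coordinates of one frame as an M x 3 matrix (rows = marker ids).
frame_positions <- function(traj, frame, ids = marker_ids(traj)) {
  m <- t(traj$positions[frame, , ids, drop = TRUE])
  if (length(ids) == 1L) m <- matrix(m, 1L, 3L)
  rownames(m) <- ids
  m
}

#' Least-squares rigid transform between two point sets
#'
#' Solves the orthogonal Procrustes problem: the rotation `R` (proper,
#' det = +1) and translation `t` minimizing the sum of squared distances
#' `sum(|obs_i - (R ref_i + t)|^2)`, by SVD of the cross-covariance matrix
#' (Kabsch algorithm) with a reflection guard.
#'
#' @param ref,obs numeric n x 3 matrices of corresponding points (n >= 3).
#' @return list with `rotation` (3x3), `translation` (3-vector, mm) and
#'   `rms` residual (mm).
#' @export
fit_rigid_transform <- function(ref, obs) {
  ref <- as.matrix(ref); obs <- as.matrix(obs)
  stopifnot(nrow(ref) == nrow(obs), ncol(ref) == 3L, ncol(obs) == 3L)
  if (nrow(ref) < 3L) stop("at least 3 point pairs are required")
  cr <- colMeans(ref); co <- colMeans(obs)
  X <- sweep(ref, 2L, cr); Y <- sweep(obs, 2L, co)
  s <- svd(crossprod(X, Y))        # H = X^T Y = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(co - R %*% cr)
  fit <- sweep(ref %*% t(R), 2L, tr, `+`)
  list(rotation = R, translation = tr,
       rms = sqrt(mean(rowSums((obs - fit)^2))))
}

#' Per-frame pose estimation of one body from its markers
#'
#' Fits, independently at every frame, the rigid transform mapping the
#' body's CT/model-frame reference markers onto their observed 3D positions.
#' Frames where fewer than 3 of the body's markers (or only collinear ones)
#' are observed are reported as missing. Markers are weighted uniformly.
#'
#' @param ref a [marker_set()].
#' @param traj a [trajectory_set()] containing (at least) the reference
#'   markers.
#' @return object of class `pose_series`: list with `body_id`, `rotations`
#'   (3 x 3 x frames array), `translations` (frames x 3, mm), `rms`
#'   (per-frame residual, mm), `present` (logical per frame) and
#'   `frame_rate`.
#' @export
fit_pose_series <- function(ref, traj) {
  stopifnot(inherits(ref, "marker_set"), inherits(traj, "trajectory_set"))
  ids <- intersect(rownames(ref$positions), marker_ids(traj))
  if (length(ids) < 3L) {
    stop("body '", ref$body_id,
         "': fewer than 3 of its markers are present in the trajectories")
  }
  nf <- n_frames(traj)
  rot <- array(NA_real_, c(3L, 3L, nf))
  tra <- matrix(NA_real_, nf, 3L)
  rms <- rep(NA_real_, nf)
  present <- logical(nf)
  obs_all <- traj$positions[, , ids, drop = FALSE]
  refp <- ref$positions[ids, , drop = FALSE]
  for (f in seq_len(nf)) {
    obs <- t(obs_all[f, , ])
    ok <- apply(is.finite(obs), 1L, all)
    if (sum(ok) < 3L) next
    sub_ref <- refp[ok, , drop = FALSE]
    if (svd(scale(sub_ref, scale = FALSE))$d[2L] <= 1e-6) next
    fit <- fit_rigid_transform(sub_ref, obs[ok, , drop = FALSE])
    rot[, , f] <- fit$rotation
    tra[f, ] <- fit$translation
    rms[f] <- fit$rms
    present[f] <- TRUE
  }
  if (!any(present)) {
    stop("body '", ref$body_id, "': no frame could be fitted")
  }
  structure(list(body_id = ref$body_id, rotations = rot, translations = tra,
                 rms = rms, present = present, frame_rate = traj$frame_rate),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> body '%s': %d/%d frames, median rms %.4g mm\n",
              x$body_id, sum(x$present), length(x$present),
              stats::median(x$rms, na.rm = TRUE)))
  invisible(x)
}

#' Low-pass filter a pose series
#'
#' Zero-phase Butterworth filtering of the rigid-body transforms
#' themselves, before any joint decomposition: translations are filtered
#' componentwise; rotation matrices are filtered entrywise and each frame
#' is re-projected onto the nearest proper rotation (SVD polar
#' decomposition), which is accurate for the small frame-to-frame
#' orientation noise this removes. Filtering the transforms matters
#' most for the zero-pose frame: joint coordinate systems are anchored on
#' a single frame, so unfiltered single-frame noise would otherwise enter
#' every extracted angle as a constant bias.
#'
#' @param ps a [fit_pose_series()] result with all frames present.
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param order Butterworth order per pass (default 4).
#' @return a `pose_series` with smoothed rotations and translations.
#' @export
filter_pose_series <- function(ps, cutoff_hz, order = 4L) {
  stopifnot(inherits(ps, "pose_series"))
  if (!all(ps$present)) {
    warning("body '", ps$body_id,
            "': missing frames; pose series left unfiltered")
    return(ps)
  }
  nf <- length(ps$present)
  flat <- matrix(aperm(ps$rotations, c(3L, 1L, 2L)), nf, 9L)
  flat <- lowpass_filter(flat, cutoff_hz, ps$frame_rate, order)
  rot <- array(0, c(3L, 3L, nf))
  for (f in seq_len(nf)) {
    s <- svd(matrix(flat[f, ], 3L, 3L))
    d <- sign(det(s$u %*% t(s$v)))
    rot[, , f] <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  }
  ps$rotations <- rot
  ps$translations <- lowpass_filter(ps$translations, cutoff_hz,
                                    ps$frame_rate, order)
  ps
}

#' Intermarker distance series
#'
#' Euclidean distance between two markers at every frame, optionally
#' low-pass filtered (zero-phase Butterworth). Constant distance between two
#' markers is the evidence that they sit on the same rigid body; fluctuation
#' indicates joint motion (markers on different bones) or bending
#' (co-osseous markers).
#'
#' @param traj a [trajectory_set()].
#' @param a,b marker ids.
#' @param filter_cutoff_hz optional low-pass cutoff (Hz); `NULL` leaves the
#'   series unfiltered. Interior missing frames are linearly interpolated
#'   before filtering and restored to `NA` afterwards.
#' @return numeric vector of distances (mm), `NA` where either marker is
#'   missing.
#' @export
intermarker_distance <- function(traj, a, b, filter_cutoff_hz = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  ids <- marker_ids(traj)
  if (!a %in% ids || !b %in% ids) stop("unknown marker id")
  pa <- traj$positions[, , a]
  pb <- traj$positions[, , b]
  d <- sqrt(rowSums((pa - pb)^2))
  if (!any(is.finite(d))) stop("markers '", a, "' and '", b,
                               "' share no overlapping frames")
  if (is.null(filter_cutoff_hz)) return(d)
  ok <- is.finite(d)
  filled <- d
  if (!all(ok)) {
    idx <- which(ok)
    filled <- approx(idx, d[idx], xout = seq_along(d), rule = 2)$y
  }
  out <- lowpass_filter(filled, filter_cutoff_hz, traj$frame_rate)
  out[!ok] <- NA_real_
  out
}

#' Marker tracking precision from co-osseous pairs
#'
#' Tracking precision is estimated as the standard deviation of the
#' (unfiltered) intermarker distance within pairs of markers implanted in
#' the same bone, whose true separation is constant; the summary is the
#' mean and standard error of that SD across pairs.
#'
#' @param traj a [trajectory_set()].
#' @param pairs list of length-2 character vectors (co-osseous marker id
#'   pairs), or a 2-column matrix/data.frame.
#' @return list with `mean_sd` (mm), `sem` (mm), `n_pairs`, and `per_pair`
#'   (named numeric of per-pair SDs).
#' @export
tracking_precision <- function(traj, pairs) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, ]))
  }
  if (length(pairs) < 1L) stop("at least one co-osseous pair is required")
  per <- vapply(pairs, function(p) {
    d <- intermarker_distance(traj, p[[1L]], p[[2L]])
    d <- d[is.finite(d)]
    if (length(d) < 2L) stop("pair ", p[[1L]], "-", p[[2L]],
                             ": fewer than 2 usable frames")
    sd(d)
  }, numeric(1))
  names(per) <- vapply(pairs, paste, character(1), collapse = "-")
  list(mean_sd = mean(per),
       sem = if (length(per) > 1L) sd(per) / sqrt(length(per)) else NA_real_,
       n_pairs = length(per), per_pair = per)
}

#' Rigid-vs-mobile-vs-bending verdict for a marker pair
#'
#' Operationalizes the intermarker-distance screen: a filtered distance
#' series whose fluctuation amplitude (95th minus 5th percentile, robust to
#' single-frame outliers) stays within `k` times the tracking precision is
#' consistent with a constant distance, hence one rigid body. Larger
#' fluctuation means a mobile joint if the markers sit on different bones,
#' or suspected bending if they are co-osseous.
#'
#' @param distance_mm filtered distance series (mm); `NA`s ignored.
#' @param precision_mm marker tracking precision (mm), e.g. from
#'   [tracking_precision()].
#' @param co_osseous logical: do the two markers sit on the same bone?
#' @param k precision multiplier for the verdict band (default 2).
#' @param pair optional length-2 character vector of marker ids, recorded in
#'   the report.
#' @return object of class `rigidity_report`: list with `pair`, `distance_mm`,
#'   `fluctuation_mm`, `threshold_mm`, `co_osseous` and
#'   `verdict` in `c("same-rigid-body", "mobile-joint", "bending-suspected")`.
#' @export
classify_rigidity <- function(distance_mm, precision_mm, co_osseous,
                              k = 2, pair = NULL) {
  stopifnot(is.numeric(distance_mm), is.numeric(precision_mm),
            precision_mm >= 0, is.logical(co_osseous), k > 0)
  d <- distance_mm[is.finite(distance_mm)]
  if (length(d) < 2L) stop("distance series too short to classify")
  q <- quantile(d, c(0.05, 0.95), names = FALSE)
  fluct <- q[2L] - q[1L]
  thr <- k * precision_mm
  verdict <- if (fluct <= thr) {
    "same-rigid-body"
  } else if (co_osseous) {
    "bending-suspected"
  } else {
    "mobile-joint"
  }
  structure(list(pair = pair, distance_mm = distance_mm,
                 fluctuation_mm = fluct, threshold_mm = thr,
                 co_osseous = co_osseous, verdict = verdict),
            class = "rigidity_report")
}

#' @export
print.rigidity_report <- function(x, ...) {
  cat(sprintf("<rigidity_report> %s: fluctuation %.3f mm vs threshold %.3f mm -> %s\n",
              if (is.null(x$pair)) "pair" else paste(x$pair, collapse = "-"),
              x$fluctuation_mm, x$threshold_mm, x$verdict))
  invisible(x)
}
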