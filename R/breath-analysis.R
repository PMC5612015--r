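#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward (zero phase
#' lag, effective order doubled, squared magnitude response). The series is
#' extended by odd reflection at both ends before filtering so that the
#' start-up transient falls outside the retained samples; DC gain is 1, so
#' a constant series passes through unchanged. Breathing in the recordings
#' analysed here has a period of roughly 10 s (~0.1 Hz), so cutoffs of
#' 1-2 Hz sit 10-20x above the motion frequency.
#'
#' @param x numeric vector, or matrix filtered column-wise.
#' @param cutoff_hz low-pass cutoff frequency, Hz; must be below the Nyquist
#'   frequency `frame_rate/2`.
#' @param frame_rate sampling rate, Hz.
#' @param order Butterworth order of each pass (default 4).
#' @return filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz, frame_rate, order = 4L) {
  stopifnot(is.numeric(cutoff_hz), cutoff_hz > 0,
            is.numeric(frame_rate), frame_rate > 0)
  if (cutoff_hz >= frame_rate / 2) {
    stop("cutoff_hz must be below the Nyquist frequency frame_rate/2")
  }
  if (is.matrix(x)) {
    return(apply(x, 2L, lowpass_filter, cutoff_hz = cutoff_hz,
                 frame_rate = frame_rate, order = order))
  }
  n <- length(x)
  if (n <= 3L * (order + 1L)) {
    stop("series too short for a zero-phase filter of order ", order)
  }
  if (!all(is.finite(x))) stop("series contains non-finite values")
  bf <- signal::butter(order, 2 * cutoff_hz / frame_rate, type = "low")
  # Renormalize the numerator so the discretized filter has unit DC gain
  # exactly (the bilinear-transform coefficients carry ~1e-11 of rounding).
  bf$b <- bf$b * (sum(bf$a) / sum(bf$b))
  npad <- min(n - 1L, as.integer(ceiling(3 * frame_rate / cutoff_hz)))
  head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  ext <- c(head_pad, x, tail_pad)
  # Filter the deviation from the first sample: a constant series then
  # passes through exactly, and the start-up transient is driven only by
  # signal variation, which the reflection padding absorbs.
  run <- function(v) {
    as.numeric(signal::filter(bf, v - v[1L])) + v[1L]
  }
  y <- rev(run(rev(run(ext))))
  y[(npad + 1L):(npad + n)]
}

#' Segment a breathing trace into cycles
#'
#' Delimits breath cycles by successive inhalation peaks of a (filtered)
#' ribcage-expansion signal: local maxima (including the endpoints, so a
#' trial that starts or ends exactly at an inhalation peak contributes its
#' boundary cycles) are screened by height and thinned greedily by
#' amplitude so that retained peaks are at least `min_separation_s` apart.
#' Signals whose total range is below `min_range` (e.g. a flat trace) yield
#' no cycles.
#'
#' @param expansion numeric vector, a filtered signal that is maximal at
#'   peak inhalation.
#' @param frame_rate sampling rate, Hz.
#' @param min_separation_s minimum peak separation, s (default 3; breaths
#'   in the recordings emulated here last ~10 s).
#' @param min_height_frac peaks lower than
#'   `min + min_height_frac * range` of the signal are discarded (default
#'   0.5), which rejects noise ripples on the near-flat inhalation
#'   plateau; lower it to keep genuinely shallow breaths.
#' @param min_range minimum peak-to-trough range for the signal to count as
#'   breathing at all (same units as `expansion`).
#' @return data.frame with columns `start`, `end` (frame indices of
#'   consecutive inhalation peaks, 1-based, end inclusive); zero rows if
#'   fewer than two peaks are found (with a warning).
#' @export
segment_breaths <- function(expansion, frame_rate, min_separation_s = 3,
                            min_height_frac = 0.5, min_range = 1e-6) {
  stopifnot(is.numeric(expansion), length(expansion) > 2L)
  x <- expansion
  empty <- data.frame(start = integer(0), end = integer(0))
  if (!all(is.finite(x)) || diff(range(x)) <= min_range) {
    warning("no breathing cycles found (flat or invalid signal)")
    return(empty)
  }
  n <- length(x)
  i <- 2:(n - 1L)
  cand <- i[x[i] >= x[i - 1L] & x[i] >= x[i + 1L] &
              (x[i] > x[i - 1L] | x[i] > x[i + 1L])]
  if (x[1L] >= x[2L]) cand <- c(1L, cand)
  if (x[n] >= x[n - 1L]) cand <- c(cand, n)
  cand <- cand[x[cand] >= min(x) + min_height_frac * diff(range(x))]
  if (length(cand) == 0L) {
    warning("no breathing cycles found (no interior peaks)")
    return(empty)
  }
  min_sep <- max(1L, as.integer(round(min_separation_s * frame_rate)))
  keep <- integer(0)
  for (p in cand[order(x[cand], decreasing = TRUE)]) {
    if (all(abs(p - keep) >= min_sep)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  if (length(keep) < 2L) {
    warning("fewer than one complete breathing cycle found")
    return(empty)
  }
  data.frame(start = keep[-length(keep)], end = keep[-1L])
}

#' Resample one breath cycle to 100 phase points
#'
#' Linearly interpolates each angle component onto `n_points` equispaced
#' points spanning the cycle (point k sits at phase (k-1)/(n_points-1) of
#' the inhalation-to-inhalation interval), then subtracts each component's
#' mean, so that cycles of different durations and baselines become
#' directly comparable.
#'
#' @param angles numeric T x 3 matrix (columns z, y, x degrees) covering one
#'   cycle, or a vector for a single component.
#' @param n_points number of phase points (default 100).
#' @return `n_points` x 3 matrix (or vector), zero-mean per component, of
#'   class `breath_cycle`.
#' @export
resample_cycle <- function(angles, n_points = 100L) {
  vec <- is.null(dim(angles))
  m <- if (vec) matrix(angles, ncol = 1L) else as.matrix(angles)
  if (nrow(m) < 10L) stop("cycle too short to resample (< 10 frames)")
  if (!all(is.finite(m))) stop("cycle contains non-finite values")
  phase_in <- seq(0, 1, length.out = nrow(m))
  phase_out <- seq(0, 1, length.out = n_points)
  out <- apply(m, 2L, function(col) approx(phase_in, col, xout = phase_out)$y)
  offset <- colMeans(out)
  out <- sweep(out, 2L, offset)
  if (vec) out <- as.numeric(out)
  class(out) <- c("breath_cycle", class(out))
  # The removed baseline (mean angle per component, relative to the zero
  # pose) travels with the cycle: rotation reconstruction needs it back,
  # because Euler angles shifted by per-component constants describe a
  # different rotation.
  attr(out, "offset") <- offset
  out
}

#' Average resampled breath cycles
#'
#' Pointwise mean and sample standard deviation across cycles that have
#' already been phase-normalized by [resample_cycle()].
#'
#' @param cycles list of equally sized cycle matrices.
#' @return list of class `averaged_cycle` with `mean` and `sd` matrices and
#'   `n` (number of cycles).
#' @export
average_cycles <- function(cycles) {
  stopifnot(is.list(cycles), length(cycles) >= 1L)
  dims <- vapply(cycles, function(c) dim(as.matrix(unclass(c))), integer(2))
  if (any(dims != dims[, 1L])) stop("cycles must all have the same shape")
  arr <- simplify2array(lapply(cycles, function(c) as.matrix(unclass(c))))
  mu <- apply(arr, c(1L, 2L), mean)
  sdev <- if (length(cycles) > 1L) apply(arr, c(1L, 2L), sd) else 0 * mu
  offsets <- lapply(cycles, attr, "offset")
  offset <- if (all(!vapply(offsets, is.null, logical(1)))) {
    colMeans(do.call(rbind, offsets))
  } else NULL
  structure(list(mean = mu, sd = sdev, n = length(cycles), offset = offset),
            class = "averaged_cycle")
}

# Default expansion signal: score of the first principal component of the
# three Euler traces. For near-planar (hinge-like) joint motion all three
# traces are proportional, so PC1 carries essentially all the variance.
expansion_signal <- function(angles) {
  pc <- prcomp(angles, center = TRUE, scale. = FALSE)
  as.numeric(pc$x[, 1L])
}

#' In vivo axis of total rib rotation over a breath cycle
#'
#' Locates peak inhalation and peak exhalation on an averaged, 100-point
#' cycle, reconstructs the two orientations from their ZYX Euler triples,
#' and converts their difference rotation to an axis-angle representation:
#' the "total" rotation of the rib across the breathing cycle. The
#' peak-to-peak difference is always computed on reconstructed rotation
#' matrices - Euler angles are never subtracted componentwise. The two peak
#' phases are the extrema of an expansion signal, by default the first
#' principal component score of the three Euler traces.
#'
#' @param avg an [average_cycles()] result, or a 100 x 3 matrix of mean
#'   angles (columns z, y, x, degrees).
#' @param reference_axis optional 3-vector (e.g. the anatomical axis): the
#'   recovered axis is flipped so its dot product with it is non-negative.
#'   Without it, the axis's largest-magnitude component is made positive.
#' @param expansion optional replacement expansion signal (length 100).
#' @param spline_spar optional smoothing parameter in (0, 1\]: when set, a
#'   cubic smoothing spline is passed over each component of the averaged
#'   trace before peak-picking and endpoint reading (off by default; the
#'   plain pointwise average is the reproducible baseline).
#' @param min_theta_deg below this total rotation the axis direction is
#'   unreliable; the result is flagged (`degenerate = TRUE`) with a warning.
#' @return list of class `invivo_axis`: `axis` (unit 3-vector), `theta_deg`,
#'   `plane_angles` (degrees to sagittal/coronal/transverse),
#'   `ternary` (percent |x|:|y|:|z|), `peak_inhale`, `peak_exhale`
#'   (phase indices), `degenerate`.
#' @export
total_rotation_axis <- function(avg, reference_axis = NULL, expansion = NULL,
                                spline_spar = NULL, min_theta_deg = 0.5) {
  m <- if (inherits(avg, "averaged_cycle")) avg$mean else as.matrix(avg)
  stopifnot(ncol(m) == 3L)
  if (!is.null(spline_spar)) {
    ph <- seq_len(nrow(m))
    m <- apply(m, 2L, function(col) {
      stats::smooth.spline(ph, col, spar = spline_spar)$y
    })
  }
  if (is.null(expansion)) expansion <- expansion_signal(m)
  stopifnot(length(expansion) == nrow(m))
  p_in <- which.max(expansion)
  p_ex <- which.min(expansion)
  # Restore the baseline removed during mean-zeroing before reconstructing
  # rotations: Euler triples only compose correctly on their true scale.
  offset <- if (inherits(avg, "averaged_cycle") && !is.null(avg$offset)) {
    avg$offset
  } else attr(avg, "offset", exact = TRUE)
  if (is.null(offset)) offset <- c(0, 0, 0)
  R_in <- euler_to_matrix(m[p_in, ] + offset)
  R_ex <- euler_to_matrix(m[p_ex, ] + offset)
  aa <- matrix_to_axis_angle(relative_rotation(R_in, R_ex),
                             reference = reference_axis)
  degenerate <- aa$theta_deg < min_theta_deg
  if (degenerate) {
    warning(sprintf(
      "total rotation %.3g deg is below %.3g deg; axis direction unreliable",
      aa$theta_deg, min_theta_deg))
  }
  structure(list(axis = aa$axis, theta_deg = aa$theta_deg,
                 plane_angles = vector_plane_angles(aa$axis),
                 ternary = ternary_composition(aa$axis),
                 peak_inhale = p_in, peak_exhale = p_ex,
                 degenerate = degenerate),
            class = "invivo_axis")
}

#' @export
print.invivo_axis <- function(x, ...) {
  cat(sprintf("<invivo_axis> theta %.2f deg about (%.3f, %.3f, %.3f)\n",
              x$theta_deg, x$axis[1L], x$axis[2L], x$axis[3L]))
  cat(sprintf("  plane angles (sag/cor/trans): %.1f / %.1f / %.1f deg\n",
              x$plane_angles[1L], x$plane_angles[2L], x$plane_angles[3L]))
  invisible(x)
}

#' Regress measured against predicted axis orientations
#'
#' Ordinary least-squares regression of the measured (in vivo) angle on the
#' predicted (anatomical) angle between the rotation axis and each body
#' plane, pooled over joints. Under a perfect hinge model the points fall on
#' the identity line; departures are tested via the intercept-differs-from-0
#' and slope-differs-from-1 t tests.
#'
#' @param data data.frame with columns `plane` (factor/character),
#'   `predicted` and `measured` (degrees).
#' @return data.frame, one row per plane: `slope`, `intercept`, `r_squared`,
#'   `p_value` (slope vs 0), `p_intercept_vs_0`, `p_slope_vs_1`, `n`.
#' @export
regress_predicted_vs_measured <- function(data) {
  stopifnot(all(c("plane", "predicted", "measured") %in% names(data)))
  planes <- unique(as.character(data$plane))
  rows <- lapply(planes, function(pl) {
    d <- data[data$plane == pl, , drop = FALSE]
    if (nrow(d) < 3L) stop("plane '", pl, "': at least 3 pairs are required")
    if (sd(d$predicted) < 1e-12) {
      stop("plane '", pl, "': predicted values are constant (degenerate design)")
    }
    fit <- lm(measured ~ predicted, data = d)
    sm <- summary(fit)
    co <- sm$coefficients
    t_slope1 <- (co[2L, 1L] - 1) / co[2L, 2L]
    data.frame(plane = pl,
               slope = co[2L, 1L], intercept = co[1L, 1L],
               r_squared = sm$r.squared,
               p_value = co[2L, 4L],
               p_intercept_vs_0 = co[1L, 4L],
               p_slope_vs_1 = 2 * pt(abs(t_slope1), df = fit$df.residual,
                                     lower.tail = FALSE),
               n = nrow(d))
  })
  do.call(rbind, rows)
}
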