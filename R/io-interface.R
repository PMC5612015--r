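fmt17 <- function(x) {
  # Full-precision decimal formatting so that write -> read round trips
  # reproduce doubles bit-exactly.
  ifelse(is.finite(x), sprintf("%.17g", x), "")
}

#' Write marker trajectories as an XMALab-dialect CSV
#'
#' Header row of `<marker>_X`, `<marker>_Y`, `<marker>_Z` columns, one row
#' per frame; missing observations are blank cells. Values are written at
#' full precision, so a write/read round trip is exact.
#'
#' @param traj a [trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  ids <- marker_ids(traj)
  cols <- list()
  for (id in ids) {
    for (k in 1:3) {
      cols[[paste0(id, "_", c("X", "Y", "Z")[k])]] <-
        fmt17(traj$positions[, k, id])
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read marker trajectories from an XMALab-dialect CSV
#'
#' Expects a header of `<marker>_X/_Y/_Z` triplets, one row per frame.
#' Blank or non-finite cells become missing (`NA`) observations. Errors
#' name the offending marker or line.
#'
#' @param path CSV file path.
#' @param frame_rate sampling rate in Hz (not stored in the XMALab export).
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path, frame_rate) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  nm <- names(df)
  suff <- sub(".*_([XYZ])$", "\\1", nm)
  base <- sub("_[XYZ]$", "", nm)
  if (any(suff == nm)) {
    stop("malformed header: columns without _X/_Y/_Z suffix: ",
         paste(nm[suff == nm], collapse = ", "))
  }
  ids <- unique(base)
  arr <- array(NA_real_, c(nrow(df), 3L, length(ids)),
               dimnames = list(NULL, c("x", "y", "z"), ids))
  for (id in ids) {
    for (k in 1:3) {
      col <- paste0(id, "_", c("X", "Y", "Z")[k])
      if (!col %in% nm) {
        stop("marker '", id, "': missing column ", col)
      }
      raw <- df[[col]]
      blank <- is.na(raw) | !nzchar(trimws(raw))
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!blank & is.na(val))
      if (length(bad) > 0L) {
        stop("non-numeric value in column ", col, " at line ", bad[1L] + 1L)
      }
      arr[, k, id] <- val
    }
  }
  trajectory_set(arr, frame_rate)
}

#' Write / read reference marker sets
#'
#' CSV with columns `body_id, marker_id, x, y, z` (mm, CT/model frame).
#'
#' @param bodies named list of [marker_set()] objects.
#' @param path CSV file path.
#' @return `path` invisibly for the writer; a named list of [marker_set()]
#'   for the reader.
#' @export
write_marker_sets <- function(bodies, path) {
  rows <- do.call(rbind, lapply(bodies, function(b) {
    data.frame(body_id = b$body_id, marker_id = rownames(b$positions),
               x = fmt17(b$positions[, 1L]), y = fmt17(b$positions[, 2L]),
               z = fmt17(b$positions[, 3L]))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_sets
#' @export
read_marker_sets <- function(path) {
  df <- read.csv(path, colClasses = c(rep("character", 2L), rep("numeric", 3L)))
  stopifnot(all(c("body_id", "marker_id", "x", "y", "z") %in% names(df)))
  out <- lapply(split(df, df$body_id), function(d) {
    pos <- as.matrix(d[, c("x", "y", "z")])
    rownames(pos) <- d$marker_id
    marker_set(d$body_id[1L], pos)
  })
  out[unique(df$body_id)]
}

#' Write / read vertebral landmark tables
#'
#' CSV with columns `vertebra_id, side, landmark, x, y, z` in the
#' column-aligned frame, as consumed by [compute_axes()].
#'
#' @param landmarks landmark data.frame.
#' @param path CSV file path.
#' @return `path` invisibly for the writer; the data.frame for the reader.
#' @export
write_landmarks <- function(landmarks, path) {
  out <- landmarks
  for (cc in c("x", "y", "z")) out[[cc]] <- fmt17(landmarks[[cc]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  read.csv(path, colClasses = c("integer", rep("character", 2L),
                                rep("numeric", 3L)))
}

#' Export a simulated dataset as a plain-text fixture bundle
#'
#' Writes the noisy trajectories (XMALab dialect), the reference marker
#' sets, the vertebral landmarks, the joint definitions and the full ground
#' truth (joint angle series, rotation axes, breath boundaries) to a
#' directory. For a noiseless run, re-importing the trajectories reproduces
#' the in-memory values exactly.
#'
#' @param sim a [simulate_breathing()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
export_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ribcage_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    trajectories = file.path(dir, "trajectories.csv"),
    markers = file.path(dir, "marker_sets.csv"),
    landmarks = file.path(dir, "landmarks.csv"),
    joints = file.path(dir, "joints.json"),
    truth_angles = file.path(dir, "truth_joint_angles.csv"),
    truth_axes = file.path(dir, "truth_axes.csv"),
    truth_breaths = file.path(dir, "truth_breath_frames.csv"))
  write_trajectories(sim$trajectories, paths[["trajectories"]])
  write_marker_sets(sim$model$bodies, paths[["markers"]])
  write_landmarks(sim$model$landmarks, paths[["landmarks"]])
  writeLines(joints_to_json(sim$model$joints), paths[["joints"]])
  # frames are 0-based in files (1-based inside R)
  ang <- do.call(rbind, lapply(names(sim$truth$joint_angles), function(j) {
    out <- sim$truth$joint_angles[[j]]
    out$frame <- out$frame - 1L
    cbind(joint_id = j, out)
  }))
  write.csv(ang, paths[["truth_angles"]], row.names = FALSE, quote = FALSE)
  write.csv(sim$truth$axes, paths[["truth_axes"]], row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(frame = sim$truth$breath_frames - 1L),
            paths[["truth_breaths"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# Minimal JSON serialization of joint definitions (no extra dependency at
# run time; jsonlite can read the output).
joints_to_json <- function(joints) {
  esc <- function(s) gsub('"', '\\\\"', s)
  num <- function(v) paste0("[", paste(sprintf("%.17g", v), collapse = ","), "]")
  mat <- function(m) paste0("[", paste(apply(m, 1L, num), collapse = ","), "]")
  items <- vapply(joints, function(d) {
    fields <- c(
      sprintf('"joint_id":"%s"', esc(d$joint_id)),
      sprintf('"archetype":"%s"', esc(d$archetype)),
      sprintf('"proximal_body_id":"%s"', esc(d$proximal_body_id)),
      sprintf('"distal_body_id":"%s"', esc(d$distal_body_id)),
      sprintf('"anchor":%s', num(d$anchor)),
      sprintf('"zero_pose_frame":%d', as.integer(d$zero_pose_frame)))
    if (!is.null(d$distal_axis_points)) {
      fields <- c(fields,
        sprintf('"distal_axis_points":%s', mat(d$distal_axis_points)),
        sprintf('"proximal_plane_points":%s', mat(d$proximal_plane_points)))
    }
    paste0("{", paste(fields, collapse = ","), "}")
  }, character(1))
  paste0("[\n", paste(items, collapse = ",\n"), "\n]")
}

default_pipeline_params <- function() {
  list(cutoff_hz = 1.5, filter_order = 4L, resample_points = 100L,
       min_peak_separation_s = 3, rigidity_k = 2, min_theta_deg = 0.5,
       spline_spar = NULL)
}

# Mean distance of all markers from their per-frame centroid: a direct
# measure of ribcage expansion, used to orient the expansion signal.
marker_spread <- function(traj) {
  pos <- traj$positions
  ctr <- apply(pos, c(1L, 2L), mean, na.rm = TRUE)
  d <- sqrt(apply(sweep(pos, c(1L, 2L), ctr)^2, c(1L, 3L), sum))
  rowMeans(d, na.rm = TRUE)
}

# Marker pair spanning a joint for the mobility screen: on each body, the
# marker farthest from the joint anchor. Sensitivity to relative motion
# grows with the lever arm, so the far pair has the most detection power.
cross_pair_for_joint <- function(defn, prox_set, dist_set) {
  far <- function(ms) {
    d <- sqrt(rowSums(sweep(ms$positions, 2L, defn$anchor)^2))
    rownames(ms$positions)[which.max(d)]
  }
  c(far(prox_set), far(dist_set))
}

#' Run the full rib-kinematics pipeline
#'
#' Orchestrates the analysis sequence: per-body pose fitting, tracking
#' precision from co-osseous marker pairs, the rigidity screen (co-osseous
#' and cross-joint pairs), JCS construction and joint-angle extraction,
#' zero-phase low-pass filtering, breath segmentation on a reference
#' expansion signal, 100-point cycle resampling and averaging, the in vivo
#' axis-angle of total rotation per joint and, when predicted axes are
#' supplied, the predicted-versus-measured body-plane-angle regression.
#'
#' @param trajectories a [trajectory_set()].
#' @param bodies named list of [marker_set()] objects.
#' @param joints named list of [joint_definition()]s. Definitions with
#'   `zero_pose_frame = NA` are resolved to the first detected inhalation
#'   peak (two-pass extraction).
#' @param predicted_axes optional data.frame with columns `joint_id`,
#'   `axis_x`, `axis_y`, `axis_z` (e.g. from [compute_axes()] plus a joint
#'   mapping): enables axis sign alignment and the regression.
#' @param params named list of overrides of the defaults: `cutoff_hz`
#'   (1.5), `filter_order` (4), `resample_points` (100),
#'   `min_peak_separation_s` (3), `rigidity_k` (2), `min_theta_deg` (0.5),
#'   `spline_spar` (NULL = no spline smoothing of averaged traces).
#' @param reference_joint joint id whose expansion signal defines the
#'   global breath boundaries (default: the first joint).
#' @return list of class `rib_pipeline_result` with elements `poses`,
#'   `precision`, `rigidity` (data.frame), `angles` (filtered
#'   [extract_joint_angles()] tables), `breaths`, `averaged`, `invivo_axes`
#'   (data.frame), `comparison` (data.frame) and `regression` (data.frame,
#'   when predicted axes were supplied), plus `params`.
#' @export
run_pipeline <- function(trajectories, bodies, joints, predicted_axes = NULL,
                         params = list(), reference_joint = names(joints)[1L]) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            length(bodies) > 0L, length(joints) > 0L)
  prm <- utils::modifyList(default_pipeline_params(), params)
  fr <- trajectories$frame_rate

  poses <- lapply(bodies, fit_pose_series, traj = trajectories)
  # Filter the rigid-body transforms before any joint decomposition (the
  # JCS zero-pose anchor is a single frame, so unfiltered single-frame
  # noise would bias every extracted angle).
  poses <- lapply(poses, filter_pose_series, cutoff_hz = prm$cutoff_hz,
                  order = prm$filter_order)

  co_pairs <- list()
  for (b in bodies) {
    ids <- rownames(b$positions)
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      for (i in seq_len(ncol(cmb))) {
        co_pairs[[length(co_pairs) + 1L]] <-
          c(cmb[1L, i], cmb[2L, i], body = b$body_id)
      }
    }
  }
  precision <- tracking_precision(trajectories,
                                  lapply(co_pairs, function(p) p[1:2]))

  rigidity <- list()
  for (p in co_pairs) {
    d <- intermarker_distance(trajectories, p[[1L]], p[[2L]],
                              filter_cutoff_hz = prm$cutoff_hz)
    rep_ <- classify_rigidity(d, precision$mean_sd, co_osseous = TRUE,
                              k = prm$rigidity_k, pair = p[1:2])
    rigidity[[length(rigidity) + 1L]] <-
      data.frame(marker_a = p[[1L]], marker_b = p[[2L]], co_osseous = TRUE,
                 joint_id = NA_character_,
                 fluctuation_mm = rep_$fluctuation_mm,
                 threshold_mm = rep_$threshold_mm, verdict = rep_$verdict)
  }
  for (jd in joints) {
    pr <- cross_pair_for_joint(jd, bodies[[jd$proximal_body_id]],
                               bodies[[jd$distal_body_id]])
    d <- intermarker_distance(trajectories, pr[[1L]], pr[[2L]],
                              filter_cutoff_hz = prm$cutoff_hz)
    rep_ <- classify_rigidity(d, precision$mean_sd, co_osseous = FALSE,
                              k = prm$rigidity_k, pair = pr)
    rigidity[[length(rigidity) + 1L]] <-
      data.frame(marker_a = pr[[1L]], marker_b = pr[[2L]], co_osseous = FALSE,
                 joint_id = jd$joint_id,
                 fluctuation_mm = rep_$fluctuation_mm,
                 threshold_mm = rep_$threshold_mm, verdict = rep_$verdict)
  }
  rigidity <- do.call(rbind, rigidity)

  extract_filtered <- function(jd) {
    jc <- build_jcs(jd, poses[[jd$proximal_body_id]],
                    poses[[jd$distal_body_id]])
    ang <- extract_joint_angles(jc, poses[[jd$proximal_body_id]],
                                poses[[jd$distal_body_id]])
    ang[, c("z_deg", "y_deg", "x_deg")] <-
      lowpass_filter(as.matrix(ang[, c("z_deg", "y_deg", "x_deg")]),
                     prm$cutoff_hz, fr, prm$filter_order)
    ang
  }

  # Resolve "auto" zero poses in two passes: provisional zero at the first
  # fitted frame, then re-anchor at the first detected inhalation peak.
  first_fitted <- function(jd) {
    which(poses[[jd$proximal_body_id]]$present &
            poses[[jd$distal_body_id]]$present)[1L]
  }
  auto_ids <- names(joints)[vapply(joints,
                                   function(jd) is.na(jd$zero_pose_frame),
                                   logical(1))]
  joints <- lapply(joints, function(jd) {
    if (is.na(jd$zero_pose_frame)) jd$zero_pose_frame <- first_fitted(jd)
    jd
  })
  ref_ang <- extract_filtered(joints[[reference_joint]])
  expn <- expansion_signal(as.matrix(
    ref_ang[, c("z_deg", "y_deg", "x_deg")]))
  # Orient the principal-component score so that its maxima are inhalation
  # peaks: correlate it against a direct ribcage-expansion proxy, the mean
  # distance of all markers from their per-frame centroid (maximal when
  # the ribs are unfolded at maximum inhalation).
  spread <- marker_spread(trajectories)
  if (stats::cor(expn, spread, use = "complete.obs") < 0) expn <- -expn
  breaths <- segment_breaths(expn, fr, prm$min_peak_separation_s)
  if (nrow(breaths) > 0L && length(auto_ids) > 0L) {
    # Prefer an interior inhalation peak: at the recording edges the
    # zero-phase filter cannot average noise symmetrically, and the zero
    # pose is a single-frame anchor whose noise enters every angle.
    # ... and anchor on the average pose over all interior peaks: maximum
    # inhalation is a recurring posture, so averaging suppresses the
    # single-frame tracking noise a one-instant anchor would freeze in.
    peaks <- unique(c(breaths$start, breaths$end))
    interior <- peaks[peaks > 1L & peaks < length(expn)]
    zero_f <- if (length(interior) > 0L) interior else peaks[1L]
    joints[auto_ids] <- lapply(joints[auto_ids], function(jd) {
      jd$zero_pose_frame <- zero_f
      jd
    })
  }

  angles <- lapply(joints, extract_filtered)
  averaged <- lapply(angles, function(ang) {
    m <- as.matrix(ang[, c("z_deg", "y_deg", "x_deg")])
    cycles <- lapply(seq_len(nrow(breaths)), function(b) {
      resample_cycle(m[breaths$start[b]:breaths$end[b], , drop = FALSE],
                     prm$resample_points)
    })
    average_cycles(cycles)
  })

  invivo <- do.call(rbind, lapply(names(joints), function(jid) {
    ref_axis <- NULL
    if (!is.null(predicted_axes) && jid %in% predicted_axes$joint_id) {
      ref_axis <- as.numeric(
        predicted_axes[predicted_axes$joint_id == jid,
                       c("axis_x", "axis_y", "axis_z")])
    }
    iv <- total_rotation_axis(averaged[[jid]], reference_axis = ref_axis,
                              spline_spar = prm$spline_spar,
                              min_theta_deg = prm$min_theta_deg)
    data.frame(joint_id = jid, theta_deg = iv$theta_deg,
               axis_x = iv$axis[1L], axis_y = iv$axis[2L],
               axis_z = iv$axis[3L],
               sagittal_deg = iv$plane_angles[["sagittal"]],
               coronal_deg = iv$plane_angles[["coronal"]],
               transverse_deg = iv$plane_angles[["transverse"]],
               ternary_x = iv$ternary[["x"]], ternary_y = iv$ternary[["y"]],
               ternary_z = iv$ternary[["z"]],
               degenerate = iv$degenerate)
  }))

  comparison <- NULL
  regression <- NULL
  if (!is.null(predicted_axes)) {
    shared <- intersect(invivo$joint_id, predicted_axes$joint_id)
    if (length(shared) > 0L) {
      comparison <- do.call(rbind, lapply(shared, function(jid) {
        pa <- as.numeric(predicted_axes[predicted_axes$joint_id == jid,
                                        c("axis_x", "axis_y", "axis_z")])
        pang <- vector_plane_angles(normalize3(pa))
        mv <- invivo[invivo$joint_id == jid, ]
        data.frame(joint_id = jid,
                   plane = c("sagittal", "coronal", "transverse"),
                   predicted = as.numeric(pang),
                   measured = c(mv$sagittal_deg, mv$coronal_deg,
                                mv$transverse_deg))
      }))
      if (length(shared) >= 3L) {
        regression <- regress_predicted_vs_measured(comparison)
      }
    }
  }

  structure(list(poses = poses, precision = precision, rigidity = rigidity,
                 angles = angles, breaths = breaths, averaged = averaged,
                 invivo_axes = invivo, comparison = comparison,
                 regression = regression, params = prm),
            class = "rib_pipeline_result")
}

#' @export
print.rib_pipeline_result <- function(x, ...) {
  cat(sprintf("<rib_pipeline_result> %d bodies, %d joints, %d breaths\n",
              length(x$poses), nrow(x$invivo_axes), nrow(x$breaths)))
  if (!is.null(x$regression)) {
    cat("  predicted-vs-measured regression:\n")
    print(x$regression[, c("plane", "slope", "intercept", "r_squared")],
          row.names = FALSE)
  }
  invisible(x)
}
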