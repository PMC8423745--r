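#' Displacement traces
#'
#' A displacement trace is the high-rate (nominally 1000 Hz) recording of the
#' mandibular incisal-point displacement relative to the centric occlusion
#' reference pose: columns `t` (s), `dx`, `dy`, `dz` (mm) in the package
#' coordinate frame (x = subject's right, y = superior, z = anterior; origin
#' at the incisal midpoint in centric occlusion).
#'
#' @param t sample times, s, strictly increasing and uniform.
#' @param dx,dy,dz displacement components, mm.
#' @return a `displacement_trace` (data.frame with a `sampling_rate`
#'   attribute).
#' @export
displacement_trace <- function(t, dx, dy, dz) {
  d <- data.frame(t = as.numeric(t), dx = as.numeric(dx),
                  dy = as.numeric(dy), dz = as.numeric(dz))
  if (nrow(d) < 2) stop("a displacement trace needs at least two samples")
  dt <- diff(d$t)
  if (any(dt <= 0)) stop("sample times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    stop("non-uniform sampling: timestamp jitter ",
         format(max(dt) - min(dt)), " s exceeds 1e-6 s")
  if (max(abs(unlist(d[1, c("dx", "dy", "dz")]))) > 0) {
    off <- unlist(d[1, c("dx", "dy", "dz")])
    d$dx <- d$dx - off[1]; d$dy <- d$dy - off[2]; d$dz <- d$dz - off[3]
    message(sprintf(
      "first sample re-based to the centric reference; offset removed: (%.6g, %.6g, %.6g) mm",
      off[1], off[2], off[3]))
  }
  attr(d, "sampling_rate") <- 1 / mean(dt)
  class(d) <- c("displacement_trace", "data.frame")
  d
}

#' Read a displacement trace from CSV
#'
#' Expects the exact header `t,dx,dy,dz` (seconds, millimetres). A non-zero
#' first sample is re-based to zero with a message.
#'
#' @param path CSV file path.
#' @return a [displacement_trace()].
#' @export
load_displacement_trace <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t", "dx", "dy", "dz")
  if (!identical(names(d)[seq_along(need)], need))
    stop("displacement trace schema error: expected header 't,dx,dy,dz', got '",
         paste(names(d), collapse = ","), "'")
  displacement_trace(d$t, d$dx, d$dy, d$dz)
}

#' Write a displacement trace to CSV
#' @param trace a [displacement_trace()].
#' @param path output path.
#' @export
save_displacement_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("t", "dx", "dy", "dz")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rotation traces
#'
#' Per-plane signed rotation angles of the mandible versus the centric
#' reference, sampled at the video frame rate. All angles are radians unless
#' `angle_unit = "deg"`.
#'
#' @param t frame times, s.
#' @param theta_sag,theta_fro,theta_hor angles in the sagittal, frontal and
#'   horizontal planes.
#' @param angle_unit `"rad"` (default) or `"deg"`.
#' @return a `rotation_trace` data.frame (radians internally).
#' @export
rotation_trace <- function(t, theta_sag, theta_fro, theta_hor,
                           angle_unit = c("rad", "deg")) {
  angle_unit <- match.arg(angle_unit)
  k <- if (angle_unit == "deg") pi / 180 else 1
  d <- data.frame(t = as.numeric(t), theta_sag = k * as.numeric(theta_sag),
                  theta_fro = k * as.numeric(theta_fro),
                  theta_hor = k * as.numeric(theta_hor))
  if (nrow(d) < 2) stop("a rotation trace needs at least two frames")
  if (any(diff(d$t) <= 0)) stop("frame times must be strictly increasing")
  if (max(abs(unlist(d[1, -1]))) > 1e-12)
    stop("rotation trace must start at zero angles (centric reference)")
  attr(d, "frame_rate") <- 1 / mean(diff(d$t))
  class(d) <- c("rotation_trace", "data.frame")
  d
}

#' Read / write rotation traces (CSV header `t,theta_sag,theta_fro,theta_hor`)
#' @param path CSV path.
#' @param angle_unit unit of the stored angles.
#' @return a [rotation_trace()].
#' @export
load_rotation_trace <- function(path, angle_unit = c("rad", "deg")) {
  d <- utils::read.csv(path)
  need <- c("t", "theta_sag", "theta_fro", "theta_hor")
  if (!identical(names(d)[seq_along(need)], need))
    stop("rotation trace schema error: expected header '",
         paste(need, collapse = ","), "', got '",
         paste(names(d), collapse = ","), "'")
  rotation_trace(d$t, d$theta_sag, d$theta_fro, d$theta_hor,
                 angle_unit = match.arg(angle_unit))
}

#' Marker tracks
#'
#' A marker track carries the 2-D image coordinates of one fixed and one
#' movable skeletal landmark over a video recording of one viewing plane.
#' The admissible pairs follow the recording protocol: RZP (fixed) with
#' gonion (movable) in the sagittal view, nasion with pogonion frontally,
#' and the hyoid with pogonion horizontally.
#'
#' @param plane `"sagittal"`, `"frontal"` or `"horizontal"`.
#' @param t frame times, s.
#' @param fixed_uv,mov_uv n x 2 matrices of pixel coordinates.
#' @return a `marker_track`.
#' @export
marker_track <- function(plane, t, fixed_uv, mov_uv) {
  plane <- match.arg(plane, c("sagittal", "frontal", "horizontal"))
  pair <- switch(plane,
                 sagittal = c("RZP", "gonion"),
                 frontal = c("nasion", "pogonion"),
                 horizontal = c("hyoid", "pogonion"))
  fixed_uv <- as.matrix(fixed_uv); mov_uv <- as.matrix(mov_uv)
  if (length(t) < 2) stop("a marker track needs at least two frames")
  if (nrow(fixed_uv) != length(t) || nrow(mov_uv) != length(t))
    stop("marker coordinate rows must match the number of frames")
  structure(list(plane = plane, fixed = pair[1], movable = pair[2],
                 t = as.numeric(t), fixed_uv = fixed_uv, mov_uv = mov_uv,
                 frame_rate = 1 / mean(diff(t))),
            class = "marker_track")
}

#' Extract the per-plane rotation angle from a marker pair
#'
#' The plane angle at frame t is the signed angle (counter-clockwise
#' positive in the plane's viewing orientation) between the movable-minus-
#' fixed landmark vector at frame t and at frame 0.
#'
#' @param track a [marker_track()].
#' @return a single-plane `rotation_trace`-like data.frame with columns `t`
#'   and `theta` (radians).
#' @export
extract_plane_angle <- function(track) {
  v <- track$mov_uv - track$fixed_uv
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-12))
    stop("degenerate marker pair: fixed and movable landmarks coincide at frame ",
         which(len < 1e-12)[1])
  v0 <- v[1, ]
  # signed angle from the baseline vector to the frame-t vector,
  # counter-clockwise positive in the plane's viewing orientation
  theta <- atan2(v0[1] * v[, 2] - v0[2] * v[, 1],
                 v[, 1] * v0[1] + v[, 2] * v0[2])
  data.frame(t = track$t, theta = theta)
}

#' Assemble a full rotation trace from three marker tracks
#'
#' @param sagittal,frontal,horizontal [marker_track()] objects, one per
#'   plane. Frame times must agree within half a frame.
#' @return a [rotation_trace()].
#' @export
rotation_trace_from_tracks <- function(sagittal, frontal, horizontal) {
  stopifnot(sagittal$plane == "sagittal", frontal$plane == "frontal",
            horizontal$plane == "horizontal")
  as_ <- extract_plane_angle(sagittal)
  af <- extract_plane_angle(frontal)
  ah <- extract_plane_angle(horizontal)
  if (max(abs(as_$t - af$t)) > 0.5 / sagittal$frame_rate ||
      max(abs(as_$t - ah$t)) > 0.5 / sagittal$frame_rate)
    stop("marker tracks do not share a common time base")
  rotation_trace(as_$t, as_$theta, af$theta, ah$theta)
}

## ---- rigid transforms ---------------------------------------------------

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Compose a rigid transform from per-plane angles and a translation
#'
#' The sagittal-plane angle rotates about the x axis, the frontal-plane angle
#' about the z axis and the horizontal-plane angle about the y axis. The
#' fixed composition order is `R = R_hor %*% R_fro %*% R_sag`. Points
#' transform as `p -> R (p - c) + c + translation` about the rotation
#' center `c` (default: the incisal reference point, the origin).
#'
#' @param theta_sag,theta_fro,theta_hor plane angles, radians.
#' @param translation length-3 translation, mm.
#' @param rotation_center length-3 point, mm.
#' @return a `rigid_transform` (list with `R`, `t`, `center`).
#' @export
compose_transform <- function(theta_sag = 0, theta_fro = 0, theta_hor = 0,
                              translation = c(0, 0, 0),
                              rotation_center = c(0, 0, 0)) {
  stopifnot(all(is.finite(c(theta_sag, theta_fro, theta_hor, translation,
                            rotation_center))))
  R <- rot_y(theta_hor) %*% rot_z(theta_fro) %*% rot_x(theta_sag)
  structure(list(R = R, t = as.numeric(translation),
                 center = as.numeric(rotation_center),
                 angles = c(sag = theta_sag, fro = theta_fro,
                            hor = theta_hor)),
            class = "rigid_transform")
}

#' Identity transform
#' @return a `rigid_transform`.
#' @export
identity_transform <- function() compose_transform()

#' Apply a rigid transform to points
#' @param tf a `rigid_transform`.
#' @param pts n x 3 matrix (or length-3 vector).
#' @return transformed points, same shape.
#' @export
apply_transform <- function(tf, pts) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(pts, 1, 3) else as.matrix(pts)
  out <- sweep(p, 2, tf$center) %*% t(tf$R)
  out <- sweep(out, 2, tf$center + tf$t, `+`)
  if (vec) as.numeric(out) else out
}

#' Rotate direction vectors (no translation)
#' @param tf a `rigid_transform`.
#' @param dirs n x 3 matrix of directions.
#' @return rotated directions.
#' @export
apply_rotation <- function(tf, dirs) as.matrix(dirs) %*% t(tf$R)

## ---- merged trajectories ------------------------------------------------

#' Build a merged trajectory from displacement and rotation recordings
#'
#' The two streams cover the same task interval but are not synchronously
#' sampled; both are rescaled to the common interval, which is split into
#' `n_segments` equal time bins. At each bin end the displacement (linear
#' interpolation of the high-rate trace) and the three plane angles (linear
#' interpolation of each angle series) form one absolute rigid transform
#' relative to the centric reference pose.
#'
#' @param disp a [displacement_trace()].
#' @param rot a [rotation_trace()].
#' @param n_segments number of equal time bins (>= 1).
#' @param rotation_center rotation center, mm (default incisal origin).
#' @param task task label.
#' @return a `merged_trajectory`: data.frame with columns `segment`,
#'   `t_start`, `t_end`, `tx`, `ty`, `tz`, `theta_sag`, `theta_fro`,
#'   `theta_hor` plus attributes `task` and `rotation_center`. Transforms are
#'   absolute poses at each bin end; the pose at the start of segment 1 is
#'   the identity.
#' @export
segment_and_merge <- function(disp, rot, n_segments,
                              rotation_center = c(0, 0, 0),
                              task = c("centric_closing", "protrusion",
                                       "right_excursion", "left_excursion")) {
  task <- match.arg(task)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > nrow(disp))
    stop("resolution error: n_segments (", n_segments,
         ") exceeds the displacement sample count (", nrow(disp), ")")
  frame_dt <- 1 / attr(rot, "frame_rate")
  t0 <- max(disp$t[1], rot$t[1])
  t1 <- min(disp$t[nrow(disp)], rot$t[nrow(rot)])
  if (abs(disp$t[1] - rot$t[1]) > frame_dt ||
      abs(disp$t[nrow(disp)] - rot$t[nrow(rot)]) > frame_dt)
    stop("coverage error: displacement and rotation recordings differ by ",
         "more than one video frame at the task boundaries")
  edges <- seq(t0, t1, length.out = n_segments + 1)
  at <- edges[-1]
  li <- function(x, y) stats::approx(x, y, xout = at, rule = 2)$y
  traj <- data.frame(segment = seq_len(n_segments),
                     t_start = edges[-length(edges)], t_end = at,
                     tx = li(disp$t, disp$dx), ty = li(disp$t, disp$dy),
                     tz = li(disp$t, disp$dz),
                     theta_sag = li(rot$t, rot$theta_sag),
                     theta_fro = li(rot$t, rot$theta_fro),
                     theta_hor = li(rot$t, rot$theta_hor))
  new_trajectory(traj, task, rotation_center)
}

new_trajectory <- function(df, task, rotation_center) {
  attr(df, "task") <- task
  attr(df, "rotation_center") <- as.numeric(rotation_center)
  class(df) <- c("merged_trajectory", "data.frame")
  df
}

#' Per-segment rigid transforms of a trajectory
#' @param traj a `merged_trajectory`.
#' @return list of `rigid_transform`, one per segment (absolute poses).
#' @export
trajectory_transforms <- function(traj) {
  ctr <- attr(traj, "rotation_center")
  lapply(seq_len(nrow(traj)), function(i)
    compose_transform(traj$theta_sag[i], traj$theta_fro[i], traj$theta_hor[i],
                      c(traj$tx[i], traj$ty[i], traj$tz[i]), ctr))
}

#' Mirror a trajectory about the mid-sagittal plane
#'
#' Reflection about x = 0: the lateral translation component and the frontal
#' and horizontal plane angles change sign; the vertical/anterior components
#' and the sagittal angle are preserved. Excursion task labels swap sides.
#'
#' @param traj a `merged_trajectory`.
#' @return the mirrored `merged_trajectory`.
#' @export
mirror_trace <- function(traj) {
  task <- attr(traj, "task")
  new_task <- switch(task,
                     right_excursion = "left_excursion",
                     left_excursion = "right_excursion",
                     {
                       warning("mirroring a non-excursion task ('", task, "')")
                       task
                     })
  out <- traj
  out$tx <- -out$tx
  out$theta_fro <- -out$theta_fro
  out$theta_hor <- -out$theta_hor
  ctr <- attr(traj, "rotation_center") * c(-1, 1, 1)
  new_trajectory(as.data.frame(out), new_task, ctr)
}

#' Read / write merged trajectories
#' (CSV header `segment,t_start,t_end,tx,ty,tz,theta_sag,theta_fro,theta_hor`)
#' @param traj a `merged_trajectory`.
#' @param path CSV path.
#' @param task,rotation_center metadata used when reading.
#' @export
save_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$task <- attr(traj, "task")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path, rotation_center = c(0, 0, 0)) {
  df <- utils::read.csv(path)
  need <- c("segment", "t_start", "t_end", "tx", "ty", "tz",
            "theta_sag", "theta_fro", "theta_hor")
  if (!all(need %in% names(df)))
    stop("trajectory schema error: expected columns '",
         paste(need, collapse = ","), "'")
  task <- if ("task" %in% names(df)) df$task[1] else "centric_closing"
  new_trajectory(df[need], task, rotation_center)
}

## ---- synthetic recordings -----------------------------------------------

min_jerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

# virtual landmark layout (pixels); baselines ~1100 px so 0.5 px jitter maps
# to about 1e-3 rad of angle noise per frame
marker_layout <- list(
  sagittal = list(fixed = c(1250, 520), base = c(-700, 860)),
  frontal = list(fixed = c(1280, 350), base = c(40, 1100)),
  horizontal = list(fixed = c(1280, 1500), base = c(-55, -1110)))

#' Generate a synthetic jaw-motion recording
#'
#' Renders a smooth (minimum-jerk) trajectory from the centric pose to a task
#' endpoint as the two recording modalities: a high-rate displacement trace
#' of the incisal point and three per-plane marker tracks obtained by
#' rotating a virtual fixed/movable landmark pair by the programmed plane
#' angle, with optional Gaussian pixel jitter.
#'
#' @param task task label; supplies preset amplitudes/angles when they are
#'   not given (see [task_presets]).
#' @param amplitudes length-3 endpoint displacement (mm), default from
#'   preset.
#' @param angles length-3 endpoint plane angles (rad), default from preset.
#' @param duration task duration, s.
#' @param disp_rate displacement sampling rate, Hz.
#' @param frame_rate video frame rate, Hz.
#' @param noise_px marker pixel jitter standard deviation.
#' @param seed RNG seed fixing the jitter.
#' @return list with `disp` ([displacement_trace()]), `tracks` (list of three
#'   [marker_track()]), and `ground_truth` (functions of time for the
#'   programmed displacement and angles).
#' @export
generate_synthetic_recording <- function(task = c("right_excursion",
                                                  "left_excursion",
                                                  "centric_closing",
                                                  "protrusion"),
                                         amplitudes = NULL, angles = NULL,
                                         duration = 3.5, disp_rate = 1000,
                                         frame_rate = 30, noise_px = 0,
                                         seed = NULL) {
  task <- match.arg(task)
  if (duration <= 0) stop("duration must be positive")
  preset <- task_presets[[task]]
  if (is.null(amplitudes)) amplitudes <- preset$amplitude
  if (is.null(angles)) angles <- preset$angles
  if (!all(is.finite(c(amplitudes, angles)))) stop("non-finite inputs")
  if (!is.null(seed)) set.seed(seed)
  td <- seq(0, duration, by = 1 / disp_rate)
  s <- min_jerk(td / duration)
  disp <- displacement_trace(td, amplitudes[1] * s, amplitudes[2] * s,
                             amplitudes[3] * s)
  tv <- seq(0, duration, by = 1 / frame_rate)
  sv <- min_jerk(tv / duration)
  ang <- list(sagittal = angles[1] * sv, frontal = angles[2] * sv,
              horizontal = angles[3] * sv)
  tracks <- lapply(names(marker_layout), function(pl) {
    lay <- marker_layout[[pl]]
    th <- ang[[pl]]
    # rotate the baseline CCW by the programmed angle (matches the
    # sign convention of extract_plane_angle)
    rot <- cbind(cos(th) * lay$base[1] - sin(th) * lay$base[2],
                 sin(th) * lay$base[1] + cos(th) * lay$base[2])
    fixed <- matrix(lay$fixed, length(tv), 2, byrow = TRUE)
    mov <- sweep(rot, 2, lay$fixed, `+`)
    if (noise_px > 0) {
      fixed <- fixed + matrix(stats::rnorm(2 * length(tv), 0, noise_px),
                              ncol = 2)
      mov <- mov + matrix(stats::rnorm(2 * length(tv), 0, noise_px), ncol = 2)
    }
    marker_track(pl, tv, fixed, mov)
  })
  names(tracks) <- names(marker_layout)
  gt_disp <- function(t) outer(min_jerk(pmin(pmax(t / duration, 0), 1)),
                               amplitudes)
  gt_ang <- function(t) outer(min_jerk(pmin(pmax(t / duration, 0), 1)),
                              angles)
  list(disp = disp, tracks = tracks, task = task,
       ground_truth = list(displacement = gt_disp, angles = gt_ang))
}
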