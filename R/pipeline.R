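#' Task specification
#'
#' Bundles everything one simulated task needs: the dentition model, the
#' merged trajectory driving the lower arch, and optional occlusal
#' modifications applied (to a copy of the model) before running.
#'
#' @param model a `dentition_model`.
#' @param trajectory a `merged_trajectory` (e.g. [preset_trajectory()] or
#'   [segment_and_merge()]).
#' @param modifications optional list of [modification_spec()] applied to the
#'   lower arch before the run.
#' @param reseat re-seat the model into centric contact after modifications
#'   (see [seat_centric()]).
#' @param cutoff far cutoff, mm.
#' @param k penalty stiffness override, N mm^-3.
#' @return a `task_spec`.
#' @export
task_spec <- function(model, trajectory, modifications = NULL,
                      reseat = FALSE, cutoff = 5, k = NULL) {
  stopifnot(inherits(model, "dentition_model"),
            inherits(trajectory, "merged_trajectory"))
  if (nrow(trajectory) < 1) stop("empty trajectory")
  structure(list(model = model, trajectory = trajectory,
                 modifications = modifications, reseat = reseat,
                 cutoff = cutoff, k = k),
            class = "task_spec")
}

apply_modifications <- function(model, specs, reseat = TRUE) {
  if (is.null(specs)) return(model)
  if (inherits(specs, "modification_spec")) specs <- list(specs)
  for (sp in specs)
    model$lower <- carve_region(model$lower, model$lower_labels, sp)
  if (reseat) model <- seat_centric(model)
  model
}

config_hash <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  obj <- lapply(list(...), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  })
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run one simulated task
#'
#' Iterates the penalty contact solver over every trajectory segment in
#' order (one quasi-static solve per merged segment) and collects per-tooth
#' and global stress summaries. Fully deterministic for a given model,
#' trajectory and configuration.
#'
#' @param spec a [task_spec()].
#' @return a `stress_report`: per-tooth x per-frame matrices of max
#'   principal stress `sigma1` (MPa), its normal `p` and shear `tau`
#'   components and contact `area`; per-frame global maxima with tooth
#'   locations, contact area (mm^2) and total normal force (N); metadata
#'   with a reproducible configuration hash.
#' @export
run_task <- function(spec) {
  model <- apply_modifications(spec$model, spec$modifications,
                               reseat = spec$reseat)
  traj <- spec$trajectory
  tfs <- trajectory_transforms(traj)
  index <- build_spatial_index(model$upper)
  geom <- lower_face_geometry(model$lower)
  k <- if (is.null(spec$k)) foundation_stiffness(model$material) else spec$k
  labels <- model$lower_labels
  teeth <- sort(setdiff(unique(labels), 0L))
  nf <- length(tfs)
  nt <- length(teeth)
  sigma1 <- p_mat <- tau_mat <- area_mat <- matrix(0, nt, nf,
                                                   dimnames = list(teeth, NULL))
  max_face <- matrix(NA_integer_, nt, nf, dimnames = list(teeth, NULL))
  g_area <- g_force <- g_max <- numeric(nf)
  g_tooth <- integer(nf)
  dt <- diff(c(traj$t_start[1], traj$t_end))
  st <- NULL
  tooth_faces <- lapply(teeth, function(tt) which(labels == tt))
  for (i in seq_len(nf)) {
    st <- resolve_frame(model, tfs[[i]], index, prev_frame = st, dt = dt[i],
                        geom = geom, k = k, cutoff = spec$cutoff,
                        check_version = (i == 1L))
    for (j in seq_len(nt)) {
      idx <- tooth_faces[[j]]
      s <- st$sigma1[idx]
      if (length(s) && max(s) > 0) {
        b <- idx[which.max(s)]
        sigma1[j, i] <- st$sigma1[b]
        p_mat[j, i] <- st$p[b]
        tau_mat[j, i] <- st$tau[b]
        max_face[j, i] <- b
      }
      area_mat[j, i] <- sum(st$area[idx][st$contact[idx]])
    }
    g_area[i] <- st$contact_area
    g_force[i] <- st$total_force
    g_max[i] <- if (nt) max(sigma1[, i]) else 0
    g_tooth[i] <- if (nt && g_max[i] > 0) teeth[which.max(sigma1[, i])] else 0L
  }
  structure(list(
    teeth = teeth, t = traj$t_end, n_frames = nf,
    sigma1 = sigma1, p = p_mat, tau = tau_mat, area = area_mat,
    max_face = max_face,
    global_max = g_max, global_tooth = g_tooth,
    contact_area = g_area, total_force = g_force,
    metadata = list(
      task = attr(traj, "task"), n_segments = nf, k = k,
      mu = model$material$mu, cutoff = spec$cutoff,
      seated_by = attr(model, "seated_by"),
      config_hash = config_hash(attr(traj, "task"), as.data.frame(traj),
                                model$lower$vertices, model$upper$vertices,
                                k, model$material$mu, spec$cutoff))),
    class = "stress_report")
}

#' @export
print.stress_report <- function(x, ...) {
  peak <- if (length(x$global_max)) max(x$global_max) else 0
  at <- if (peak > 0) x$global_tooth[which.max(x$global_max)] else NA
  cat(sprintf(
    "stress_report (%s): %d frames, %d teeth; peak sigma1 %.3g MPa at FDI %s\n",
    x$metadata$task, x$n_frames, length(x$teeth), peak, at))
  invisible(x)
}

#' Run a mirror-trace experiment
#'
#' Runs an excursion trajectory and its mid-sagittal mirror on the same
#' model, for before/after comparison of balancing-side loading.
#'
#' @param model a `dentition_model`.
#' @param trajectory the base excursion `merged_trajectory`.
#' @param ... passed to [task_spec()].
#' @return list with `base` and `mirrored` stress reports.
#' @export
run_mirror_experiment <- function(model, trajectory, ...) {
  base <- run_task(task_spec(model, trajectory, ...))
  mirrored <- run_task(task_spec(model, mirror_trace(trajectory), ...))
  list(base = base, mirrored = mirrored)
}

#' Run a carve-then-rerun modification experiment
#'
#' Runs every supplied task trajectory on the unmodified model and on a
#' carved copy. After carving, the copy is re-seated into its new
#' intercuspal position (the mandible closes further once an interference
#' is removed), which is what redistributes contact to previously
#' non-contacting teeth.
#'
#' @param model a `dentition_model`.
#' @param specs a [modification_spec()] or list of them.
#' @param trajectories named list of `merged_trajectory` objects.
#' @param reseat re-seat the carved model (default TRUE).
#' @param ... passed to [task_spec()].
#' @return list with `before` and `after`: named lists of stress reports.
#' @export
run_modification_experiment <- function(model, specs, trajectories,
                                        reseat = TRUE, ...) {
  if (inherits(trajectories, "merged_trajectory"))
    trajectories <- list(task = trajectories)
  before <- lapply(trajectories, function(tr)
    run_task(task_spec(model, tr, ...)))
  after <- lapply(trajectories, function(tr)
    run_task(task_spec(model, tr, modifications = specs, reseat = reseat,
                       ...)))
  list(before = before, after = after)
}

#' Carve specification for a planted interference
#'
#' Builds the [modification_spec()] that removes a generated interference
#' bump: the region is centred on the lingual flank of the cusp (where the
#' balancing-side wall contact occurs during a contralateral excursion),
#' with full removal depth there and a cosine taper that removes about half
#' the depth at the apex.
#'
#' @param model a generated `dentition_model` with an interference.
#' @param tooth FDI code (default: the planted interference tooth).
#' @return a `modification_spec`.
#' @export
interference_carve_spec <- function(model, tooth = NULL) {
  p <- attr(model, "params")
  gt <- attr(model, "ground_truth")
  if (is.null(p) || is.null(p$interference))
    stop("model does not carry a generated interference")
  if (is.null(tooth)) tooth <- p$interference$tooth
  row <- gt[gt$fdi == tooth, ]
  if (nrow(row) != 1) stop("tooth FDI ", tooth, " not present in the model")
  g <- arch_geometry(p)
  v_hat <- arch_outward(g, row$phi)        # buccal in-plane direction
  s <- p$wall_slope
  r_s <- p$cusp_tip_radius
  hyp <- sqrt(1 + s^2)
  dx_f <- r_s * s / hyp                    # flank contact offset from apex
  dy_f <- r_s * (1 - 1 / hyp)
  center <- c(row$apex_x - dx_f * v_hat[1],  # lingual side
              row$apex_y - dy_f,
              row$apex_z - dx_f * v_hat[2])
  radius <- 2 * sqrt(dx_f^2 + dy_f^2)
  modification_spec(tooth, center, radius, p$interference$height,
                    direction = c(0, 1, 0))
}

#' Per-tooth stress summary table
#'
#' One row per tooth per frame with the tooth's maximum principal stress,
#' its normal and shear components and contact area, plus one task-level row
#' (`frame = NA`) carrying the highest stress of the whole task and its
#' tooth.
#'
#' @param report a `stress_report`.
#' @return a data.frame; row count = teeth x frames + 1.
#' @export
per_tooth_summary <- function(report) {
  nt <- length(report$teeth)
  nf <- report$n_frames
  df <- data.frame(
    tooth = rep(report$teeth, nf),
    frame = rep(seq_len(nf), each = nt),
    sigma1 = as.vector(report$sigma1),
    p = as.vector(report$p),
    tau = as.vector(report$tau),
    area = as.vector(report$area))
  peak <- max(report$global_max, 0)
  task_row <- data.frame(
    tooth = if (peak > 0)
      report$global_tooth[which.max(report$global_max)] else NA_integer_,
    frame = NA_integer_, sigma1 = peak,
    p = NA_real_, tau = NA_real_, area = NA_real_)
  rbind(df, task_row)
}

#' Time-stress curve of one tooth
#'
#' The per-frame maximum principal stress on the tooth together with its
#' normal (vertical) and shear components.
#'
#' @param report a `stress_report`.
#' @param tooth FDI code present in the report.
#' @return a `stress_curve` data.frame with columns `t`, `sigma1`, `p`,
#'   `tau`.
#' @export
time_stress_curve <- function(report, tooth) {
  i <- match(tooth, report$teeth)
  if (is.na(i))
    stop("tooth FDI ", tooth, " not in report; available: ",
         paste(report$teeth, collapse = ", "))
  out <- data.frame(t = report$t, sigma1 = report$sigma1[i, ],
                    p = report$p[i, ], tau = report$tau[i, ])
  attr(out, "tooth") <- tooth
  class(out) <- c("stress_curve", "data.frame")
  out
}

#' @export
plot.stress_curve <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$sigma1, x$p, x$tau), type = "l", lty = 1,
                    col = c("black", "blue", "red"), xlab = "time (s)",
                    ylab = "stress (MPa)",
                    main = paste("FDI", attr(x, "tooth")), ...)
  graphics::legend("topleft", c("sigma1", "normal", "shear"), lty = 1,
                   col = c("black", "blue", "red"), bty = "n")
  invisible(x)
}

#' Compare two stress reports
#'
#' @param a,b `stress_report`s over the same tooth set and frame count.
#' @param mirror_labels compare tooth T of `a` with its contralateral tooth
#'   in `b` (for mirror experiments).
#' @return data.frame per tooth: change in max sigma1, change in the number
#'   of contact frames, and whether the tooth gained or lost contact.
#' @export
compare_reports <- function(a, b, mirror_labels = FALSE) {
  bt <- if (mirror_labels) mirror_fdi(a$teeth) else a$teeth
  if (!setequal(bt, b$teeth) || a$n_frames != b$n_frames)
    stop("comparison error: reports have different tooth sets or frame counts")
  j <- match(bt, b$teeth)
  max_a <- apply(a$sigma1, 1, max)
  max_b <- apply(b$sigma1[j, , drop = FALSE], 1, max)
  cf_a <- rowSums(a$area > 0)
  cf_b <- rowSums(b$area[j, , drop = FALSE] > 0)
  data.frame(tooth = a$teeth,
             d_sigma1 = max_b - max_a,
             d_contact_frames = cf_b - cf_a,
             gained_contact = cf_a == 0 & cf_b > 0,
             lost_contact = cf_a > 0 & cf_b == 0)
}

#' Hash a stress report
#'
#' MD5 digest of the serialized report, for byte-level reproducibility
#' checks.
#'
#' @param report a `stress_report`.
#' @return character md5 digest.
#' @export
report_hash <- function(report) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(report, f, compress = FALSE)
  unname(tools::md5sum(f))
}

## ---- report I/O ---------------------------------------------------------

#' Write / read a stress report as CSV
#'
#' Writes `<prefix>_tooth.csv` (long per-tooth table), `<prefix>_frame.csv`
#' (per-frame globals) and `<prefix>_meta.csv`. [read_stress_report()]
#' reconstructs an equal report (metadata restricted to scalar fields).
#'
#' @param report a `stress_report`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_stress_report <- function(report, prefix) {
  nt <- length(report$teeth)
  nf <- report$n_frames
  tooth <- data.frame(
    tooth = rep(report$teeth, nf),
    frame = rep(seq_len(nf), each = nt),
    sigma1 = as.vector(report$sigma1), p = as.vector(report$p),
    tau = as.vector(report$tau), area = as.vector(report$area),
    max_face = as.vector(report$max_face))
  frame <- data.frame(frame = seq_len(nf), t = report$t,
                      global_max = report$global_max,
                      global_tooth = report$global_tooth,
                      contact_area = report$contact_area,
                      total_force = report$total_force)
  meta <- data.frame(key = c("task", "n_segments", "k", "mu", "cutoff",
                             "config_hash"),
                     value = c(report$metadata$task, report$metadata$n_segments,
                               format(report$metadata$k, digits = 17),
                               format(report$metadata$mu, digits = 17),
                               format(report$metadata$cutoff, digits = 17),
                               report$metadata$config_hash))
  utils::write.csv(tooth, paste0(prefix, "_tooth.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(frame, paste0(prefix, "_frame.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(meta, paste0(prefix, "_meta.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(prefix)
}

#' @rdname write_stress_report
#' @export
read_stress_report <- function(prefix) {
  tooth <- utils::read.csv(paste0(prefix, "_tooth.csv"))
  frame <- utils::read.csv(paste0(prefix, "_frame.csv"))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"),
                          colClasses = "character")
  teeth <- sort(unique(tooth$tooth))
  nf <- nrow(frame)
  shape <- function(col) matrix(tooth[[col]], length(teeth), nf,
                                dimnames = list(teeth, NULL))
  kv <- stats::setNames(meta$value, meta$key)
  structure(list(
    teeth = teeth, t = frame$t, n_frames = nf,
    sigma1 = shape("sigma1"), p = shape("p"), tau = shape("tau"),
    area = shape("area"), max_face = shape("max_face"),
    global_max = frame$global_max, global_tooth = frame$global_tooth,
    contact_area = frame$contact_area, total_force = frame$total_force,
    metadata = list(task = kv[["task"]],
                    n_segments = as.integer(kv[["n_segments"]]),
                    k = as.numeric(kv[["k"]]), mu = as.numeric(kv[["mu"]]),
                    cutoff = as.numeric(kv[["cutoff"]]),
                    config_hash = kv[["config_hash"]])),
    class = "stress_report")
}

#' Export a stress field on the lower arch as VTK polydata
#'
#' @param model a `dentition_model`.
#' @param state a `contact_state` from [resolve_frame()].
#' @param path output `.vtk` path.
#' @export
export_stress_vtk <- function(model, state, path) {
  save_mesh(model$lower, path, format = "vtk",
            scalar_fields = list(sigma1 = state$sigma1, p = state$p,
                                 tau = state$tau))
}
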