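#' Recorded-task presets
#'
#' Endpoint displacement amplitudes (mm, incisal point), per-plane endpoint
#' rotation angles (radians) and default merged-segment counts for the four
#' recorded tasks. Amplitudes follow the recorded excursion ranges (right
#' excursion 6.9 mm lateral / 6.6 mm vertical, left excursion 4.1 mm /
#' 1.9 mm); angles are the recorded per-plane values in (sagittal, frontal,
#' horizontal) order; segment counts are 18 (centric closing), 61
#' (protrusion), 29 (left excursion) and 35 (right excursion).
#'
#' @format a named list, one entry per task, each with `amplitude`, `angles`,
#'   `n_segments` and `duration` (s).
#' @export
task_presets <- list(
  centric_closing = list(amplitude = c(0, 0.3, 0),
                         angles = c(0.104, 0.001, 0.003),
                         n_segments = 18L, duration = 3.5),
  protrusion = list(amplitude = c(0, -3, 5),
                    angles = c(0.111, 0.002, 0.001),
                    n_segments = 61L, duration = 3.5),
  right_excursion = list(amplitude = c(6.9, -6.6, 0),
                         angles = c(0.084, 0.001, 0.471),
                         n_segments = 35L, duration = 3.5),
  left_excursion = list(amplitude = c(-4.1, -1.9, 0),
                        angles = c(0.052, 0.002, 0.179),
                        n_segments = 29L, duration = 3.5))

#' Build a preset task trajectory for stress simulation
#'
#' Runs the full recording pipeline for a preset task: a noiseless synthetic
#' recording is generated, the plane angles are extracted from the rendered
#' marker tracks, and the two streams are segmented and merged into a rigid
#' trajectory.
#'
#' By default the rotational components are held at zero for stress tasks.
#' The recorded per-plane angles are magnitudes observed on facial landmark
#' pairs; applied as rigid-body rotations about the incisal reference point
#' (the only point the displacement recording constrains) the largest of
#' them would translate posterior teeth by centimetres, which no occlusal
#' geometry admits - the physical rotation center (the condyle) is not
#' observable from either recording. Set `include_rotation = TRUE` to apply
#' the preset angles regardless (e.g. for kinematic studies with a chosen
#' `rotation_center`).
#'
#' @param task one of the four task labels.
#' @param n_segments segment count (default: the task preset).
#' @param include_rotation apply the preset plane angles (default FALSE).
#' @param rotation_center rotation center, mm.
#' @return a `merged_trajectory`.
#' @export
preset_trajectory <- function(task, n_segments = NULL,
                              include_rotation = FALSE,
                              rotation_center = c(0, 0, 0)) {
  task <- match.arg(task, names(task_presets))
  preset <- task_presets[[task]]
  if (is.null(n_segments)) n_segments <- preset$n_segments
  angles <- if (include_rotation) preset$angles else c(0, 0, 0)
  rec <- generate_synthetic_recording(task, amplitudes = preset$amplitude,
                                      angles = angles,
                                      duration = preset$duration)
  rot <- rotation_trace_from_tracks(rec$tracks$sagittal, rec$tracks$frontal,
                                    rec$tracks$horizontal)
  segment_and_merge(rec$disp, rot, n_segments,
                    rotation_center = rotation_center, task = task)
}
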