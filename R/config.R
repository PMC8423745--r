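#' Read a pipeline configuration file
#'
#' A single YAML file drives the command-line tools. Recognised keys (all
#' optional; defaults mirror the package's standard constants):
#'
#' * `geometry`: arguments of [arch_params()], plus
#'   `interference: {tooth, height}`.
#' * `material`: `E_gpa`, `nu`, `mu`, `h_mm` (see [material_params()]).
#' * `contact`: `cutoff_mm`, `k_override`.
#' * `tasks`: `segments` (named per task), `include_rotation`, `angle_unit`.
#' * `seeds`: `geometry`, `recording`.
#' * `modifications`: list of [modification_spec()] argument sets.
#'
#' @param path YAML file path.
#' @return a named list with validated `material`, `geometry`, `contact`,
#'   `tasks`, `seeds` and `modifications` entries.
#' @export
read_task_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  geom <- cfg$geometry
  if (!is.null(geom$interference))
    geom$interference <- list(tooth = as.integer(geom$interference$tooth),
                              height = as.numeric(geom$interference$height))
  params <- do.call(arch_params, geom %||% list())
  mat <- do.call(material_params, cfg$material %||% list())
  contact <- list(cutoff_mm = cfg$contact$cutoff_mm %||% 5,
                  k_override = cfg$contact$k_override)
  segments <- lapply(task_presets, `[[`, "n_segments")
  for (nm in names(cfg$tasks$segments %||% list()))
    segments[[nm]] <- as.integer(cfg$tasks$segments[[nm]])
  tasks <- list(segments = segments,
                include_rotation = isTRUE(cfg$tasks$include_rotation),
                angle_unit = cfg$tasks$angle_unit %||% "rad")
  seeds <- list(geometry = cfg$seeds$geometry %||% 1L,
                recording = cfg$seeds$recording %||% 1L)
  mods <- lapply(cfg$modifications %||% list(), function(m)
    modification_spec(as.integer(m$target_label), as.numeric(m$center),
                      as.numeric(m$radius), as.numeric(m$depth),
                      direction = as.numeric(m$direction %||% c(0, 1, 0))))
  list(params = params, material = mat, contact = contact, tasks = tasks,
       seeds = seeds, modifications = mods)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
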