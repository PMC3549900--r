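#' Run a full simulation from a validated configuration
#'
#' Convenience wrapper wiring a [load_config()] result into
#' [generate_femur_mesh()] and [run_evolution()].
#'
#' @param config An `osteofem_config` (from [load_config()] or
#'   [validate_config()]).
#' @param mesh Optional pre-built mesh (skips meshing).
#' @return An [run_evolution()] result.
#' @export
simulate_from_config <- function(config, mesh = NULL) {
  stopifnot(inherits(config, "osteofem_config"))
  patient <- if (!is.null(config$patient$csv)) {
    read_bmd_csv(config$patient$csv)
  } else {
    healthy_femur_bmd()
  }
  geom <- do.call(femur_geometry, config$geometry)
  if (is.null(mesh)) {
    mesh <- generate_femur_mesh(geom, target_edge = config$mesh$target_edge,
      order = config$mesh$order)
  }
  law <- do.call(density_law, config$density_law)
  damage <- do.call(damage_params, config$damage)
  loads <- do.call(load_case, config$load_case)
  times <- seq(config$time$start, config$time$end, by = config$time$step)
  run_evolution(
    patient = patient, scenario = config$scenario, mesh = mesh,
    times = times, law = law, damage = damage, loads = loads,
    offset_space = config$offset_space, irreversible = config$irreversible
  )
}
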