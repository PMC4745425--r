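#' Read a run configuration from YAML
#'
#' The configuration format uses explicit unit suffixes in its keys
#' (mm, MPa, s, ...) and is converted to SI on load. All sections have
#' defaults equal to the reference compliance-mismatch setup, so an empty
#' file yields the default run. Schema (all top-level keys optional):
#'
#' ```yaml
#' geometry:
#'   inner_diameter_mm: 8
#'   outer_diameter_mm: 10
#' inlet_extension_mm: 30
#' poissons_ratio: 0.499
#' segments:                      # ordered, inlet to outlet
#'   - {length_mm: 50, youngs_modulus_MPa: 200}
#'   - {length_mm: 50, youngs_modulus_MPa: 5}
#'   - {length_mm: 50, youngs_modulus_MPa: 200}
#' probe_positions_mm: [70, 100, 140]
#' fluid:
#'   density_kg_m3: 1050
#'   dynamic_viscosity_Pa_s: 0.0035
#' waveform:
#'   period_s: 1
#'   diastolic_reynolds: 190      # alternatively diastolic_mean_velocity_m_s
#'   peak_reynolds: 500           # alternatively peak_mean_velocity_m_s
#'   peak_time_fraction: 0.15
#'   systolic_width_fraction: 0.25
#'   harmonics_retained: 12
#' solver:
#'   dx_mm: 0.5
#'   cfl: 0.9
#'   cycles: 3
#'   output_dt_s: 0.01
#'   convergence_tolerance: 1.0e-4
#' ```
#'
#' @param path Path to a YAML configuration file.
#' @return A named list with components `model` (a [segmented_vessel()]),
#'   `fluid` (a [fluid_properties()]), `waveform` (a [waveform_params()])
#'   and `solver` (a [solver_settings()]).
#' @seealso [write_config()] for the inverse operation.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  config_from_list(if (is.null(raw)) list() else raw)
}

#' Build a run configuration from a plain list
#'
#' Same schema as [read_config()]; useful for programmatic configuration.
#'
#' @param raw A named list in the configuration schema (possibly empty).
#' @return As [read_config()].
#' @export
config_from_list <- function(raw = list()) {
  stopifnot(is.list(raw))
  pick <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]

  geom_raw <- pick(raw, "geometry", list())
  geometry <- vessel_geometry(
    inner_diameter = pick(geom_raw, "inner_diameter_mm", 8) / 1000,
    outer_diameter = pick(geom_raw, "outer_diameter_mm", 10) / 1000
  )
  nu <- pick(raw, "poissons_ratio", 0.499)
  seg_raw <- pick(raw, "segments", list(
    list(length_mm = 50, youngs_modulus_MPa = 200),
    list(length_mm = 50, youngs_modulus_MPa = 5),
    list(length_mm = 50, youngs_modulus_MPa = 200)
  ))
  segments <- lapply(seg_raw, function(s) {
    if (is.null(s$length_mm) || is.null(s$youngs_modulus_MPa))
      stop("each segment needs `length_mm` and `youngs_modulus_MPa`")
    list(length = s$length_mm / 1000,
         material = wall_material(s$youngs_modulus_MPa * 1e6, nu))
  })
  model <- segmented_vessel(
    segments = segments,
    inlet_extension_length = pick(raw, "inlet_extension_mm", 30) / 1000,
    geometry = geometry,
    probe_positions = pick(raw, "probe_positions_mm", c(70, 100, 140)) / 1000
  )

  fl_raw <- pick(raw, "fluid", list())
  fluid <- fluid_properties(
    density = pick(fl_raw, "density_kg_m3", 1050),
    dynamic_viscosity = pick(fl_raw, "dynamic_viscosity_Pa_s", 0.0035)
  )

  wf_raw <- pick(raw, "waveform", list())
  # velocities may be given directly or via the Reynolds numbers they imply
  re_to_v <- function(re) re * fluid$dynamic_viscosity /
    (fluid$density * geometry$inner_diameter)
  v_dia <- if (!is.null(wf_raw$diastolic_mean_velocity_m_s)) {
    wf_raw$diastolic_mean_velocity_m_s
  } else re_to_v(pick(wf_raw, "diastolic_reynolds", 190))
  v_peak <- if (!is.null(wf_raw$peak_mean_velocity_m_s)) {
    wf_raw$peak_mean_velocity_m_s
  } else re_to_v(pick(wf_raw, "peak_reynolds", 500))
  waveform <- waveform_params(
    period = pick(wf_raw, "period_s", 1),
    diastolic_mean_velocity = v_dia,
    peak_mean_velocity = v_peak,
    peak_time_fraction = pick(wf_raw, "peak_time_fraction", 0.15),
    systolic_width_fraction = pick(wf_raw, "systolic_width_fraction", 0.25),
    harmonics_retained = pick(wf_raw, "harmonics_retained", 12L)
  )

  so_raw <- pick(raw, "solver", list())
  solver <- solver_settings(
    dx = pick(so_raw, "dx_mm", 0.5) / 1000,
    cfl = pick(so_raw, "cfl", 0.9),
    cycles = pick(so_raw, "cycles", 3L),
    output_dt = pick(so_raw, "output_dt_s", 0.01),
    convergence_tolerance = pick(so_raw, "convergence_tolerance", 1e-4)
  )

  list(model = model, fluid = fluid, waveform = waveform, solver = solver)
}

#' Write a run configuration to YAML
#'
#' Serializes a configuration (as returned by [read_config()] or
#' [config_from_list()]) back to the unit-suffixed YAML schema. Values are
#' written with enough digits that decimal inputs round-trip exactly.
#'
#' @param config A configuration list with `model`, `fluid`, `waveform`,
#'   `solver` components.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  m <- config$model
  out <- list(
    geometry = list(
      inner_diameter_mm = m$geometry$inner_diameter * 1000,
      outer_diameter_mm = m$geometry$outer_diameter * 1000
    ),
    inlet_extension_mm = m$inlet_extension_length * 1000,
    poissons_ratio = m$segments[[1]]$material$poissons_ratio,
    segments = lapply(m$segments, function(s) list(
      length_mm = s$length * 1000,
      youngs_modulus_MPa = s$material$youngs_modulus / 1e6
    )),
    probe_positions_mm = as.list(m$probe_positions * 1000),
    fluid = list(
      density_kg_m3 = config$fluid$density,
      dynamic_viscosity_Pa_s = config$fluid$dynamic_viscosity
    ),
    waveform = list(
      period_s = config$waveform$period,
      diastolic_mean_velocity_m_s = config$waveform$diastolic_mean_velocity,
      peak_mean_velocity_m_s = config$waveform$peak_mean_velocity,
      peak_time_fraction = config$waveform$peak_time_fraction,
      systolic_width_fraction = config$waveform$systolic_width_fraction,
      harmonics_retained = config$waveform$harmonics_retained
    ),
    solver = list(
      dx_mm = config$solver$dx * 1000,
      cfl = config$solver$cfl,
      cycles = config$solver$cycles,
      output_dt_s = config$solver$output_dt,
      convergence_tolerance = config$solver$convergence_tolerance
    )
  )
  yaml::write_yaml(out, path, precision = 17L)  # %.17g round-trips doubles
  invisible(path)
}
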