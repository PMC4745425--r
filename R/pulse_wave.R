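#' Elastic tube law
#'
#' Thin-wall elastic pressure--area relation closing the 1D flow equations:
#' `p(A) = p_ext + beta * (sqrt(A) - sqrt(A0))` with stiffness coefficient
#' `beta = sqrt(pi) * h * E / ((1 - nu^2) * A0)`. The `(1 - nu^2)` factor is
#' the plane-strain correction appropriate for a long tethered tube with a
#' nearly incompressible wall.
#'
#' @param geometry A [vessel_geometry()]; the lumen gives the reference area
#'   `A0 = pi * (D0/2)^2` and the wall thickness enters `beta`.
#' @param material A [wall_material()].
#' @param external_pressure Perivascular pressure in Pa (default 0).
#' @return An object of class `tube_law` with fields `reference_area` (m^2),
#'   `beta` (Pa/m), `external_pressure` (Pa).
#' @export
tube_law <- function(geometry, material, external_pressure = 0) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(material, "wall_material"))
  A0 <- pi * (geometry$inner_diameter / 2)^2
  beta <- sqrt(pi) * geometry$wall_thickness * material$youngs_modulus /
    ((1 - material$poissons_ratio^2) * A0)
  structure(list(reference_area = A0, beta = beta,
                 external_pressure = external_pressure),
            class = "tube_law")
}

#' Transmural pressure of a tube law
#'
#' @param law A [tube_law()].
#' @param area Lumen area(s) in m^2 (> 0).
#' @return Pressure(s) in Pa.
#' @export
tube_pressure <- function(law, area) {
  stopifnot(inherits(law, "tube_law"), all(area > 0))
  law$external_pressure + law$beta * (sqrt(area) - sqrt(law$reference_area))
}

#' Pulse-wave speed of an elastic tube
#'
#' Characteristic speed `c = sqrt(beta * sqrt(A) / (2 * rho))` of the 1D
#' system. At the reference area this equals the Moens--Korteweg-type speed
#' `sqrt(h * E / (2 * rho * R0 * (1 - nu^2)))`.
#'
#' @param law A [tube_law()].
#' @param area Lumen area(s) in m^2; defaults to the reference area.
#' @param fluid A [fluid_properties()].
#' @return Wave speed(s) in m/s.
#' @examples
#' law <- tube_law(vessel_geometry(), wall_material(5e6))
#' wave_speed(law, fluid = fluid_properties()) # ~28 m/s, compliant segment
#' @export
wave_speed <- function(law, area = law$reference_area, fluid) {
  stopifnot(inherits(law, "tube_law"), inherits(fluid, "fluid_properties"),
            all(area > 0))
  sqrt(law$beta * sqrt(area) / (2 * fluid$density))
}

#' Linear reflection coefficient at a stiffness junction
#'
#' For a small-amplitude pressure wave incident from the upstream tube onto
#' a junction between tubes of equal reference area but different stiffness,
#' the reflected pressure fraction is `(Z2 - Z1) / (Z1 + Z2)` with
#' characteristic impedance `Z = rho * c / A0`. A wave running from a stiff
#' tube into a compliant one (Z2 < Z1) is reflected with negative sign; for
#' a 40-fold modulus drop (200 to 5 MPa) the magnitude is
#' `(sqrt(200) - sqrt(5)) / (sqrt(200) + sqrt(5)) ~ 0.727`.
#'
#' @param law_upstream,law_downstream [tube_law()] objects of the two tubes.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless signed reflection coefficient.
#' @export
junction_reflection <- function(law_upstream, law_downstream, fluid) {
  z <- function(law) fluid$density * wave_speed(law, fluid = fluid) /
    law$reference_area
  z1 <- z(law_upstream)
  z2 <- z(law_downstream)
  (z2 - z1) / (z1 + z2)
}

#' Solver settings for the 1D pulse-wave scheme
#'
#' @param dx Cell size in m.
#' @param cfl CFL safety factor in (0, 1); the interior time step is chosen
#'   so that `dt * (|u| + c)_max / dx` stays below it.
#' @param cycles Number of cardiac cycles to run from zero initial
#'   conditions; three suffice for this model's transients to die out.
#' @param output_dt Output cadence in s (interior stepping subdivides it).
#' @param convergence_tolerance Relative cycle-to-cycle pressure change
#'   below which the run is flagged converged.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dx = 0.5e-3, cfl = 0.9, cycles = 3L,
                            output_dt = 0.01, convergence_tolerance = 1e-4) {
  stopifnot(dx > 0, cfl > 0, cfl < 1, cycles >= 1, output_dt > 0,
            convergence_tolerance > 0)
  structure(list(dx = dx, cfl = cfl, cycles = as.integer(cycles),
                 output_dt = output_dt,
                 convergence_tolerance = convergence_tolerance),
            class = "solver_settings")
}

#' Discrete pulse-wave state
#'
#' Cell-averaged area and flow on a uniform axial grid, for use with
#' [advance_state()].
#'
#' @param x_grid Cell-centre positions in m (uniform spacing).
#' @param area Lumen areas in m^2 (> 0).
#' @param flow Volumetric flows in m^3/s.
#' @param time Current time in s.
#' @return An object of class `pulse_wave_state`.
#' @export
pulse_wave_state <- function(x_grid, area, flow, time = 0) {
  stopifnot(length(x_grid) == length(area), length(area) == length(flow),
            all(is.finite(area)), all(area > 0), all(is.finite(flow)))
  dx <- diff(x_grid)
  if (length(dx) && max(abs(dx - dx[1])) > 1e-9 * dx[1])
    stop("x_grid must be uniform")
  structure(list(x_grid = x_grid, area = area, flow = flow, time = time),
            class = "pulse_wave_state")
}

# harmonic coefficients -> (ar, ai) vectors for the C++ inlet evaluator
harmonics_to_ri <- function(decomposition) {
  co <- decomposition$coefficients
  list(ar = Re(co), ai = Im(co), omega = decomposition$fundamental_frequency)
}

#' Advance a pulse-wave state
#'
#' Low-level driver of the MacCormack scheme: advances `n_steps` of size
#' `dt` with a per-cell tube-law stiffness. The inlet either prescribes the
#' cross-sectional mean velocity (via a harmonic decomposition) or is
#' non-reflecting; the outlet is always non-reflecting (the incoming
#' characteristic is held at its rest value, the 1D reading of a
#' zero-normal-traction outflow). Aborts with an error if the CFL limit is
#' exceeded or the area leaves the physical range.
#'
#' @param state A [pulse_wave_state()].
#' @param beta Per-cell tube-law stiffness in Pa/m (length of the grid).
#' @param reference_area Common reference area A0 in m^2.
#' @param fluid A [fluid_properties()].
#' @param dt Time step in s.
#' @param n_steps Number of steps to take.
#' @param inlet `"nonreflecting"` or a [decompose()] result prescribing the
#'   inlet mean velocity over time.
#' @param cfl_limit Abort threshold for the observed CFL number.
#' @return The advanced [pulse_wave_state()], with attributes `v_in`,
#'   `v_out` (time-integrated boundary fluxes, m^3) and `max_cfl`.
#' @export
advance_state <- function(state, beta, reference_area, fluid, dt, n_steps,
                          inlet = "nonreflecting", cfl_limit = 0.95) {
  stopifnot(inherits(state, "pulse_wave_state"),
            length(beta) == length(state$area))
  dx <- state$x_grid[2] - state$x_grid[1]
  if (identical(inlet, "nonreflecting")) {
    inlet_type <- 0L
    ri <- list(ar = 0, ai = 0, omega = 0)
  } else if (inherits(inlet, "harmonic_decomposition")) {
    inlet_type <- 1L
    ri <- harmonics_to_ri(inlet)
  } else stop("`inlet` must be \"nonreflecting\" or a harmonic_decomposition")
  res <- .pw_advance_cpp(state$area, state$flow, beta, reference_area,
                         fluid$density, fluid$dynamic_viscosity,
                         dx, dt, as.integer(n_steps), state$time,
                         inlet_type, ri$omega, ri$ar, ri$ai, cfl_limit)
  if (!isTRUE(res$ok))
    stop(sprintf("pulse-wave step aborted at t = %.6g s: %s", res$t, res$message))
  out <- pulse_wave_state(state$x_grid, res$A, res$Q, res$t)
  attr(out, "v_in") <- res$v_in
  attr(out, "v_out") <- res$v_out
  attr(out, "max_cfl") <- res$max_cfl
  out
}

#' Simulate pulsatile flow through a segmented vessel
#'
#' Propagates the inlet mean-velocity waveform through the vessel with the
#' 1D area-averaged fluid-structure solver, starting from zero initial
#' conditions (A = A0, Q = 0) and running the configured number of cardiac
#' cycles. The per-cell tube-law stiffness follows the segment materials, so
#' waves reflect at the stiffness junctions. Probe series are linearly
#' interpolated to the exact probe positions at the output cadence; wall
#' shear stress at each probe is derived from the local flow and
#' instantaneous radius, by default through the Poiseuille closure
#' `tau = 4 mu Q / (pi R^3)` (a Womersley-corrected closure is available).
#' Cycle convergence is assessed as the maximum relative change of the
#' probe pressure waveforms between the last two cycles.
#'
#' @param model A [segmented_vessel()].
#' @param waveform A [mean_velocity_series()] for the inlet.
#' @param fluid A [fluid_properties()].
#' @param settings A [solver_settings()].
#' @param wss_method `"poiseuille"` (default) or `"womersley"`; see
#'   [wss_from_flow()].
#' @param inlet_harmonics Harmonics used to represent the inlet waveform
#'   (capped at the Nyquist limit of the series).
#' @param store_fields If `TRUE`, keep full-field area/flow snapshots at the
#'   output cadence (matrices under `$fields`).
#' @return An object of class `pulse_wave_run`: list with `probes` (one
#'   data.frame per probe: `time_s`, `pressure_Pa`, `area_m2`,
#'   `flow_m3_per_s`, `wss_Pa`, final cycle only), `probe_positions` (m),
#'   `all_cycles` (same columns, all cycles), `convergence` (per-probe
#'   relative change between the last two cycles), `converged`,
#'   `volume_audit` (change in stored volume vs net boundary influx),
#'   `wave_speeds` (per segment, m/s), `grid` (dx, n_cells, dt, steps),
#'   `max_cfl`, plus the inputs (`model`, `fluid`, `settings`, `period`).
#' @export
simulate_pulse_wave <- function(model, waveform, fluid, settings = solver_settings(),
                                wss_method = c("poiseuille", "womersley"),
                                inlet_harmonics = NULL, store_fields = FALSE) {
  stopifnot(inherits(model, "segmented_vessel"),
            inherits(waveform, "mean_velocity_series"),
            inherits(fluid, "fluid_properties"),
            inherits(settings, "solver_settings"))
  wss_method <- match.arg(wss_method)
  period <- waveform$period

  n_cells <- max(8L, as.integer(round(model$total_length / settings$dx)))
  dx <- model$total_length / n_cells
  x <- (seq_len(n_cells) - 0.5) * dx
  laws <- lapply(x, function(xi) tube_law(model$geometry, material_at(model, xi)))
  beta <- vapply(laws, `[[`, numeric(1), "beta")
  A0 <- laws[[1]]$reference_area

  n_period <- length(waveform$values) - 1L
  K <- if (is.null(inlet_harmonics)) min(20L, (n_period - 1L) %/% 2L) else inlet_harmonics
  inlet <- decompose(waveform, K)

  c0 <- vapply(laws, function(l) wave_speed(l, fluid = fluid), numeric(1))
  u_margin <- 2.5 * max(abs(waveform$values))  # distension raises |u| above the mean
  dt_cfl <- settings$cfl * dx / (max(c0) + u_margin)
  n_sub <- max(1L, as.integer(ceiling(settings$output_dt / dt_cfl)))
  dt <- settings$output_dt / n_sub

  n_frames_cycle <- as.integer(round(period / settings$output_dt))
  n_frames <- settings$cycles * n_frames_cycle
  times <- seq_len(n_frames) * settings$output_dt

  state <- pulse_wave_state(x, rep(A0, n_cells), rep(0, n_cells), time = 0)
  probe_x <- model$probe_positions
  interp_probe <- function(v) stats::approx(x, v, xout = probe_x, rule = 2)$y

  np <- length(probe_x)
  A_rec <- matrix(NA_real_, n_frames + 1L, np)
  Q_rec <- matrix(NA_real_, n_frames + 1L, np)
  A_rec[1L, ] <- interp_probe(state$area)
  Q_rec[1L, ] <- interp_probe(state$flow)
  fields <- if (store_fields) {
    list(x = x, times = c(0, times),
         area = matrix(NA_real_, n_frames + 1L, n_cells),
         flow = matrix(NA_real_, n_frames + 1L, n_cells))
  } else NULL
  if (store_fields) {
    fields$area[1L, ] <- state$area
    fields$flow[1L, ] <- state$flow
  }

  vol0 <- sum(state$area) * dx
  v_in <- 0; v_out <- 0; max_cfl <- 0
  for (f in seq_len(n_frames)) {
    state <- advance_state(state, beta, A0, fluid, dt, n_sub, inlet = inlet)
    v_in <- v_in + attr(state, "v_in")
    v_out <- v_out + attr(state, "v_out")
    max_cfl <- max(max_cfl, attr(state, "max_cfl"))
    A_rec[f + 1L, ] <- interp_probe(state$area)
    Q_rec[f + 1L, ] <- interp_probe(state$flow)
    if (store_fields) {
      fields$area[f + 1L, ] <- state$area
      fields$flow[f + 1L, ] <- state$flow
    }
  }
  vol1 <- sum(state$area) * dx
  audit_err <- abs((vol1 - vol0) - (v_in - v_out)) /
    max(vol0, abs(v_in) + abs(v_out))

  beta_probe <- vapply(probe_x, function(xi)
    tube_law(model$geometry, material_at(model, xi))$beta, numeric(1))
  all_times <- c(0, times)
  probes_all <- lapply(seq_len(np), function(j) {
    p <- beta_probe[j] * (sqrt(A_rec[, j]) - sqrt(A0))
    R <- sqrt(A_rec[, j] / pi)
    wss <- 4 * fluid$dynamic_viscosity * Q_rec[, j] / (pi * R^3)
    data.frame(time_s = all_times, pressure_Pa = p, area_m2 = A_rec[, j],
               flow_m3_per_s = Q_rec[, j], wss_Pa = wss)
  })

  # final cycle: frames covering (cycles-1)*T < t <= cycles*T
  last_idx <- seq.int(n_frames - n_frames_cycle + 2L, n_frames + 1L)
  prev_idx <- last_idx - n_frames_cycle
  probes <- lapply(probes_all, function(df) {
    out <- df[last_idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  if (wss_method == "womersley") {
    for (j in seq_len(np)) {
      probes[[j]]$wss_Pa <- wss_from_flow(probes[[j]]$flow_m3_per_s, period,
                                          model$geometry, fluid,
                                          method = "womersley")
    }
  }

  convergence <- if (settings$cycles >= 2L) {
    vapply(seq_len(np), function(j) {
      p_last <- probes_all[[j]]$pressure_Pa[last_idx]
      p_prev <- probes_all[[j]]$pressure_Pa[prev_idx]
      max(abs(p_last - p_prev)) / max(max(abs(p_last)), .Machine$double.eps)
    }, numeric(1))
  } else rep(NA_real_, np)
  converged <- settings$cycles >= 2L &&
    all(convergence <= settings$convergence_tolerance)
  if (!converged)
    warning(sprintf(
      "cycle-to-cycle pressure change %.3g exceeds tolerance %.3g (or < 2 cycles run)",
      max(convergence), settings$convergence_tolerance), call. = FALSE)

  seg_speeds <- vapply(model$segments, function(s)
    wave_speed(tube_law(model$geometry, s$material), fluid = fluid), numeric(1))

  structure(list(
    probes = probes, probe_positions = probe_x, all_cycles = probes_all,
    convergence = convergence, converged = converged,
    volume_audit = list(volume_change = vol1 - vol0, net_inflow = v_in - v_out,
                        relative_error = audit_err),
    wave_speeds = seg_speeds,
    grid = list(dx = dx, n_cells = n_cells, dt = dt,
                steps_per_frame = n_sub, n_frames = n_frames),
    max_cfl = max_cfl, fields = fields,
    model = model, fluid = fluid, settings = settings, period = period,
    wss_method = wss_method
  ), class = "pulse_wave_run")
}

#' @export
print.pulse_wave_run <- function(x, ...) {
  cat(sprintf("1D pulse-wave run: %d cells (dx = %.3g mm), dt = %.3g us, %d cycles\n",
              x$grid$n_cells, 1000 * x$grid$dx, 1e6 * x$grid$dt,
              x$settings$cycles))
  cat(sprintf("  segment wave speeds: %s m/s\n",
              paste(sprintf("%.1f", x$wave_speeds), collapse = ", ")))
  cat(sprintf("  cycle convergence (max rel. change, last two cycles): %s\n",
              paste(sprintf("%.2e", x$convergence), collapse = ", ")))
  cat(sprintf("  converged: %s; volume audit rel. error: %.2e; max CFL %.3f\n",
              x$converged, x$volume_audit$relative_error, x$max_cfl))
  invisible(x)
}
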