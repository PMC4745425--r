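# Shared simulation fixtures, computed once per test run on first use.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_fluid <- function() fluid_properties()
default_waveform <- function() generate_waveform(waveform_params(), 256L)

# reference stiff--compliant--stiff run at the default resolution
default_run <- function() memo("default_run",
  simulate_pulse_wave(build_default_model(), default_waveform(),
                      default_fluid(), solver_settings()))

# same model with dx and dt halved, for the grid-convergence check
fine_run <- function() memo("fine_run",
  simulate_pulse_wave(build_default_model(), default_waveform(),
                      default_fluid(), solver_settings(dx = 0.25e-3)))

# uniform near-rigid tube (E = 2 GPa) with the Womersley WSS closure
rigid_run <- function() memo("rigid_run", {
  rigid <- segmented_vessel(
    list(list(length = 0.18, material = wall_material(2e9))),
    0, vessel_geometry(), probe_positions = c(0.07, 0.10, 0.14))
  simulate_pulse_wave(rigid, default_waveform(), default_fluid(),
                      solver_settings(dx = 1e-3, cycles = 2L),
                      wss_method = "womersley")
})

# uniform stiff tube driven by a constant inlet velocity (steady regime)
steady_run <- function() memo("steady_run", {
  stiff <- segmented_vessel(
    list(list(length = 0.18, material = wall_material(200e6))),
    0, vessel_geometry(), probe_positions = c(0.07, 0.10, 0.14))
  wf <- generate_waveform(
    waveform_params(diastolic_mean_velocity = 0.12, peak_mean_velocity = 0.12),
    64L)
  simulate_pulse_wave(stiff, wf, default_fluid(),
                      solver_settings(dx = 1e-3, cycles = 2L))
})

# single right-going small-amplitude pulse in a uniform compliant tube;
# returns the measured propagation speed and the tube-law speed
pulse_speed_experiment <- function() memo("pulse_speed", {
  fl <- default_fluid()
  law <- tube_law(vessel_geometry(), wall_material(5e6))
  A0 <- law$reference_area
  c0 <- wave_speed(law, fluid = fl)
  N <- 600L; dx <- 0.3 / N
  x <- (seq_len(N) - 0.5) * dx
  A <- A0 * (1 + 0.01 * exp(-((x - 0.05) / 0.01)^2))
  u <- 4 * (wave_speed(law, A, fl) - c0)    # right-running simple wave
  st <- pulse_wave_state(x, A, A * u)
  dt <- 0.9 * dx / (c0 * 1.05)
  n <- round(0.1 / c0 / dt)                 # ~10 cm of travel
  st2 <- advance_state(st, rep(law$beta, N), A0, fl, dt, n)
  centroid <- function(s) sum(s$x_grid * (s$area - A0)) / sum(s$area - A0)
  list(measured = (centroid(st2) - centroid(st)) / (n * dt),
       analytic = c0,
       audit = abs((sum(st2$area) - sum(st$area)) * dx -
                     (attr(st2, "v_in") - attr(st2, "v_out"))) /
               (sum(st$area) * dx))
})

# small pressure pulse launched in a stiff tube towards a compliant one;
# returns measured and analytic junction reflection coefficients
reflection_experiment <- function() memo("reflection", {
  fl <- default_fluid()
  g <- vessel_geometry()
  law1 <- tube_law(g, wall_material(200e6))
  law2 <- tube_law(g, wall_material(5e6))
  A0 <- law1$reference_area
  c1 <- wave_speed(law1, fluid = fl)
  N <- 1000L; dx <- 1 / N
  x <- (seq_len(N) - 0.5) * dx
  beta <- ifelse(x < 0.5, law1$beta, law2$beta)
  dp <- 50                                   # small amplitude: ~0.02% of A0
  A <- A0 + 2 * sqrt(A0) * dp / law1$beta * exp(-((x - 0.25) / 0.03)^2)
  u <- 4 * (wave_speed(law1, A, fl) - c1)
  u[x >= 0.5] <- 0; A[x >= 0.5] <- A0
  st <- pulse_wave_state(x, A, A * u)
  p_of <- function(s) beta * (sqrt(s$area) - sqrt(A0))
  p_inc <- max(p_of(st)[x < 0.5])
  dt <- 0.9 * dx / (c1 * 1.05)
  n <- round(0.4 / c1 / dt)                  # pulse reaches junction and returns
  st2 <- advance_state(st, beta, A0, fl, dt, n)
  refl <- p_of(st2)[x < 0.45]
  list(measured = refl[which.max(abs(refl))] / p_inc,
       analytic = junction_reflection(law1, law2, fl))
})
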