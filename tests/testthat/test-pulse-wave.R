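test_that("tube law and wave speed match their closed forms", {
  fl <- default_fluid()
  g <- vessel_geometry()
  law <- tube_law(g, wall_material(5e6))
  A0 <- pi * 0.004^2
  expect_equal(law$reference_area, A0)
  expect_equal(tube_pressure(law, A0), 0)
  # p(A) strictly increasing
  A <- A0 * seq(0.8, 1.2, length.out = 21)
  expect_true(all(diff(tube_pressure(law, A)) > 0))
  # Moens-Korteweg-type speed at the reference area
  mk <- sqrt(0.001 * 5e6 / (2 * 1050 * 0.004 * (1 - 0.499^2)))
  expect_equal(wave_speed(law, fluid = fl), mk)
  expect_equal(mk, 28.153, tolerance = 1e-4)
  # c ~ sqrt(E): 40x modulus -> sqrt(40)x speed
  law_s <- tube_law(g, wall_material(200e6))
  expect_equal(wave_speed(law_s, fluid = fl) / wave_speed(law, fluid = fl),
               sqrt(40))
  # beta -> 0 gives speed -> 0
  soft <- law; soft$beta <- 0
  expect_equal(wave_speed(soft, fluid = fl), 0)
})

test_that("junction reflection coefficient follows the impedance mismatch", {
  fl <- default_fluid()
  g <- vessel_geometry()
  law_s <- tube_law(g, wall_material(200e6))
  law_c <- tube_law(g, wall_material(5e6))
  expect_equal(junction_reflection(law_s, law_s, fl), 0)
  r <- junction_reflection(law_s, law_c, fl)
  expect_equal(abs(r), (sqrt(200) - sqrt(5)) / (sqrt(200) + sqrt(5)),
               tolerance = 1e-12)
  expect_lt(r, 0)                              # into the more compliant tube
  expect_equal(junction_reflection(law_c, law_s, fl), -r)
})

test_that("the rest state is a fixed point to machine precision", {
  fl <- default_fluid()
  law <- tube_law(vessel_geometry(), wall_material(5e6))
  A0 <- law$reference_area
  N <- 150L
  x <- (seq_len(N) - 0.5) * (0.3 / N)
  st <- pulse_wave_state(x, rep(A0, N), rep(0, N))
  st2 <- advance_state(st, rep(law$beta, N), A0, fl, dt = 5e-6, n_steps = 200)
  expect_equal(st2$area, st$area, tolerance = 1e-15)
  expect_lt(max(abs(st2$flow)), 1e-18)
})

test_that("a small pulse advances at the tube-law wave speed", {
  ex <- pulse_speed_experiment()
  expect_lt(abs(ex$measured - ex$analytic) / ex$analytic, 0.02)
})

test_that("the volume audit closes for a boundary-driven run", {
  ex <- pulse_speed_experiment()
  expect_lt(ex$audit, 1e-8)
  expect_lt(default_run()$volume_audit$relative_error, 1e-8)
})

test_that("a pulse hitting a stiff-to-compliant junction reflects as predicted", {
  ex <- reflection_experiment()
  expect_lt(abs(ex$measured - ex$analytic) / abs(ex$analytic), 0.05)
  expect_lt(ex$measured, 0)
})

test_that("the stepper aborts with diagnostics on CFL violation", {
  fl <- default_fluid()
  law <- tube_law(vessel_geometry(), wall_material(200e6))
  A0 <- law$reference_area
  N <- 50L
  x <- (seq_len(N) - 0.5) * (0.1 / N)
  st <- pulse_wave_state(x, rep(A0, N), rep(0, N))
  # dt far beyond dx / c for the stiff tube
  expect_error(advance_state(st, rep(law$beta, N), A0, fl,
                             dt = 1e-3, n_steps = 10), "CFL")
})

test_that("zero inflow yields an all-zero solution", {
  fl <- default_fluid()
  m <- build_default_model()
  wf <- generate_waveform(
    waveform_params(diastolic_mean_velocity = 0, peak_mean_velocity = 0), 64L)
  run <- simulate_pulse_wave(m, wf, fl, solver_settings(dx = 2e-3, cycles = 2L))
  for (df in run$probes) {
    expect_equal(df$pressure_Pa, rep(0, nrow(df)))
    expect_equal(df$flow_m3_per_s, rep(0, nrow(df)))
    expect_equal(df$wss_Pa, rep(0, nrow(df)))
  }
})

test_that("steady flow in a uniform tube matches the Poiseuille pressure drop", {
  run <- steady_run()
  p <- vapply(run$probes, function(d) mean(d$pressure_Pa), numeric(1))
  R <- 0.004
  expected <- 8 * default_fluid()$dynamic_viscosity * 0.12 * (0.14 - 0.07) / R^2
  expect_equal(p[1] - p[3], expected, tolerance = 0.05)
  # flow is uniform along the tube in steady state
  q <- vapply(run$probes, function(d) mean(d$flow_m3_per_s), numeric(1))
  expect_equal(q / (pi * R^2), rep(0.12, 3), tolerance = 0.01)
})

test_that("three cycles reach a periodic solution at every probe", {
  run <- default_run()
  expect_true(run$converged)
  expect_true(all(run$convergence < 0.01))
})

test_that("in the rigid limit the probe WSS matches the Womersley analytic series", {
  run <- rigid_run()
  wf <- default_waveform()
  ff <- solve_womersley(default_fluid(), vessel_geometry(), decompose(wf, 12),
                        times = run$probes[[1]]$time_s)
  for (df in run$probes) {
    expect_lt(max(abs(df$wss_Pa - ff$wall_shear_stress)) /
                max(abs(ff$wall_shear_stress)), 0.05)
  }
  # probe-to-probe waveform delay vanishes: peak flow frames coincide
  peaks <- vapply(run$probes, function(d) which.max(d$flow_m3_per_s), integer(1))
  expect_true(all(peaks == peaks[1]))
})

test_that("halving dx and dt leaves probe pressures unchanged to under 1%", {
  r1 <- default_run()
  r2 <- fine_run()
  for (j in seq_along(r1$probes)) {
    d <- max(abs(r1$probes[[j]]$pressure_Pa - r2$probes[[j]]$pressure_Pa)) /
      max(abs(r2$probes[[j]]$pressure_Pa))
    expect_lt(d, 0.01)
  }
})

test_that("cycle-max strain is largest at the compliant middle probe", {
  run <- default_run()
  A0 <- pi * 0.004^2
  smax <- vapply(run$probes, function(d)
    max(hoop_strain_kinematic(d$area_m2, A0)), numeric(1))
  expect_gt(smax[2], smax[1])
  expect_gt(smax[2], smax[3])
})

test_that("a single cycle is flagged as not demonstrating convergence", {
  fl <- default_fluid()
  m <- build_default_model()
  wf <- generate_waveform(waveform_params(), 128L)
  expect_warning(
    run <- simulate_pulse_wave(m, wf, fl, solver_settings(dx = 2e-3, cycles = 1L)),
    "cycle")
  expect_false(run$converged)
})
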