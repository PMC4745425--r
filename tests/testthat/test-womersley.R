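test_that("complex Bessel series agrees with base besselJ on the real axis", {
  x <- c(0.1, 1, 2.5, 7, 13, 19)
  expect_equal(Re(pulsewave:::bessel_j0_complex(complex(real = x))),
               besselJ(x, 0), tolerance = 1e-8)
  expect_equal(Re(pulsewave:::bessel_j1_complex(complex(real = x))),
               besselJ(x, 1), tolerance = 1e-8)
  # derivative identity J0' = -J1 at a complex Womersley-type argument
  z <- 5.5 * complex(real = -1, imaginary = 1) / sqrt(2)
  h <- 1e-6
  dj0 <- (pulsewave:::bessel_j0_complex(z + h) -
            pulsewave:::bessel_j0_complex(z - h)) / (2 * h)
  expect_equal(dj0, -pulsewave:::bessel_j1_complex(z), tolerance = 1e-8)
})

test_that("dimensionless numbers match their closed forms", {
  fl <- default_fluid()
  g <- vessel_geometry()
  expect_equal(womersley_number(fl, g, 1), 5.491747, tolerance = 1e-6)
  # alpha ~ 1/sqrt(mu) and 1/sqrt(T)
  fl4 <- fluid_properties(1050, 4 * 0.0035)
  expect_equal(womersley_number(fl4, g, 1), womersley_number(fl, g, 1) / 2)
  expect_equal(womersley_number(fl, g, 4), womersley_number(fl, g, 1) / 2)
  expect_error(womersley_number(fl, g, 0), "positive")

  expect_equal(reynolds_number(fl, 0.008, 0), 0)
  expect_equal(reynolds_number(fl, 0.008, 0.0833), 199.92, tolerance = 1e-6)
  expect_equal(reynolds_number(fl, 0.008, 0.2),
               2 * reynolds_number(fl, 0.008, 0.1))
  expect_error(reynolds_number(fl, 0.008, -0.1), "non-negative")
})

steady_decomposition <- function(u_m) {
  tgrid <- seq(0, 1, length.out = 33)
  decompose(mean_velocity_series(tgrid, rep(u_m, 33)), 4)
}

test_that("steady mode recovers Poiseuille flow exactly", {
  fl <- default_fluid()
  g <- vessel_geometry()
  ff <- solve_womersley(fl, g, steady_decomposition(0.2), radial_points = 33,
                        times = c(0, 0.25, 0.5))
  R <- g$inner_diameter / 2
  expect_equal(ff$axial_velocity[1, ], rep(0.4, 3))            # centreline 2 u_m
  parab <- 2 * 0.2 * (1 - (ff$radial_grid / R)^2)
  expect_equal(ff$axial_velocity[, 2], parab, tolerance = 1e-12)
  expect_equal(ff$wall_shear_stress, rep(0.7, 3))              # 4 mu u_m / R
  expect_equal(ff$pressure_gradient,
               rep(-8 * fl$dynamic_viscosity * 0.2 / R^2, 3))
  s <- wss_series(ff)
  expect_equal(c(s$max, s$min, s$mean), rep(0.7, 3))
})

test_that("no-slip and zero-flow behaviour hold for pulsatile fields", {
  fl <- default_fluid()
  g <- vessel_geometry()
  wf <- generate_waveform(waveform_params(), 256L)
  ff <- solve_womersley(fl, g, decompose(wf, 12), radial_points = 64,
                        times = seq(0, 1, 0.02))
  expect_true(all(ff$axial_velocity[64, ] == 0))
  zero <- solve_womersley(fl, g, steady_decomposition(0), times = seq(0, 1, 0.1))
  expect_true(all(zero$axial_velocity == 0))
  expect_true(all(wss_series(zero)$wss == 0))
  expect_error(solve_womersley(fl, g, steady_decomposition(0.1),
                               radial_points = 4), "radial_points")
})

test_that("cross-sectional average of the solved field reproduces the input series", {
  fl <- default_fluid()
  g <- vessel_geometry()
  wf <- generate_waveform(waveform_params(), 256L)
  ff <- solve_womersley(fl, g, decompose(wf, 12), radial_points = 201,
                        times = wf$times)
  r <- ff$radial_grid
  R <- max(r)
  avg <- apply(ff$axial_velocity, 2, function(u) {
    f <- u * r
    2 / R^2 * sum((f[-1] + f[-length(f)]) / 2 * diff(r))
  })
  expect_lt(max(abs(avg - wf$values)) / max(abs(wf$values)), 0.005)
})

test_that("wall shear stress matches a finite-difference oracle at the wall", {
  fl <- default_fluid()
  g <- vessel_geometry()
  wf <- generate_waveform(waveform_params(), 256L)
  nr <- 2001
  ff <- solve_womersley(fl, g, decompose(wf, 12), radial_points = nr,
                        times = seq(0, 1, 0.01))
  dr <- diff(ff$radial_grid)[1]
  # one-sided difference of u at the wall; u(R) = 0
  tau_fd <- fl$dynamic_viscosity * ff$axial_velocity[nr - 1, ] / dr
  expect_lt(max(abs(tau_fd - ff$wall_shear_stress)) /
              max(abs(ff$wall_shear_stress)), 0.02)
})

test_that("oscillatory profile approaches the quasi-steady parabola as alpha -> 0", {
  g <- vessel_geometry()
  R <- g$inner_diameter / 2
  r <- seq(0, R, length.out = 101)
  mode <- pulsewave:::womersley_mode(0.1, 0.0035, R, 1, alpha_min = 1e-6)
  parab <- 2 * (1 - (r / R)^2)
  expect_lt(max(Mod(mode$profile(r) - parab)) / 2, 0.01)
  # the guarded branch below alpha_min is the exact quasi-steady limit
  tiny <- pulsewave:::womersley_mode(1e-5, 0.0035, R, 1)
  expect_equal(tiny$wss, complex(real = 4 * 0.0035 / R))
})

test_that("WSS phase lead over the mean velocity grows monotonically with alpha", {
  R <- vessel_geometry()$inner_diameter / 2
  lead <- vapply(c(1, 3, 5.5, 10), function(alpha) {
    Arg(pulsewave:::womersley_mode(alpha, 0.0035, R, 1)$wss)
  }, numeric(1))
  expect_true(all(lead > 0))
  expect_true(all(diff(lead) > 0))
})

test_that("the two WSS closures agree for slow oscillations and steady flow", {
  fl <- default_fluid()
  g <- vessel_geometry()
  R <- g$inner_diameter / 2
  q0 <- 0.1 * pi * R^2
  flow <- rep(q0, 50)
  expect_equal(wss_from_flow(flow, 1, g, fl, "poiseuille"),
               wss_from_flow(flow, 1, g, fl, "womersley"))
  # very long period -> quasi-steady: closures converge
  tt <- seq(0, 999, length.out = 100) / 1000
  flow2 <- q0 * (1 + 0.3 * cos(2 * pi * tt))
  w_p <- wss_from_flow(flow2, 1000, g, fl, "poiseuille")
  w_w <- wss_from_flow(flow2, 1000, g, fl, "womersley")
  expect_equal(w_w, w_p, tolerance = 0.01)
})
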