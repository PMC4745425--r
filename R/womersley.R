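# Maclaurin series for J0 and J1 at complex argument. Base R's besselJ is
# real-only. The alternating series is safe here: for |z| <= ~25 the largest
# term is comparable to the result (no catastrophic cancellation), and the
# oscillatory-mode arguments i^{3/2} * alpha_k stay well inside that range
# for physiological Womersley numbers and harmonic counts.
bessel_j0_complex <- function(z) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  q <- -(z * z) / 4
  for (m in 1:120) {
    term <- term * q / (m * m)
    out <- out + term
    if (all(Mod(term) < 1e-18 * (Mod(out) + 1))) break
  }
  out
}

bessel_j1_complex <- function(z) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  q <- -(z * z) / 4
  for (m in 1:120) {
    term <- term * q / (m * (m + 1))
    out <- out + term
    if (all(Mod(term) < 1e-18 * (Mod(out) + 1))) break
  }
  out * z / 2
}

#' Womersley number
#'
#' alpha = (D0/2) * sqrt(2 * pi * rho / (T * mu)): the ratio of oscillatory
#' inertia to viscous forces for pulsatile flow of period `period` in a tube
#' of inner diameter D0. For the reference carotid parameters (D0 = 8 mm,
#' T = 1 s, rho = 1050 kg/m^3, mu = 0.0035 Pa.s) it evaluates to 5.49,
#' i.e. 5.5 to two significant figures.
#'
#' @param fluid A [fluid_properties()].
#' @param geometry A [vessel_geometry()] (its inner diameter is used).
#' @param period Oscillation period in s.
#' @return The dimensionless Womersley number.
#' @examples
#' womersley_number(fluid_properties(), vessel_geometry(), 1) # ~5.49
#' @export
womersley_number <- function(fluid, geometry, period) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geometry, "vessel_geometry"),
            is.numeric(period), length(period) == 1L)
  if (!is.finite(period) || period <= 0) stop("`period` must be positive (s)")
  (geometry$inner_diameter / 2) *
    sqrt(2 * pi * fluid$density / (period * fluid$dynamic_viscosity))
}

#' Reynolds number
#'
#' Re = rho * D0 * V / mu based on the inner diameter and the instantaneous
#' cross-sectional mean velocity. Reverse-flow instants should be passed as
#' `abs(V)` by the caller; a negative velocity is rejected.
#'
#' @param fluid A [fluid_properties()].
#' @param inner_diameter Inner diameter in m.
#' @param mean_velocity Cross-sectional mean velocity in m/s (>= 0);
#'   vectorized.
#' @return Dimensionless Reynolds number(s).
#' @export
reynolds_number <- function(fluid, inner_diameter, mean_velocity) {
  stopifnot(inherits(fluid, "fluid_properties"),
            is.numeric(inner_diameter), inner_diameter > 0,
            is.numeric(mean_velocity))
  if (any(mean_velocity < 0))
    stop("`mean_velocity` must be non-negative; take abs() for reverse flow")
  fluid$density * inner_diameter * mean_velocity / fluid$dynamic_viscosity
}

# Per-mode Womersley factors for a mode whose *mean velocity* coefficient is
# c_k (one-sided convention). Returns complex factors:
#   profile(r): velocity shape, cross-sectional average 1
#   wss:  tau_k such that tau(t) += Re(c_k * wss * exp(i k w t)), positive
#         for forward flow (tau = -mu du/dr at the wall)
#   dpdx: G_k such that dp/dx(t) += Re(c_k * dpdx * exp(i k w t))
# For alpha below `alpha_min` the quasi-steady (Poiseuille) limit is used to
# avoid cancellation in 1 - 2 J1/(Lambda J0).
womersley_mode <- function(alpha, mu, radius, k_omega_rho, alpha_min = 1e-3) {
  if (alpha < alpha_min) {
    return(list(
      profile = function(r) 2 * (1 - (r / radius)^2) + 0i,
      wss = complex(real = 4 * mu / radius),
      dpdx = complex(real = -8 * mu / radius^2)
    ))
  }
  lambda <- alpha * complex(real = -1, imaginary = 1) / sqrt(2)  # i^{3/2} alpha
  j0l <- bessel_j0_complex(lambda)
  j1l <- bessel_j1_complex(lambda)
  D <- 1 - 2 * j1l / (lambda * j0l)
  list(
    profile = function(r) (1 - bessel_j0_complex(lambda * r / radius) / j0l) / D,
    wss = -mu * (lambda / radius) * j1l / (j0l * D),
    dpdx = -1i * k_omega_rho / D
  )
}

#' Womersley solution for pulsatile flow in a rigid tube
#'
#' Superposes the exact axisymmetric harmonic solutions of the Navier-Stokes
#' equations in a rigid straight tube, driven by the harmonic decomposition
#' of a prescribed cross-sectional mean-velocity series (flow-driven, not
#' pressure-driven: the per-mode pressure gradient is back-computed and
#' reported). The steady mode is the Poiseuille parabola; each oscillatory
#' mode k is the classical Bessel-function profile normalized so its
#' cross-sectional average equals coefficient k.
#'
#' @param fluid A [fluid_properties()].
#' @param geometry A [vessel_geometry()].
#' @param harmonics A [decompose()] result for the driving mean-velocity
#'   series.
#' @param radial_points Number of radial samples from the axis to the wall
#'   (>= 8).
#' @param times Output times in s.
#' @return An object of class `flow_field`: list with `radial_grid` (m, 0 to
#'   inner radius), `times` (s), `axial_velocity` (matrix, radius x time,
#'   m/s), `wall_shear_stress` (Pa over time, positive for forward flow),
#'   `pressure_gradient` (dp/dx, Pa/m over time, negative for forward flow)
#'   and `mean_velocity` (m/s over time).
#' @export
solve_womersley <- function(fluid, geometry, harmonics, radial_points = 64L,
                            times = seq(0, 2 * pi / harmonics$fundamental_frequency,
                                        length.out = 101L)) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geometry, "vessel_geometry"),
            inherits(harmonics, "harmonic_decomposition"))
  if (radial_points < 8) stop("`radial_points` must be >= 8 (grid must resolve the wall)")
  R <- geometry$inner_diameter / 2
  mu <- fluid$dynamic_viscosity
  nu <- mu / fluid$density
  omega <- harmonics$fundamental_frequency
  coefs <- harmonics$coefficients
  r <- seq(0, R, length.out = radial_points)

  c0 <- Re(coefs[1])
  u <- outer(2 * c0 * (1 - (r / R)^2), rep(1, length(times)))
  wss <- rep(4 * mu * c0 / R, length(times))
  dpdx <- rep(-8 * mu * c0 / R^2, length(times))
  vmean <- rep(c0, length(times))

  for (k in seq_along(coefs)[-1]) {
    ck <- coefs[k]
    if (ck == 0) next
    kk <- k - 1
    alpha <- R * sqrt(kk * omega / nu)
    mode <- womersley_mode(alpha, mu, R, kk * omega * fluid$density)
    phase <- exp(1i * kk * omega * times)
    u <- u + Re(outer(ck * mode$profile(r), phase))
    wss <- wss + Re(ck * mode$wss * phase)
    dpdx <- dpdx + Re(ck * mode$dpdx * phase)
    vmean <- vmean + Re(ck * phase)
  }
  u[length(r), ] <- 0  # no-slip holds analytically; pin round-off
  structure(list(radial_grid = r, times = times, axial_velocity = u,
                 wall_shear_stress = wss, pressure_gradient = dpdx,
                 mean_velocity = vmean,
                 geometry = geometry, fluid = fluid),
            class = "flow_field")
}

#' Wall shear stress series of a flow field
#'
#' Extracts the wall shear stress over time together with its cycle maximum,
#' minimum and mean.
#'
#' @param flowfield A [solve_womersley()] result.
#' @return A list with `times`, `wss` (Pa) and scalars `max`, `min`, `mean`.
#' @export
wss_series <- function(flowfield) {
  stopifnot(inherits(flowfield, "flow_field"))
  w <- flowfield$wall_shear_stress
  list(times = flowfield$times, wss = w,
       max = max(w), min = min(w), mean = mean(w))
}

#' Wall shear stress from a flow series
#'
#' Converts a volumetric flow series at a location into wall shear stress,
#' either by the quasi-steady Poiseuille closure tau = 4 mu Q / (pi R^3) or
#' by the Womersley closure, which applies the analytic per-harmonic
#' amplitude and phase factors of oscillatory tube flow to the harmonic
#' content of the series and is accurate for near-rigid tubes.
#'
#' @param flow Volumetric flow in m^3/s, uniformly sampling one period
#'   (without a duplicated endpoint).
#' @param period Period in s.
#' @param geometry A [vessel_geometry()].
#' @param fluid A [fluid_properties()].
#' @param method `"poiseuille"` or `"womersley"`.
#' @param harmonics Harmonic count for the Womersley closure; capped at the
#'   Nyquist limit of the series.
#' @return Wall shear stress in Pa at the input sample times.
#' @export
wss_from_flow <- function(flow, period, geometry, fluid,
                          method = c("poiseuille", "womersley"),
                          harmonics = 12L) {
  method <- match.arg(method)
  R <- geometry$inner_diameter / 2
  mu <- fluid$dynamic_viscosity
  if (method == "poiseuille") return(4 * mu * flow / (pi * R^3))
  n <- length(flow)
  K <- min(harmonics, (n - 1) %/% 2)
  omega <- 2 * pi / period
  X <- stats::fft(flow / (pi * R^2)) / n          # mean-velocity harmonics
  tt <- period * (seq_len(n) - 1) / n
  wss <- rep(4 * mu * Re(X[1]) / R, n)
  nu <- mu / fluid$density
  for (kk in seq_len(K)) {
    ck <- 2 * X[kk + 1]
    alpha <- R * sqrt(kk * omega / nu)
    mode <- womersley_mode(alpha, mu, R, kk * omega * fluid$density)
    wss <- wss + Re(ck * mode$wss * exp(1i * kk * omega * tt))
  }
  wss
}
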