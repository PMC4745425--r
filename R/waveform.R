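#' Mean velocity implied by a Reynolds number
#'
#' Inverts Re = rho * D0 * V / mu for the cross-sectional mean velocity V.
#' Used to anchor the default inlet waveform to a stated diastolic/systolic
#' Reynolds range rather than to hard-coded velocities, so that overriding
#' the fluid or geometry keeps the Reynolds envelope consistent.
#'
#' @param reynolds Target Reynolds number (>= 0).
#' @param fluid A [fluid_properties()].
#' @param geometry A [vessel_geometry()].
#' @return Mean velocity in m/s.
#' @export
mean_velocity_from_reynolds <- function(reynolds,
                                        fluid = fluid_properties(),
                                        geometry = vessel_geometry()) {
  stopifnot(is.numeric(reynolds), reynolds >= 0)
  reynolds * fluid$dynamic_viscosity / (fluid$density * geometry$inner_diameter)
}

#' Inlet waveform parameters
#'
#' Parameters of the closed-form carotid-like inlet waveform: a diastolic
#' plateau plus a single Gaussian systolic pulse, band-limited to a fixed
#' number of Fourier harmonics. Default velocities are derived from a
#' diastolic Reynolds number of 190 and a peak-systolic Reynolds number of
#' 500 in an 8 mm lumen (V = Re mu / (rho D0), about 0.079 and 0.208 m/s),
#' the physiological envelope of common-carotid flow.
#'
#' @param period Cardiac period in s.
#' @param diastolic_mean_velocity Plateau (diastolic) mean velocity, m/s.
#' @param peak_mean_velocity Peak-systolic mean velocity, m/s; must be
#'   >= diastolic (equality degenerates to a constant waveform).
#' @param peak_time_fraction Location of the systolic peak as a fraction of
#'   the period, in (0, 1).
#' @param systolic_width_fraction Full width at half maximum of the
#'   Gaussian systolic pulse as a fraction of the period, in (0, 1).
#' @param harmonics_retained Number of Fourier harmonics kept, >= 1.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(period = 1,
                            diastolic_mean_velocity = mean_velocity_from_reynolds(190),
                            peak_mean_velocity = mean_velocity_from_reynolds(500),
                            peak_time_fraction = 0.15,
                            systolic_width_fraction = 0.25,
                            harmonics_retained = 12L) {
  stopifnot(is.numeric(period), period > 0,
            is.numeric(diastolic_mean_velocity), diastolic_mean_velocity >= 0,
            is.numeric(peak_mean_velocity),
            peak_time_fraction > 0, peak_time_fraction < 1,
            systolic_width_fraction > 0, systolic_width_fraction < 1,
            harmonics_retained >= 1)
  if (peak_mean_velocity < diastolic_mean_velocity)
    stop("`peak_mean_velocity` must not be below `diastolic_mean_velocity`")
  structure(list(period = period,
                 diastolic_mean_velocity = diastolic_mean_velocity,
                 peak_mean_velocity = peak_mean_velocity,
                 peak_time_fraction = peak_time_fraction,
                 systolic_width_fraction = systolic_width_fraction,
                 harmonics_retained = as.integer(harmonics_retained)),
            class = "waveform_params")
}

# Closed-form Fourier coefficients of the plateau + Gaussian systolic pulse,
# one-sided convention: v(t) = Re(sum_k c_k exp(i k w t)), c_0 real.
# The periodically wrapped Gaussian bump of full width at half maximum
# `systolic_width_fraction * period` has two-sided coefficients
# amp * sqrt(2 pi) * sf * exp(-(2 pi k sf)^2 / 2) * exp(-2 pi i k tp),
# sf = sigma / period. Unlike a raised-cosine pulse, these decay faster
# than geometrically, so truncation at the default 12 harmonics leaves no
# visible Gibbs ripple and the sampled minimum/maximum stay on the
# configured diastolic/peak velocities to ~1e-5 relative.
waveform_coefficients <- function(params) {
  K <- params$harmonics_retained
  amp <- params$peak_mean_velocity - params$diastolic_mean_velocity
  sf <- params$systolic_width_fraction / (2 * sqrt(2 * log(2)))  # FWHM -> sigma
  tp <- params$peak_time_fraction
  k <- seq_len(K)
  g <- sqrt(2 * pi) * sf * exp(-(2 * pi * k * sf)^2 / 2)
  c0 <- params$diastolic_mean_velocity + amp * sqrt(2 * pi) * sf
  ck <- 2 * amp * g * exp(-2i * pi * k * tp)   # one-sided = twice two-sided
  c(complex(real = c0, imaginary = 0), ck)
}

#' Generate the periodic inlet mean-velocity waveform
#'
#' Samples one full period of the band-limited plateau + systolic-pulse
#' waveform on a uniform grid including both endpoints, so the first and
#' last samples coincide (periodicity). The waveform is deterministic; an
#' optional Gaussian perturbation (for robustness studies) requires an
#' explicit seed.
#'
#' @param params A [waveform_params()].
#' @param n_samples Number of samples across one period (>= 16), endpoints
#'   included.
#' @param noise_sd Standard deviation (m/s) of optional additive Gaussian
#'   noise; 0 (default) keeps the generator deterministic.
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @return An object of class `mean_velocity_series` with fields `times`
#'   (s), `values` (m/s) and `period` (s).
#' @examples
#' wf <- generate_waveform(waveform_params(), 256)
#' range(wf$values) # diastolic plateau to systolic peak
#' @export
generate_waveform <- function(params, n_samples = 256L, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "waveform_params"), n_samples >= 16)
  times <- seq(0, params$period, length.out = n_samples)
  values <- evaluate_harmonics_raw(waveform_coefficients(params),
                                   2 * pi / params$period, times)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("noisy waveform generation requires an explicit `seed`")
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    values <- values + stats::rnorm(n_samples, sd = noise_sd)
    values[n_samples] <- values[1]  # keep the series periodic
  }
  mean_velocity_series(times, values, params$period)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Periodic mean-velocity series
#'
#' Container for one period of a cross-sectional mean velocity signal on a
#' strictly increasing time grid whose first and last samples coincide.
#'
#' @param times Time grid in s covering exactly one period, endpoints
#'   included.
#' @param values Mean velocities in m/s, same length as `times`.
#' @param period Period in s; defaults to `times[length(times)] - times[1]`.
#' @return An object of class `mean_velocity_series`.
#' @export
mean_velocity_series <- function(times, values, period = NULL) {
  stopifnot(is.numeric(times), is.numeric(values), length(times) == length(values),
            length(times) >= 2, all(is.finite(times)), all(is.finite(values)),
            all(diff(times) > 0))
  if (is.null(period)) period <- times[length(times)] - times[1]
  scale <- max(abs(values), .Machine$double.eps)
  if (abs(values[1] - values[length(values)]) > 1e-12 * scale)
    stop("series is not periodic: first and last values differ")
  structure(list(times = times, values = values, period = period),
            class = "mean_velocity_series")
}

#' Fourier decomposition of a periodic series
#'
#' Discrete Fourier analysis of one period of a uniformly sampled periodic
#' signal, truncated to a requested harmonic count. The representation is
#' one-sided: `v(t) = Re(sum_{k=0}^{K} c_k exp(i k omega t))` with real
#' `c_0` equal to the time-average.
#'
#' @param series A [mean_velocity_series()] on a uniform grid.
#' @param harmonics Number of harmonics K to retain; must not exceed the
#'   Nyquist limit of the grid, `floor((n - 1) / 2)` for `n` samples per
#'   period.
#' @return An object of class `harmonic_decomposition` with fields
#'   `fundamental_frequency` (rad/s) and `coefficients` (complex, index
#'   k = 0..K).
#' @seealso [reconstruct_harmonics()] for the inverse.
#' @export
decompose <- function(series, harmonics) {
  stopifnot(inherits(series, "mean_velocity_series"), harmonics >= 0)
  t <- series$times
  v <- series$values
  # drop the duplicated endpoint so the grid covers the period exactly once
  if (isTRUE(all.equal(t[length(t)] - t[1], series$period))) {
    t <- t[-length(t)]
    v <- v[-length(v)]
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("decompose() requires a uniform time grid")
  n <- length(v)
  if (harmonics > (n - 1) %/% 2)
    stop(sprintf("harmonics = %d exceeds the Nyquist limit %d of an %d-point grid",
                 harmonics, (n - 1) %/% 2, n))
  X <- stats::fft(v) / n
  coef <- complex(real = numeric(harmonics + 1))
  coef[1] <- complex(real = Re(X[1]), imaginary = 0)
  if (harmonics >= 1) coef[1 + seq_len(harmonics)] <- 2 * X[1 + seq_len(harmonics)]
  structure(list(fundamental_frequency = 2 * pi / series$period,
                 coefficients = coef),
            class = "harmonic_decomposition")
}

evaluate_harmonics_raw <- function(coefficients, omega, times) {
  v <- rep(Re(coefficients[1]), length(times))
  for (k in seq_along(coefficients)[-1]) {
    v <- v + Re(coefficients[k] * exp(1i * (k - 1) * omega * times))
  }
  v
}

#' Evaluate a harmonic decomposition at given times
#'
#' @param decomposition A [decompose()] result.
#' @param times Times in s (any values; the representation is periodic).
#' @return Numeric vector of reconstructed values.
#' @export
reconstruct_harmonics <- function(decomposition, times) {
  stopifnot(inherits(decomposition, "harmonic_decomposition"))
  evaluate_harmonics_raw(decomposition$coefficients,
                         decomposition$fundamental_frequency, times)
}

#' Export / import a waveform as two-column CSV
#'
#' The on-disk format is one period of the series with a header row,
#' columns `time_s` and `mean_velocity_m_per_s`, so a digitized measured
#' waveform can be substituted for the synthetic default.
#'
#' @param series A [mean_velocity_series()].
#' @param path CSV file path.
#' @return `path` invisibly (`write_waveform_csv`); a
#'   [mean_velocity_series()] (`read_waveform_csv`).
#' @export
write_waveform_csv <- function(series, path) {
  stopifnot(inherits(series, "mean_velocity_series"))
  utils::write.csv(data.frame(time_s = series$times,
                              mean_velocity_m_per_s = series$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "mean_velocity_m_per_s") %in% names(df)))
    stop("waveform CSV must have columns time_s, mean_velocity_m_per_s")
  mean_velocity_series(df$time_s, df$mean_velocity_m_per_s)
}
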