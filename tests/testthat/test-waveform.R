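test_that("default waveform hits the configured diastolic and peak velocities", {
  p <- waveform_params()
  wf <- generate_waveform(p, 256L)
  expect_equal(min(wf$values), p$diastolic_mean_velocity, tolerance = 0.01)
  expect_equal(max(wf$values), p$peak_mean_velocity, tolerance = 0.01)
  # periodicity of the sampled series
  expect_equal(wf$values[1], wf$values[length(wf$values)],
               tolerance = 1e-12)
  # default velocities bracket the diastole/systole Reynolds envelope
  re <- reynolds_number(default_fluid(), 0.008, range(wf$values))
  expect_equal(re[1], 190, tolerance = 0.01)
  expect_equal(re[2], 500, tolerance = 0.01)
})

test_that("degenerate and invalid waveform parameters are handled", {
  const <- generate_waveform(
    waveform_params(diastolic_mean_velocity = 0.1, peak_mean_velocity = 0.1),
    64L)
  expect_equal(const$values, rep(0.1, 64))
  expect_error(waveform_params(diastolic_mean_velocity = 0.2,
                               peak_mean_velocity = 0.1),
               "must not be below")
  expect_error(generate_waveform(waveform_params(), 8L), "n_samples")
  expect_error(generate_waveform(waveform_params(), 64L, noise_sd = 0.01),
               "seed")
})

test_that("waveform time-average is invariant under grid refinement", {
  avg <- vapply(c(64L, 256L, 2048L), function(n) {
    wf <- generate_waveform(waveform_params(), n)
    mean(wf$values[-length(wf$values)])   # drop duplicated endpoint
  }, numeric(1))
  expect_equal(avg[1], avg[3], tolerance = 1e-6)
  expect_equal(avg[2], avg[3], tolerance = 1e-6)
})

test_that("decompose recovers constants, single modes, and round-trips", {
  tgrid <- seq(0, 1, length.out = 65)
  const <- mean_velocity_series(tgrid, rep(0.3, 65))
  d <- decompose(const, 10)
  expect_equal(Re(d$coefficients[1]), 0.3)
  expect_true(all(Mod(d$coefficients[-1]) < 1e-14))

  cosine <- mean_velocity_series(tgrid, cos(2 * pi * tgrid))
  d1 <- decompose(cosine, 10)
  expect_equal(Mod(d1$coefficients[2]), 1, tolerance = 1e-10)
  expect_true(all(Mod(d1$coefficients[-2]) < 1e-10))

  wf <- generate_waveform(waveform_params(), 256L)
  d2 <- decompose(wf, 120)   # all harmonics of the band-limited signal
  expect_equal(reconstruct_harmonics(d2, wf$times), wf$values,
               tolerance = 1e-10)
  # coefficient 0 equals the time-average
  expect_equal(Re(d2$coefficients[1]), mean(wf$values[-256]))
})

test_that("decompose enforces the Nyquist limit and grid uniformity", {
  tgrid <- seq(0, 1, length.out = 33)   # 32 samples per period
  s <- mean_velocity_series(tgrid, 0.1 + 0.01 * sin(2 * pi * tgrid))
  expect_silent(decompose(s, 15))
  expect_error(decompose(s, 16), "Nyquist")
  irregular <- mean_velocity_series(c(0, 0.1, 0.5, 1), c(1, 2, 3, 1))
  expect_error(decompose(irregular, 1), "uniform")
})

test_that("Parseval's identity holds for band-limited signals", {
  for (K in c(4L, 12L)) {
    p <- waveform_params(harmonics_retained = K)
    wf <- generate_waveform(p, 128L)
    v <- wf$values[-128]
    d <- decompose(wf, 63)
    co <- d$coefficients
    power_coefs <- Re(co[1])^2 + sum(Mod(co[-1])^2) / 2
    expect_equal(mean(v^2), power_coefs, tolerance = 1e-10)
  }
})

test_that("waveform CSV export and import round-trip", {
  wf <- generate_waveform(waveform_params(), 128L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  wf2 <- read_waveform_csv(path)
  expect_equal(wf2$times, wf$times)
  expect_equal(wf2$values, wf$values)
  expect_error(read_waveform_csv({
    p2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1:3, b = 1:3), p2, row.names = FALSE)
    p2
  }), "columns")
})

test_that("noisy generation is reproducible under a seed and leaves RNG state alone", {
  a <- generate_waveform(waveform_params(), 64L, noise_sd = 0.005, seed = 7L)
  b <- generate_waveform(waveform_params(), 64L, noise_sd = 0.005, seed = 7L)
  expect_identical(a$values, b$values)
  expect_equal(a$values[1], a$values[64])
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(generate_waveform(waveform_params(), 64L,
                                             noise_sd = 0.005, seed = 7L))
  expect_identical(runif(1), x1)
})
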