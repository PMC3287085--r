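test_that("Fourier fit recovers exact low-order signals", {
  t <- seq(0, 1, length.out = 64)[-64]
  w <- fit_fourier(cbind(t, 1 + sin(2 * pi * t)), K = 1, period = 1)
  expect_equal(w$a0, 1, tolerance = 1e-9)
  expect_equal(w$b[1], 1, tolerance = 1e-9)
  expect_equal(w$a[1], 0, tolerance = 1e-9)
  wc <- fit_fourier(cbind(t, rep(3.2, length(t))), K = 4, period = 1)
  expect_equal(wc$a0, 3.2, tolerance = 1e-12)
  expect_true(all(abs(c(wc$a, wc$b)) < 1e-12))
})

test_that("fit is a least-squares projection: nested models and refit idempotence", {
  set.seed(7)
  t <- seq(0, 1, length.out = 101)[-101]
  v <- 2 + 0.5 * sin(2 * pi * t) + 0.3 * cos(6 * pi * t) +
    0.1 * sin(10 * pi * t + 0.4) + 0.05 * sin(14 * pi * t)
  w2 <- fit_fourier(cbind(t, v), K = 2, period = 1)
  w8 <- fit_fourier(cbind(t, v), K = 8, period = 1)
  expect_lte(w8$rms, w2$rms)
  # refitting a reconstructed waveform returns the same coefficients
  vr <- eval_waveform(w8, t)
  w8b <- fit_fourier(cbind(t, vr), K = 8, period = 1)
  expect_equal(w8b$a0, w8$a0, tolerance = 1e-9)
  expect_equal(w8b$a, w8$a, tolerance = 1e-9)
  expect_equal(w8b$b, w8$b, tolerance = 1e-9)
})

test_that("underdetermined fits are rejected", {
  t <- seq(0, 1, length.out = 6)[-6]
  expect_error(fit_fourier(cbind(t, t), K = 3), "underdetermined")
})

test_that("waveform evaluation is periodic to machine precision", {
  w <- default_waveform()
  t <- c(0, 0.137, 0.4, 0.99)
  for (n in c(1, 3, 17)) {
    expect_equal(eval_waveform(w, t + n * w$period), eval_waveform(w, t),
                 tolerance = 1e-12)
  }
  expect_lt(abs(eval_waveform(w, 0) - eval_waveform(w, w$period)), 1e-9)
})

test_that("default waveform peaks at 0.4 s, stays non-negative, scales to 17 mm/s inlet peak", {
  w <- default_waveform()
  expect_equal(w$period, 1.0)
  g <- seq(0, w$period, by = 1e-3)
  v <- eval_waveform(w, g)
  expect_equal(g[which.max(v)], 0.4)
  expect_true(all(v >= 0))
  # spatial peak of the parabolic profile at systole = 1.5 x mean = 17 mm/s
  expect_equal(1.5 * max(v), 0.017, tolerance = 1e-9)
  # secondary diastolic feature: local maximum at 0.7 s
  i7 <- which(abs(g - 0.7) < 1e-9)
  expect_true(v[i7] > v[i7 - 20] && v[i7] > v[i7 + 20])
})

test_that("parabolic inlet profile has the right mean, peak and wall values", {
  w <- default_waveform()
  t <- 0.4
  eta <- seq(-0.5, 0.5, length.out = 2001)
  pr <- inlet_profile(w, t, eta, direction = c(1, 0))
  vt <- eval_waveform(w, t)
  # spatial mean equals v(t) (trapezoid quadrature of an exact parabola)
  expect_equal(mean(pr[-1, 1] + pr[-nrow(pr), 1]) / 2, vt, tolerance = 1e-6)
  expect_equal(max(pr[, 1]), 1.5 * vt, tolerance = 1e-12)
  expect_equal(pr[1, 1], 0)
  expect_equal(pr[nrow(pr), 1], 0)
  expect_true(all(pr[, 2] == 0))
})

test_that("waveform CSV round trip preserves the fit", {
  w <- default_waveform()
  path <- tempfile(fileext = ".csv")
  write_waveform_csv(w, path, n = 400)
  w2 <- read_waveform_csv(path, K = 8, period = 1)
  g <- seq(0, 1, by = 1e-3)
  expect_equal(eval_waveform(w2, g), eval_waveform(w, g), tolerance = 1e-9)
})
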