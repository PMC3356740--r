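test_that("extraterrestrial radiation matches the standard daily formula", {
  # published worked example of the same formula: 20 S, 3 September
  expect_equal(extraterrestrial_radiation(-20, 246), 32.2, tolerance = 0.01)
  # equator near the March equinox: ~37.6-37.8 MJ (dr and delta are small)
  expect_equal(extraterrestrial_radiation(0, 80), 37.6, tolerance = 0.01)
  # polar night: the sun never rises
  expect_identical(extraterrestrial_radiation(70, 355), 0)
  expect_true(all(extraterrestrial_radiation(seq(-90, 90, by = 15),
                                             rep(100, 13)) >= 0))
  expect_error(extraterrestrial_radiation(91, 100), "latitude")
})

test_that("extraterrestrial radiation is hemispherically symmetric at equinox", {
  # doy 81 is the closest day to the vernal equinox (declination ~0)
  for (phi in c(10, 35, 60)) {
    a <- extraterrestrial_radiation(phi, 81)
    b <- extraterrestrial_radiation(-phi, 81)
    expect_lt(abs(a - b) / a, 0.01)
  }
})

test_that("diurnal range follows the raw and smoothed conventions", {
  ws <- make_series(tmax = c(20, 22), tmin = c(10, 12))
  expect_equal(delta_t(ws, "raw"), c(10, 10))
  # 20 - (10 + 12)/2 = 9; last day falls back to the raw range
  expect_equal(delta_t(ws, "smoothed"), c(9, 10))
  # constant weather: both conventions agree
  wc <- make_series(tmax = rep(18, 5), tmin = rep(7, 5))
  expect_equal(delta_t(wc, "raw"), delta_t(wc, "smoothed"))
  # smoothing can go negative; it is floored at zero
  wn <- make_series(tmax = c(10, 20), tmin = c(9, 15))
  expect_equal(delta_t(wn, "smoothed")[1], 0)
})

test_that("weekly range average is a centered shrinking-window mean", {
  wc <- make_series(tmax = rep(20, 10), tmin = rep(10, 10))
  expect_equal(weekly_delta_t(wc), rep(10, 10))
  wi <- make_series(tmax = c(0, 0, 0, 7, 0, 0, 0), tmin = rep(0, 7))
  expect_equal(weekly_delta_t(wi)[4], 1)
  # brute-force oracle on an arbitrary series
  set.seed(1)
  dt <- round(runif(20, 2, 15), 2)
  ws <- make_series(tmax = dt, tmin = rep(0, 20))
  expected <- vapply(seq_len(20), function(i) {
    h <- min(3, i - 1, 20 - i)
    mean(dt[(i - h):(i + h)])
  }, numeric(1))
  expect_equal(weekly_delta_t(ws), expected)
  # interior points of a linear ramp are unchanged by the centered mean
  wr <- make_series(tmax = 1:15, tmin = rep(0, 15))
  expect_equal(weekly_delta_t(wr)[4:12], as.numeric(4:12))
})

test_that("Fourier transmissivity evaluates its harmonics", {
  expect_equal(fourier_tau(0.7, 123), 0.7)
  expect_equal(fourier_tau(c(0.7, 0.1, 0, 0, 0), 365), 0.8)
  # orthogonality: the annual mean equals the constant term
  co <- c(0.72, 0.05, -0.03, 0.02, 0.04)
  expect_equal(mean(fourier_tau(co, 1:365)), 0.72, tolerance = 1e-10)
  expect_warning(fourier_tau(c(0.95, 0.1, 0, 0, 0), 365), "outside")
  expect_error(fourier_tau(c(0.7, 0.1), 10), "length")
})

test_that("S-shaped clear-day fraction curves honour their limits", {
  expect_equal(fcd_brutsaert(0, f = 0.476, g = 0.1, n = 2), 0.476)
  # at dT = 1/g the denominator is 2 regardless of n
  expect_equal(fcd_brutsaert(10, f = 0.476, g = 0.1, n = 2.285), 0.738)
  expect_equal(fcd_brutsaert(10, f = 0.476, g = 0.1, n = 7), 0.738)
  expect_equal(fcd_brutsaert(1e6, f = 0.3, g = 0.1, n = 2), 1,
               tolerance = 1e-6)
  expect_equal(fcd_brutsaert(c(0, 5, 50), f = 1, g = 0.1, n = 2),
               rep(1, 3))
  expect_equal(fcd_van_genuchten(0, f = 0.4, g = 0.1, n = 2, m = 0.7), 0.4)
  expect_error(fcd_brutsaert(-1, 0.4, 0.1, 2), "negative")
  expect_error(fcd_van_genuchten(-1, 0.4, 0.1, 2, 1), "negative")
})

test_that("van Genuchten curve with m = 1 equals the Brutsaert curve", {
  grid <- expand.grid(dt = seq(0, 25, length.out = 10),
                      f = seq(0, 0.9, length.out = 10),
                      g = seq(0.02, 0.5, length.out = 10),
                      n = seq(0.5, 5, length.out = 10))
  a <- fcd_van_genuchten(grid$dt, grid$f, grid$g, grid$n, m = 1)
  b <- fcd_brutsaert(grid$dt, grid$f, grid$g, grid$n)
  expect_lt(max(abs(a - b)), 1e-12)
})

test_that("both clear-day curves are monotone and bounded in [f, 1)", {
  set.seed(7)
  for (k in 1:25) {
    f <- runif(1, 0, 0.95); g <- runif(1, 0.02, 0.5)
    n <- runif(1, 0.3, 5); m <- runif(1, 0.2, 3)
    dt <- sort(runif(50, 0, 30))
    for (v in list(fcd_brutsaert(dt, f, g, n),
                   fcd_van_genuchten(dt, f, g, n, m))) {
      expect_true(all(diff(v) >= -1e-12))
      expect_true(all(v >= f - 1e-12 & v < 1))
    }
  }
})

test_that("S-shape estimation composes its factors", {
  md <- test_metadata()
  ws <- make_series(tmax = rep(20, 4), tmin = rep(10, 4),
                    prcp = c(0, 5, 0, 5))
  # flat Fcd (g tiny): Rs reduces to Ra * tau * f
  spec <- variant_spec("constant", "brutsaert")
  ps <- parameter_set(0.72, list(all = c(f = 0.5, g = 1e-4, n = 5)))
  rs <- estimate_s_shape(ws, spec, ps, md)
  ra <- extraterrestrial_radiation(40, ws$doy)
  expect_equal(rs, ra * 0.72 * 0.5, tolerance = 1e-8)
  # wet vs dry day, all else equal: ratio 1 : (1 + q)
  spec_q <- variant_spec("constant", "brutsaert", precip_factor = TRUE)
  psq <- parameter_set(0.72, list(all = c(f = 0.5, g = 1e-4, n = 5)),
                       q = 0.25)
  rsq <- estimate_s_shape(ws, spec_q, psq, md)
  # divide out the astronomical trend between the two days
  expect_equal((rsq[2] / ra[2]) / (rsq[1] / ra[1]), 1.25, tolerance = 1e-6)
})

test_that("full 7-parameter variant matches a step-by-step hand evaluation", {
  md <- site_metadata(latitude = 40, dt_avg = 11)
  ws <- weather_series(2001L, doy = c(100L, 101L), tmax = c(21, 23),
                       tmin = c(9, 11), prcp = c(3, 0))
  ps <- regional_parameters(md)
  rs <- estimate_s_shape(ws, "0-2-1-4", ps, md)
  # independent arithmetic for day 1 (doy 100, wet):
  ra <- extraterrestrial_radiation(40, 100)
  tau <- 0.00591 * 11 + 0.6758
  dts <- 21 - (9 + 11) / 2                      # smoothed range
  fcd <- 1 - (1 - 0.476) / (1 + (0.106 * dts)^2.285)
  x <- 2 * pi * 100 / 365
  fs <- 1 + (-0.259) * cos(x) + (-0.00377 * 11 + 0.0312) * sin(x) +
    (-0.00341 * 11 + 0.0597) * cos(2 * x) +
    (-0.00076 * 11 + 0.0320) * sin(2 * x)
  expect_equal(rs[1], ra * tau * fcd * (1 + 2.25) * fs, tolerance = 1e-12)
})

test_that("reference models reproduce their closed-form special cases", {
  md <- 40
  # constant temperatures: smoothed dT = 0
  ws0 <- make_series(tmax = rep(10, 5), tmin = rep(10, 5), prcp = 0)
  dc <- reference_params("DC", tau = 0.7, b = 0.2, c = 50)
  expect_equal(estimate_reference(ws0, dc, md), rep(0, 5))
  db <- reference_params("DB", tau = 0.7, b = 0.1, c = 0.3, d = 0.4)
  expect_equal(estimate_reference(ws0, db, md), rep(0, 5))
  # HKS with only the intercept: the negative-estimate pathology
  hks <- reference_params("HKS", a = 0, b = 0, c = 0, d = 0, e = -1)
  ws <- make_series(tmax = c(20, 25), tmin = c(10, 12), prcp = c(0, 4))
  expect_equal(estimate_reference(ws, hks, md), c(-1, -1))
})

test_that("DC and DB estimates vanish as the range goes to zero", {
  eps <- 1e-6
  ws <- make_series(tmax = rep(10 + eps, 3), tmin = rep(10, 3))
  ra <- extraterrestrial_radiation(40, ws$doy)
  dc <- estimate_reference(ws, reference_params("DC", tau = 0.7, b = 0.5,
                                                c = 30), 40)
  db <- estimate_reference(ws, reference_params("DB", tau = 0.7, b = 0.1,
                                                c = 1.2, d = 0.5), 40)
  expect_true(all(dc <= 1e-6 * ra))
  expect_true(all(db <= 1e-6 * ra))
})

test_that("LS model uses neighbouring occurrence flags with edge fallback", {
  ls <- reference_params("LS", a = 0.7, b = 0.2, c = 1.5,
                         d = -0.1, e = -0.2, f = -0.1, g = 0)
  ws <- make_series(tmax = rep(20, 3), tmin = rep(10, 3),
                    prcp = c(5, 0, 5))
  rs <- estimate_reference(ws, ls, 40)
  expect_length(rs, 3)
  expect_true(all(is.finite(rs)))
  ra <- extraterrestrial_radiation(40, ws$doy)
  base <- 0.7 * (1 - exp(-0.2 * 10^1.5))
  # middle day: R_prev = 1, R_i = 0, R_next = 1
  expect_equal(rs[2], ra[2] * base * (1 - 0.1 - 0.1), tolerance = 1e-10)
  # first day reuses its own flag for the missing predecessor
  expect_equal(rs[1], ra[1] * base * (1 - 0.1 - 0.2), tolerance = 1e-10)
})

test_that("physical-bounds clamp counts and fixes violations", {
  ra <- rep(30, 4)
  ok <- apply_physical_bounds(c(5, 10, 20, 23), ra, 0.8)
  expect_equal(ok$rs, c(5, 10, 20, 23))
  expect_equal(c(ok$n_low, ok$n_high), c(0, 0))
  bad <- apply_physical_bounds(c(-1, 60, 10, -0.2), ra, 0.8)
  expect_equal(bad$rs, c(0, 24, 10, 0))
  expect_equal(c(bad$n_low, bad$n_high), c(2, 1))
})
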