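test_that("baseline fluctuation estimates the noise, not the drift", {
  tt <- seq(0, 99.9, by = 0.1)
  flat <- trace(tt, rep(2, length(tt)))
  b <- baseline_fluctuation(flat, c(0, 99))
  expect_equal(b$fluctuation, 1e-12)

  set.seed(21)
  noisy <- trace(seq_len(1000), rnorm(1000, 0, 1))
  b2 <- baseline_fluctuation(noisy, c(1, 1000))
  expect_lt(abs(b2$fluctuation - 1) , 0.1)

  # linear drift of total range 50 over the window plus unit noise: the
  # detrended fluctuation tracks the noise, a raw sd would track the drift
  drift <- trace(seq_len(1000), 0.05 * seq_len(1000) + rnorm(1000, 0, 1))
  b3 <- baseline_fluctuation(drift, c(1, 1000))
  expect_lt(abs(b3$fluctuation - 1), 0.15)
  expect_gt(stats::sd(drift$values), 10)
})

test_that("take-off detection fires at the sustained 5-sigma crossing", {
  tt <- seq(0, 200, by = 0.1)
  base <- baseline_stats(mean = 0, fluctuation = 1)
  flat <- trace(tt, rep(0, length(tt)))
  expect_true(is.na(detect_takeoff(flat, base, 50)))

  step <- trace(tt, ifelse(tt >= 100, 10, 0))
  expect_equal(detect_takeoff(step, base, 50), 100)

  ramp <- trace(tt, pmax(tt, 0))   # 1 unit/s from t = 0
  expect_equal(detect_takeoff(ramp, base, 0), 5)
  expect_error(detect_takeoff(ramp, base, 500), "span")
})

test_that("take-off is translation-equivariant and scale-invariant", {
  set.seed(8)
  tt <- seq(0, 120, by = 0.1)
  vv <- ifelse(tt >= 60, 8 * (1 - exp(-(tt - 60) / 5)), 0) +
    rnorm(length(tt), 0, 0.1)
  base <- baseline_stats(mean = 0, fluctuation = 0.1)
  t0 <- detect_takeoff(trace(tt, vv), base, 30)
  for (shift in c(7.3, 100)) {
    expect_equal(detect_takeoff(trace(tt + shift, vv), base, 30 + shift),
                 t0 + shift, tolerance = 1e-9)
  }
  for (c_scale in c(0.5, 40)) {
    scaled_base <- baseline_stats(mean = 0, fluctuation = 0.1 * c_scale)
    f1 <- wave_features(trace(tt, vv), 30, baseline = base)
    f2 <- wave_features(trace(tt, c_scale * vv), 30, baseline = scaled_base)
    expect_equal(f2$takeoff_time, f1$takeoff_time)
    expect_equal(f2$amplitude, c_scale * f1$amplitude, tolerance = 1e-9)
    expect_equal(f2$rise_time, f1$rise_time, tolerance = 1e-9)
  }
})

test_that("wave features follow closed forms on a linear ramp and a step", {
  tt <- seq(0, 100, by = 0.1)
  ramp <- trace(tt, tt)   # 0 -> 100 over 100 s
  f <- wave_features(ramp, 0, baseline = baseline_stats(mean = 0, fluctuation = 1),
                     window = 100)
  expect_equal(f$takeoff_time, 5)
  expect_equal(f$amplitude, 100)
  expect_equal(f$rise_time, 63.2 - 5, tolerance = 1e-6)

  step <- trace(tt, ifelse(tt >= 40, 25, 0))
  fs <- wave_features(step, 10, baseline = baseline_stats(mean = 0, fluctuation = 0.5),
                      window = 100)
  expect_equal(fs$takeoff_time, 40)
  expect_lte(fs$rise_time, 0.1)   # within one sample interval

  # negative (depolarization-style) deflections give positive amplitude
  vp <- trace(tt, -ifelse(tt >= 40, 25, 0), kind = "vp")
  fv <- wave_features(vp, 10, baseline = baseline_stats(mean = 0, fluctuation = 0.5),
                      window = 100)
  expect_equal(fv$amplitude, 25)
})

test_that("no-wave propagates as an undetected result", {
  tt <- seq(0, 100, by = 0.1)
  flat <- trace(tt, rnorm(length(tt), 0, 0.01))
  f <- wave_features(flat, 50, baseline = baseline_stats(mean = 0, fluctuation = 1))
  expect_false(f$detected)
  expect_true(is.na(f$rise_time))
})

test_that("pair velocity is distance over take-off difference", {
  f1 <- structure(list(detected = TRUE, takeoff_time = 10, position = 1),
                  class = "wave_features")
  f2 <- structure(list(detected = TRUE, takeoff_time = 12.56, position = 2),
                  class = "wave_features")
  expect_equal(pair_velocity(f1, f2), 1 / 2.56, tolerance = 1e-9)
  f3 <- structure(list(detected = TRUE, takeoff_time = 16.25, position = 2),
                  class = "wave_features")
  expect_equal(pair_velocity(f1, f3), 0.16, tolerance = 1e-9)
  f_eq <- structure(list(detected = TRUE, takeoff_time = 10, position = 2),
                    class = "wave_features")
  expect_error(pair_velocity(f1, f_eq), "unbounded")
  expect_warning(v <- pair_velocity(f2, f1), "ordering")
  expect_lt(v, 0)
})

test_that("exponential decay fit is exact on noiseless data (log-linear oracle)", {
  x <- 1:4
  y <- 0.8 * exp(-x / 2.55)
  fit <- fit_exponential_decay(x, y)
  expect_equal(fit$decay_constant, 2.55, tolerance = 1e-6)
  expect_equal(fit$y0, 0.8, tolerance = 1e-6)
  oracle <- ols_line(x, log(y))
  expect_equal(-1 / oracle["slope"], 2.55, tolerance = 1e-9, ignore_attr = TRUE)

  expect_warning(flatfit <- fit_exponential_decay(x, rep(3, 4)), "decay")
  expect_true(is.infinite(flatfit$decay_constant))
  expect_error(fit_exponential_decay(x, c(1, -1, 1, 1)), "positive")
})

test_that("decay constant is recovered from noisy series (50-seed median)", {
  x <- 1:4
  lams <- sapply(1:50, function(s) {
    set.seed(s)
    y <- 5 * exp(-x / 1.29) * (1 + rnorm(4, 0, 0.03))
    fit_exponential_decay(x, y)$decay_constant
  })
  expect_lt(abs(median(lams) - 1.29) / 1.29, 0.1)
})

test_that("rise-time floor fit recovers the kinetic limit", {
  a <- seq(5, 80, length.out = 8)
  r <- 9.9 + 35 * exp(-a / 22)
  fit <- fit_risetime_floor(a, r)
  expect_equal(fit$floor, 9.9, tolerance = 1e-4)
  expect_equal(fit$scale, 22, tolerance = 1e-3)

  a2 <- seq(2, 40, length.out = 10)
  fit2 <- fit_risetime_floor(a2, 0.72 + 9 * exp(-a2 / 9))
  expect_equal(fit2$floor, 0.72, tolerance = 1e-4)

  const <- fit_risetime_floor(a, rep(4.4, 8))
  expect_equal(const$floor, 4.4)
  expect_equal(const$prefactor, 0)
})
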