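test_that("plug-flow front arrives at x/(u*r) and scales linearly with distance", {
  g <- stem_geometry(r = 0.012, source_mM = 75, positions_cm = c(1, 2))
  sc <- flow_scenario(u = 0.35, lateral_tau = 0)
  t1 <- front_arrival_time(sc, g$r, 1)
  expect_equal(t1, 1 / (0.35 * 0.012), tolerance = 1e-12)
  expect_equal(front_arrival_time(sc, g$r, 2), 2 * t1, tolerance = 1e-12)
  expect_equal(convection_concentration(g, sc, 1, c(t1 - 1, t1 + 1)), c(0, 75))
})

test_that("no flow means no transport; piecewise flow accumulates distance", {
  g <- stem_geometry()
  sc0 <- flow_scenario(u = 0, lateral_tau = 0)
  expect_equal(convection_concentration(g, sc0, 1.5, c(0, 1e6)), c(0, 0))
  # u = 0.35 for 100 s, stall for 50 s, then 0.7: manual cumulative oracle
  sc <- flow_scenario(u = c(0.35, 0, 0.7), t_change = c(0, 100, 150),
                      lateral_tau = 0)
  d100 <- 0.35 * 0.012 * 100
  x_target <- d100 + 0.7 * 0.012 * 30   # reached 30 s into the last segment
  expect_equal(front_arrival_time(sc, 0.012, x_target), 180, tolerance = 1e-9)
})

test_that("convection stays within [0, source] and is non-decreasing in time", {
  g <- stem_geometry()
  set.seed(5)
  for (i in 1:20) {
    sc <- flow_scenario(u = runif(1, 0, 1), lateral_tau = runif(1, 0, 120))
    x <- runif(1, 0.2, 3)
    tt <- seq(0, 2000, by = 10)
    cc <- convection_concentration(g, sc, x, tt)
    expect_true(all(cc >= 0 & cc <= g$source_mM))
    expect_true(all(diff(cc) >= -1e-12))
  }
})

test_that("diffusion model matches erfc closed form and a finite-difference solver", {
  # median of the complementary error function
  z_half <- erfc_inv(0.5)
  expect_equal(z_half, 0.4769, tolerance = 1e-4)
  D <- 1.96e-5
  t_half <- (1 / (2 * z_half))^2 / D
  expect_equal(diffusion_concentration(D, 1, 1, t_half), 0.5, tolerance = 1e-9)
  # equilibrium limit
  expect_gt(diffusion_concentration(D, 75, 1, 1e12), 74.99)
  # independent explicit finite-difference solution, interior points < 1%
  t_probe <- 5e4
  xq <- c(0.3, 0.6, 1.0, 1.5)
  fd <- fd_diffusion(D, 1, L = 6, nx = 240, t_end = t_probe, x_query = xq)
  cf <- diffusion_concentration(D, 1, xq, t_probe)
  expect_true(all(abs(fd - cf) / cf < 0.01))
})

test_that("diffusion timescale matches its quantile-function oracle and x^2 scaling", {
  D <- 1.96e-5
  t63 <- diffusion_timescale(D, 1, 0.632)
  z <- erfc_inv(0.632)
  expect_equal(t63, (1 / (2 * z))^2 / D, tolerance = 1e-8)
  expect_equal(t63 / 86400, 1.29, tolerance = 0.01)
  expect_equal(diffusion_timescale(D, 2, 0.632), 4 * t63, tolerance = 1e-6)
  expect_lt(diffusion_timescale(D, 1, 1e-6), 2e3)
  expect_error(diffusion_timescale(D, 1, 1.5), "fraction")
})

test_that("flow-rate fit recovers the truth on noiseless forward data", {
  g <- stem_geometry()
  sc <- transport_scenario(u = 0.35, lateral_tau = 60)
  traces <- gen_transport_traces(sc, seq(0, 1500, by = 5))
  fit <- fit_flow_rate(traces, g, lateral_tau = 60)
  expect_equal(fit$u_hat, 0.35, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-6)
  expect_equal(unname(fit$front_arrival),
               c(1, 2) / (0.35 * 0.012), tolerance = 1e-4)
})

test_that("flow-rate fit under 2% noise is accurate and nearly unbiased", {
  g <- stem_geometry()
  u_hats <- sapply(1:50, function(s) {
    sc <- transport_scenario(u = 0.35, lateral_tau = 60, noise_frac = 0.02,
                             seed = s)
    fit_flow_rate(gen_transport_traces(sc, seq(0, 1500, by = 5)), g,
                  lateral_tau = 60)$u_hat
  })
  expect_gte(mean(abs(u_hats - 0.35) / 0.35 <= 0.05), 0.95)
  expect_lt(abs(mean(u_hats) - 0.35) / 0.35, 0.01)
})

test_that("flat traces make the flow rate non-identifiable", {
  g <- stem_geometry()
  tt <- seq(0, 1000, by = 5)
  zero <- lapply(c(1, 2), function(x) trace(tt, rep(0, length(tt)),
                                            position = x, kind = "cation"))
  expect_error(fit_flow_rate(zero, g), "identifiable")
})

test_that("stomatal events are detected with their programmed delays", {
  set.seed(31)
  tt <- seq(0, 3000, by = 5)
  stim <- 300
  # ABA-like closure: flow 0.35 drops to 0 at stim+450, restores at +1090
  u <- ifelse(tt < stim + 450 | tt >= stim + 1090, 0.35, 0) +
    rnorm(length(tt), 0, 0.004)
  ev <- detect_flow_events(trace(tt, u, kind = "flow"), stim)
  sup <- ev[ev$type == "suppression", ]
  rec <- ev[ev$type == "recovery", ]
  expect_equal(nrow(sup), 1)
  expect_equal(sup$delay_s, 450, tolerance = 0.05)
  expect_equal(rec$delay_s[1], 640, tolerance = 0.05)

  # light-induced opening: ramp up from stim+1000
  u2 <- ifelse(tt < stim + 1000, 0, (tt - stim - 1000) * 2e-4) +
    rnorm(length(tt), 0, 0.002)
  ev2 <- detect_flow_events(trace(tt, 0.1 + u2, kind = "flow"), stim)
  acc <- ev2[ev2$type == "acceleration", ]
  expect_gte(nrow(acc), 1)
  expect_equal(acc$delay_s[1], 1000, tolerance = 0.08)

  # constant flow: nothing
  u3 <- rep(0.35, length(tt))
  expect_equal(nrow(detect_flow_events(trace(tt, u3, kind = "flow"), stim)), 0)
  expect_error(detect_flow_events(trace(tt, u3, kind = "flow"), 5000), "span")
})
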