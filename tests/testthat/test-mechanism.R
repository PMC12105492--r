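test_that("the resting lattice is an exact fixed point", {
  lat <- stem_lattice(length_cm = 5, u = 0)
  for (i in 1:2000) lat <- mech_step(lat, 0.01)
  expect_equal(max(abs(lat$vm)), 0)
  expect_equal(max(lat$h_apo), 0)
  expect_equal(max(abs(lat$ca_cyt - lat$params$ca_rest)), 0)
  expect_equal(max(abs(lat$ca_vac - lat$params$ca_store)), 0)
})

test_that("total H2O2 is conserved without production, degradation, or flow", {
  p <- mechanism_params(k_ao = 0, k_ao_xyl = 0, k_rboh = 0)
  lat <- stem_lattice(length_cm = 5, u = 0, params = p)
  lat$h_apo[20] <- 10
  lat$h_xyl[30] <- 5
  total0 <- sum(lat$h_apo + lat$h_xyl)
  for (i in 1:1000) lat <- mech_step(lat, 0.01)
  expect_equal(sum(lat$h_apo + lat$h_xyl), total0, tolerance = 1e-12)
})

test_that("violated stability bounds raise named errors instead of diverging", {
  lat <- stem_lattice(length_cm = 5, u = 3)
  expect_error(mech_step(lat, 0.05), "advective")
  lat2 <- stem_lattice(length_cm = 5, u = 0)
  expect_error(mech_step(lat2, 0.02), "diffusive|rate")
})

test_that("single-cell transient matches an independent stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  p <- mechanism_params(d_pd = 0)     # isolate one cell
  lat <- stem_lattice(length_cm = 0.3, dx = 0.1, u = 0, params = p)
  lat$h_apo[2] <- 20
  nstep <- 1500; dt <- 0.002
  h_traj <- ca_traj <- vm_traj <- numeric(nstep)
  for (i in seq_len(nstep)) {
    lat <- mech_step(lat, dt)
    h_traj[i] <- lat$h_apo[2]; ca_traj[i] <- lat$ca_cyt[2]; vm_traj[i] <- lat$vm[2]
  }
  rhs <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      ca_act <- max(ca - ca_rest, 0)
      prod <- k_rboh * ca_act / (ca_act + K_ca)
      excess <- max(h - theta_h, 0)
      influx <- g_h * excess / (K_gh + excess)
      tpc <- if (ca > theta_ca) k_tpc * vac / ca_store else 0
      vm_t <- vm_max * tanh(k_dep * ca_act / vm_max)
      list(c(h = prod - k_ao * h + k_xfer * (hx - h),
             hx = k_xfer * (h - hx) - k_ao_xyl * hx,
             ca = influx + tpc - k_ca_rec * ca_act,
             vac = -tpc,
             vm = (vm_t - vm) / tau_vm))
    })
  }
  parms <- unclass(p)
  out <- deSolve::lsoda(c(h = 20, hx = 0, ca = p$ca_rest,
                          vac = p$ca_store, vm = 0),
                        times = seq(0, nstep * dt, by = dt), rhs, parms,
                        rtol = 1e-8, atol = 1e-10)
  idx <- seq(2, nrow(out))
  expect_lt(max(abs(out[idx, "h"] - h_traj)) / max(h_traj), 0.02)
  expect_lt(max(abs(out[idx, "ca"] - ca_traj)) / max(ca_traj), 0.02)
  expect_lt(max(abs(out[idx, "vm"] - vm_traj)) / max(vm_traj), 0.02)
  # causal ordering within the transient: Ca rises, then vm depolarizes,
  # both after the H2O2 bolus is present
  expect_gt(which(ca_traj > 0.2)[1], 0)
  expect_gt(which(vm_traj > 1)[1], which(ca_traj > 0.2)[1])
})

test_that("a calcium-channel blockade keeps the membrane at rest", {
  p <- mechanism_params(d_pd = 0)
  lat <- stem_lattice(length_cm = 0.3, dx = 0.1, u = 0, params = p,
                      ca_channel_blocked = rep(TRUE, 3))
  lat$h_apo[2] <- 20
  for (i in 1:1000) lat <- mech_step(lat, 0.01)
  expect_equal(max(abs(lat$vm)), 0)
})

test_that("with no flow the wound response is mirror-symmetric; flow breaks it", {
  s0 <- sim_symmetric_u0()
  h_to <- vapply(s0$h2o2, function(tr) mech_feat(tr, SIG_H)$takeoff_time, numeric(1))
  v_to <- vapply(s0$vm, function(tr) mech_feat(tr, SIG_V)$takeoff_time, numeric(1))
  # sensors: 2 cm counter, 1 cm counter, 1 cm down, 2 cm down
  expect_equal(unname(h_to[1]), unname(h_to[4]), tolerance = 0.2)
  expect_equal(unname(h_to[2]), unname(h_to[3]), tolerance = 0.2)
  expect_equal(unname(v_to[1]), unname(v_to[4]), tolerance = 0.2)

  sU <- sim_flow()
  fh <- lapply(sU$h2o2, mech_feat, floor = SIG_H)
  fv <- lapply(sU$vm, mech_feat, floor = SIG_V)
  v_down_h <- pair_velocity(fh[[3]], fh[[4]])
  v_down_v <- pair_velocity(fv[[3]], fv[[4]])
  v_ctr_v <- pair_velocity(fv[[2]], fv[[1]])
  expect_gt(v_down_v, v_ctr_v)
  # counterstream H2O2 velocity measured closer in, where it stays detectable
  sC <- wound_sim(0.35, c(7.55, 6.55))
  fc <- lapply(sC$h2o2, mech_feat, floor = SIG_H)
  v_ctr_h <- pair_velocity(fc[[1]], fc[[2]])
  expect_gt(v_down_h, v_ctr_h)
  # emergent speeds lie in the observed range for stem-propagating waves
  for (v in c(v_down_h, v_down_v, v_ctr_h, v_ctr_v)) {
    expect_gt(v, 0.05); expect_lt(v, 0.8)
  }
})

test_that("VP takes off before H2O2 at the dual-recording distances", {
  sU <- sim_flow()
  for (i in c(2, 3, 4)) {  # 1 cm counter, 1 cm down, 2 cm down
    t_h <- mech_feat(sU$h2o2[[i]], SIG_H)$takeoff_time
    t_v <- mech_feat(sU$vm[[i]], SIG_V)$takeoff_time
    expect_lt(t_v, t_h)
  }
})

test_that("amplitude and velocity decay with distance and fit an exponential", {
  sim <- sim_downstream_far()   # 1..4 cm downstream
  fh <- lapply(sim$h2o2, mech_feat, floor = SIG_H)
  fv <- lapply(sim$vm, mech_feat, floor = SIG_V)
  h_amp <- vapply(fh, function(f) f$amplitude, numeric(1))
  v_amp <- vapply(fv, function(f) f$amplitude, numeric(1))
  expect_true(all(diff(h_amp) <= 0))
  expect_true(all(diff(v_amp) <= 0))
  for (amp in list(h_amp, v_amp)) {
    fit <- fit_exponential_decay(1:4, amp)
    expect_lt(fit$rms, 0.1 * diff(range(amp)))
  }
  h_to <- vapply(fh, function(f) f$takeoff_time, numeric(1))
  v_to <- vapply(fv, function(f) f$takeoff_time, numeric(1))
  vel_h <- diff(1:4) / diff(h_to)
  vel_v <- diff(1:4) / diff(v_to)
  expect_true(all(diff(vel_h) <= 1e-9))
  expect_true(all(diff(vel_v) <= 1e-9))
})

test_that("stronger stimuli give larger, faster waves", {
  amps_h <- amps_v <- vels_h <- vels_v <- numeric(0)
  for (intensity in c(0.5, 1, 2)) {
    sim <- wound_sim(0.35, c(9.05, 10.05), intensity = intensity, t_end = 80)
    fh <- lapply(sim$h2o2, mech_feat, floor = SIG_H)
    fv <- lapply(sim$vm, mech_feat, floor = SIG_V)
    amps_h <- c(amps_h, fh[[1]]$amplitude)
    amps_v <- c(amps_v, fv[[1]]$amplitude)
    vels_h <- c(vels_h, pair_velocity(fh[[1]], fh[[2]]))
    vels_v <- c(vels_v, pair_velocity(fv[[1]], fv[[2]]))
  }
  expect_true(all(diff(amps_h) > 0))
  expect_true(all(diff(amps_v) > 0))
  expect_true(all(diff(vels_h) >= 0))
  expect_true(all(diff(vels_v) >= 0))
})

test_that("DPI or Gd3+ zones abolish both waves beyond the zone only", {
  # wound at 8.05 cm, zone 5.85-7.35 between the wound and the far sensor
  # at 5.55 cm; still water (u = 0) so both sides would otherwise match
  run <- function(...) {
    lat <- stem_lattice(length_cm = 16, u = 0, ...)
    simulate_mechanism(lat, stress_event(position = 8.05, time = 1),
                       t_end = 250, sensors = c(5.55, 10.55))
  }
  control <- run()
  for (ch in c("h2o2", "vm")) {
    fl <- mech_feat(control[[ch]][[1]], if (ch == "h2o2") SIG_H else SIG_V)
    expect_true(fl$detected)
  }
  for (blocked in list(run(rbohd_blocked = c(5.85, 7.35)),
                       run(ca_channel_blocked = c(5.85, 7.35)))) {
    f_far_h <- mech_feat(blocked$h2o2[[1]], SIG_H)
    f_far_v <- mech_feat(blocked$vm[[1]], SIG_V)
    f_near_h <- mech_feat(blocked$h2o2[[2]], SIG_H)
    f_near_v <- mech_feat(blocked$vm[[2]], SIG_V)
    expect_false(f_far_h$detected)
    expect_false(f_far_v$detected)
    expect_lt(f_far_h$amplitude, 5 * SIG_H)
    expect_lt(f_far_v$amplitude, 5 * SIG_V)
    expect_true(f_near_h$detected)
    expect_true(f_near_v$detected)
  }
})

test_that("exogenous H2O2 elicits dose-ordered VP and nothing at zero dose", {
  lat <- stem_lattice(length_cm = 14, u = 0.35)
  f0 <- exogenous_h2o2_response(lat, 0, distance = 1, t_end = 60,
                                noise_floor = SIG_V)
  expect_false(f0$detected)
  amps <- sapply(c(20, 50, 100), function(dose) {
    exogenous_h2o2_response(lat, dose, distance = 1, t_end = 60,
                            noise_floor = SIG_V)$amplitude
  })
  expect_true(all(diff(amps) > 0))
  # a dose that decays below the channel-gating threshold en route
  f_small <- exogenous_h2o2_response(lat, 0.05, distance = 2, t_end = 60,
                                     noise_floor = SIG_V)
  expect_false(f_small$detected)
})

test_that("the virtual sensor applies the device lag and is seed-reproducible", {
  tt <- seq(0, 3, by = 0.001)
  conc <- trace(tt, ifelse(tt >= 1, 10, 1e-3), kind = "h2o2")
  cv <- calibration_curve(0.109, 0, 1e-3, "mA", valid_range = c(1e-3, 100))
  out <- virtual_sensor(conc, cv, device_tau = 0.11)
  asym <- predict(cv, 10)
  t63 <- out$times[which(out$values >= 0.632 * asym)[1]]
  expect_equal(t63 - 1, 0.11, tolerance = 0.03)

  out0 <- virtual_sensor(conc, cv, device_tau = 0)
  expect_equal(out0$values, predict(cv, pmax(conc$values, 1e-3)),
               tolerance = 1e-12)

  n1 <- virtual_sensor(conc, cv, device_tau = 0, noise_sd = 0.02, seed = 5)
  n2 <- virtual_sensor(conc, cv, device_tau = 0, noise_sd = 0.02, seed = 5)
  n3 <- virtual_sensor(conc, cv, device_tau = 0, noise_sd = 0.02, seed = 6)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_equal(sd((n3$values - out0$values)), 0.02, tolerance = 0.3)
})
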