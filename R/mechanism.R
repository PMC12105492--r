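#' Parameters of the H2O2 / variation-potential reinforcing loop
#'
#' The simulator embodies a mutual-reinforcement loop in a chain of stem
#' cells: RBOHD produces apoplastic H2O2 when cytosolic Ca2+ is elevated
#' (Hill activation above resting Ca2+); apoplastic H2O2 above a threshold
#' gates plasma-membrane Ca2+ influx (with saturating gain); cytosolic Ca2+
#' above a second threshold opens vacuolar TPC1 channels, draining the
#' finite store; depolarization follows cytosolic Ca2+ through a saturating
#' (tanh) relation, lumping H+-ATPase inhibition and anion efflux. H2O2 also
#' enters the xylem compartment, where it is advected downstream with the
#' transpiration stream, and Ca2+ passes to neighbouring cells through
#' plasmodesmata (diffusive, bidirectional). All species relax first-order
#' towards rest, and an apoplastic antioxidant degrades H2O2.
#'
#' The default rates are calibrated so that emergent wave velocities fall in
#' the 0.1-0.7 cm/s range of stem-propagating waves and so that the loop
#' gain is slightly below self-sustaining: waves are decremental, their
#' amplitude and velocity decaying roughly exponentially with distance.
#'
#' @param k_rboh maximal RBOHD H2O2 production rate (uM/s).
#' @param K_ca Ca2+ half-activation of RBOHD (uM above rest).
#' @param theta_h apoplastic H2O2 threshold gating Ca2+ influx (uM).
#' @param g_h maximal H2O2-gated Ca2+ influx (uM/s).
#' @param K_gh half-saturation of the gated influx (uM H2O2 above threshold).
#' @param theta_ca cytosolic Ca2+ threshold for TPC1 release (uM).
#' @param k_tpc maximal vacuolar release rate (uM/s, scaled by store fill).
#' @param k_dep depolarization gain (mV per uM Ca2+ above rest).
#' @param vm_max saturation of the depolarization (mV).
#' @param tau_vm membrane-potential relaxation time (s).
#' @param k_ao apoplastic antioxidant H2O2 degradation rate (1/s).
#' @param k_ao_xyl xylem H2O2 degradation rate (1/s).
#' @param k_xfer apoplast/xylem H2O2 exchange rate (1/s, symmetric).
#' @param d_pd plasmodesmal Ca2+ exchange coefficient (cm^2/s).
#' @param k_ca_rec cytosolic Ca2+ recovery rate (1/s).
#' @param ca_rest resting cytosolic Ca2+ (uM).
#' @param ca_store initial vacuolar store (uM).
#' @param tau_drive decay time of the transient wound RBOHD drive (s).
#' @return An object of class `"mechanism_params"`.
#' @export
mechanism_params <- function(k_rboh = 10, K_ca = 10, theta_h = 0.02, g_h = 8.8,
                             K_gh = 20, theta_ca = 1.5, k_tpc = 0.3,
                             k_dep = 10, vm_max = 200, tau_vm = 0.3,
                             k_ao = 0.4, k_ao_xyl = 0.05, k_xfer = 0.3,
                             d_pd = 0.45, k_ca_rec = 1.2, ca_rest = 0.1,
                             ca_store = 40, tau_drive = 30) {
  p <- list(k_rboh = k_rboh, K_ca = K_ca, theta_h = theta_h, g_h = g_h,
            K_gh = K_gh, theta_ca = theta_ca, k_tpc = k_tpc, k_dep = k_dep,
            vm_max = vm_max, tau_vm = tau_vm, k_ao = k_ao,
            k_ao_xyl = k_ao_xyl, k_xfer = k_xfer, d_pd = d_pd,
            k_ca_rec = k_ca_rec, ca_rest = ca_rest, ca_store = ca_store,
            tau_drive = tau_drive)
  for (nm in names(p)) check_nonnegative(p[[nm]], nm)
  check_positive(theta_h, "theta_h")
  check_positive(theta_ca, "theta_ca")
  structure(p, class = "mechanism_params")
}

#' Construct a 1D stem cell lattice
#'
#' Cells are spaced `dx` cm apart along the stem, sharing a xylem
#' compartment that advects H2O2 at the flow rate `u`. Inhibitor zones mark
#' cells where RBOHD is blocked (DPI) or the H2O2-gated Ca2+ channels are
#' blocked (Gd3+).
#'
#' @param length_cm lattice extent (cm).
#' @param dx spacing of the lattice slabs (cm, default 0.1). Each lattice
#'   "cell" is a thin slab of stem tissue, not a single biological cell;
#'   `d_pd` is the effective symplastic dispersion between slabs.
#' @param u xylem flow rate (cm/s, signed; positive advects towards larger x).
#' @param r xylem area fraction (kept for bookkeeping; the lattice xylem
#'   compartment advects at the xylem-internal speed `u`).
#' @param params a `"mechanism_params"` (defaults used when omitted).
#' @param rbohd_blocked,ca_channel_blocked optional length-2 `c(from, to)`
#'   cm intervals (or logical per-cell vectors) marking DPI / Gd3+ zones.
#' @return An object of class `"stem_lattice"` holding per-cell state at
#'   rest: apoplastic and xylem H2O2 (uM), cytosolic and vacuolar Ca2+ (uM),
#'   membrane-potential deviation from rest (mV, depolarization positive).
#' @export
stem_lattice <- function(length_cm = 10, dx = 0.1, u = 0.35, r = 0.012,
                         params = mechanism_params(),
                         rbohd_blocked = NULL, ca_channel_blocked = NULL) {
  check_positive(length_cm, "length_cm")
  check_positive(dx, "dx")
  stopifnot(inherits(params, "mechanism_params"))
  n <- max(3L, as.integer(round(length_cm / dx)))
  x <- (seq_len(n) - 0.5) * dx
  zone_flags <- function(zone) {
    if (is.null(zone)) return(rep(FALSE, n))
    if (is.logical(zone)) {
      stopifnot(length(zone) == n)
      return(zone)
    }
    stopifnot(length(zone) == 2L)
    x >= zone[1] - 1e-9 & x <= zone[2] + 1e-9
  }
  structure(
    list(n = n, dx = dx, x = x, u = u, r = r, params = params,
         h_apo = rep(0, n), h_xyl = rep(0, n),
         ca_cyt = rep(params$ca_rest, n), ca_vac = rep(params$ca_store, n),
         vm = rep(0, n), drive = rep(0, n),
         rbohd_blocked = zone_flags(rbohd_blocked),
         ca_channel_blocked = zone_flags(ca_channel_blocked)),
    class = "stem_lattice"
  )
}

#' @export
print.stem_lattice <- function(x, ...) {
  cat(sprintf("<stem_lattice> %d cells, dx = %g cm (%.2g cm), u = %g cm/s\n",
              x$n, x$dx, x$n * x$dx, x$u))
  if (any(x$rbohd_blocked)) {
    cat(sprintf("  RBOHD blocked (DPI): %d cells\n", sum(x$rbohd_blocked)))
  }
  if (any(x$ca_channel_blocked)) {
    cat(sprintf("  Ca channels blocked (Gd3+): %d cells\n", sum(x$ca_channel_blocked)))
  }
  invisible(x)
}

#' Advance the lattice by one explicit Euler step
#'
#' One update of the coupled cell states: RBOHD production (zero in DPI
#' cells), H2O2-gated Ca2+ influx (zero in Gd3+ cells), TPC1 vacuolar
#' release, saturating depolarization, antioxidant degradation, symmetric
#' apoplast/xylem exchange, upwind advection of xylem H2O2, plasmodesmal
#' Ca2+ exchange, and first-order recovery of every species towards rest.
#' The step errors out (rather than silently diverging) when the CFL bound
#' `|u| * dt <= dx`, the diffusive bound `d_pd * dt <= dx^2 / 2`, or a
#' rate-stiffness bound is violated, or when the state leaves the physical
#' domain.
#'
#' @param lattice a `"stem_lattice"`.
#' @param dt time step (s).
#' @return The advanced `"stem_lattice"`.
#' @export
mech_step <- function(lattice, dt) {
  p <- lattice$params
  dx <- lattice$dx
  u <- lattice$u
  if (abs(u) * dt > dx) {
    stop(sprintf("advective stability violated: |u|*dt = %.3g > dx = %.3g",
                 abs(u) * dt, dx), call. = FALSE)
  }
  if (p$d_pd * dt > dx^2 / 2) {
    stop(sprintf("diffusive stability violated: d_pd*dt = %.3g > dx^2/2 = %.3g",
                 p$d_pd * dt, dx^2 / 2), call. = FALSE)
  }
  max_rate <- max(p$k_ao, p$k_ao_xyl, p$k_xfer, p$k_ca_rec, 1 / max(p$tau_vm, 1e-9))
  if (max_rate * dt >= 1) {
    stop(sprintf("rate stiffness violated: max rate * dt = %.3g >= 1",
                 max_rate * dt), call. = FALSE)
  }
  n <- lattice$n
  h_apo <- lattice$h_apo; h_xyl <- lattice$h_xyl
  ca <- lattice$ca_cyt; vac <- lattice$ca_vac; vm <- lattice$vm
  ca_act <- pmax(ca - p$ca_rest, 0)

  prod <- p$k_rboh * ca_act / (ca_act + p$K_ca) * (1 + lattice$drive)
  prod[lattice$rbohd_blocked] <- 0

  excess <- pmax(h_apo - p$theta_h, 0)
  influx <- p$g_h * excess / (p$K_gh + excess)
  influx[lattice$ca_channel_blocked] <- 0

  tpc <- ifelse(ca > p$theta_ca, p$k_tpc * vac / p$ca_store, 0)

  # no-flux plasmodesmal Laplacian (conservative: boundary fluxes vanish)
  lap <- c(ca[1], ca[-n]) + c(ca[-1], ca[n]) - 2 * ca

  # first-order upwind advection of xylem H2O2, zero inflow at the boundary
  adv <- if (u > 0) {
    -(u / dx) * (h_xyl - c(0, h_xyl[-n]))
  } else if (u < 0) {
    (u / dx) * (h_xyl - c(h_xyl[-1], 0))
  } else rep(0, n)

  d_h_apo <- prod - p$k_ao * h_apo + p$k_xfer * (h_xyl - h_apo)
  d_h_xyl <- adv + p$k_xfer * (h_apo - h_xyl) - p$k_ao_xyl * h_xyl
  d_ca <- influx + tpc - p$k_ca_rec * ca_act + (p$d_pd / dx^2) * lap
  d_vac <- -tpc
  vm_target <- p$vm_max * tanh(p$k_dep * ca_act / p$vm_max)
  d_vm <- (vm_target - vm) / p$tau_vm

  lattice$h_apo <- h_apo + dt * d_h_apo
  lattice$h_xyl <- h_xyl + dt * d_h_xyl
  lattice$ca_cyt <- ca + dt * d_ca
  lattice$ca_vac <- pmax(vac + dt * d_vac, 0)
  lattice$vm <- vm + dt * d_vm
  lattice$drive <- lattice$drive * exp(-dt / p$tau_drive)

  bad <- function(v) any(!is.finite(v)) || any(v < -1e-6)
  if (bad(lattice$h_apo) || bad(lattice$h_xyl) ||
      bad(lattice$ca_cyt) || bad(lattice$vm + p$vm_max)) {
    stop("integration left the physical domain: reduce dt", call. = FALSE)
  }
  lattice$h_apo <- pmax(lattice$h_apo, 0)
  lattice$h_xyl <- pmax(lattice$h_xyl, 0)
  lattice$ca_cyt <- pmax(lattice$ca_cyt, 0)
  lattice
}

#' Define a stress event
#'
#' Wound intensity maps linearly onto an initial H2O2 bolus split between
#' the apoplast and the xylem at the wound cell, plus a transient RBOHD
#' stress drive decaying with `tau_drive`.
#'
#' @param position position along the lattice (cm).
#' @param time event time (s).
#' @param intensity dimensionless stress intensity (>= 0); 1 is a standard
#'   wound.
#' @param bolus_apo,bolus_xyl H2O2 bolus per unit intensity (uM) delivered
#'   to the apoplast and xylem compartments of each cell in the wound zone.
#' @param drive transient RBOHD drive per unit intensity (dimensionless).
#' @param width extent of the damaged zone (cm); a needle wound crushes a
#'   finite region of tissue, not a single lattice slab.
#' @return An object of class `"stress_event"`.
#' @export
stress_event <- function(position, time = 0, intensity = 1,
                         bolus_apo = 40, bolus_xyl = 3, drive = 6,
                         width = 0.6) {
  check_nonnegative(intensity, "intensity")
  check_positive(width, "width")
  structure(list(position = position, time = time, intensity = intensity,
                 bolus_apo = bolus_apo, bolus_xyl = bolus_xyl, drive = drive,
                 width = width),
            class = "stress_event")
}

#' Run the mechanistic lattice simulation
#'
#' Integrates the lattice with explicit Euler steps, applying stress events
#' at their times, and records H2O2 (apoplast plus xylem, what an implanted
#' H2O2 sensor sees) and membrane-potential traces at the sensor positions.
#'
#' @param lattice a `"stem_lattice"`.
#' @param events list of `"stress_event"`s (a single event may be passed
#'   directly).
#' @param t_end simulation end time (s).
#' @param sensors sensor positions (cm), inside the lattice extent.
#' @param dt integration step (s, default 0.01).
#' @param record_dt recording interval (s, default 0.1).
#' @return An object of class `"mech_sim"`: `h2o2` and `vm` are lists of
#'   `"trace"` objects (uM and mV) keyed by sensor, plus the final lattice.
#' @examples
#' lat <- stem_lattice(length_cm = 6, u = 0.35)
#' sim <- simulate_mechanism(lat, stress_event(position = 3, time = 1),
#'                           t_end = 12, sensors = c(2, 4))
#' @export
simulate_mechanism <- function(lattice, events, t_end, sensors,
                               dt = 0.01, record_dt = 0.1) {
  stopifnot(inherits(lattice, "stem_lattice"))
  if (inherits(events, "stress_event")) events <- list(events)
  check_positive(t_end, "t_end")
  extent <- lattice$n * lattice$dx
  for (ev in events) {
    if (ev$position < 0 || ev$position > extent) {
      stop("event position outside the lattice", call. = FALSE)
    }
  }
  if (any(sensors < 0 | sensors > extent)) {
    stop("sensor position outside the lattice", call. = FALSE)
  }
  sensor_cells <- vapply(sensors, function(s) which.min(abs(lattice$x - s)),
                         integer(1))
  n_steps <- ceiling(t_end / dt)
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  n_rec <- floor(n_steps / rec_every) + 1L
  times <- numeric(n_rec)
  h_rec <- matrix(0, n_rec, length(sensors))
  vm_rec <- matrix(0, n_rec, length(sensors))
  pending <- events
  record <- function(k, t) {
    times[k] <<- t
    h_rec[k, ] <<- lattice$h_apo[sensor_cells] + lattice$h_xyl[sensor_cells]
    vm_rec[k, ] <<- lattice$vm[sensor_cells]
  }
  record(1L, 0)
  k <- 1L
  for (i in seq_len(n_steps)) {
    t_now <- (i - 1L) * dt
    if (length(pending)) {
      due <- vapply(pending, function(ev) ev$time <= t_now + dt / 2, logical(1))
      for (ev in pending[due]) {
        cells <- which(abs(lattice$x - ev$position) <= ev$width / 2 + 1e-9)
        if (!length(cells)) cells <- which.min(abs(lattice$x - ev$position))
        lattice$h_apo[cells] <- lattice$h_apo[cells] + ev$intensity * ev$bolus_apo
        lattice$h_xyl[cells] <- lattice$h_xyl[cells] + ev$intensity * ev$bolus_xyl
        lattice$drive[cells] <- lattice$drive[cells] + ev$intensity * ev$drive
      }
      pending <- pending[!due]
    }
    lattice <- mech_step(lattice, dt)
    if (i %% rec_every == 0L) {
      k <- k + 1L
      record(k, i * dt)
    }
  }
  h2o2 <- lapply(seq_along(sensors), function(j) {
    trace(times[1:k], h_rec[1:k, j], position = sensors[j],
          kind = "h2o2", units = "uM")
  })
  vm <- lapply(seq_along(sensors), function(j) {
    trace(times[1:k], vm_rec[1:k, j], position = sensors[j],
          kind = "vp", units = "mV")
  })
  names(h2o2) <- names(vm) <- sprintf("%g cm", sensors)
  structure(list(h2o2 = h2o2, vm = vm, lattice = lattice,
                 sensors = sensors, dt = dt),
            class = "mech_sim")
}

#' @export
print.mech_sim <- function(x, ...) {
  cat(sprintf("<mech_sim> %d sensors at %s cm, %d samples each\n",
              length(x$sensors), paste(x$sensors, collapse = ", "),
              length(x$h2o2[[1]]$times)))
  invisible(x)
}

#' Variation-potential response to exogenous H2O2
#'
#' Injects an H2O2 bolus into the xylem compartment (mimicking infusion
#' through a stem hole) without any mechanical stress drive, and returns the
#' membrane-potential wave features at a sensor `distance` cm downstream of
#' the injection site. Amplitude is non-decreasing in dose; zero dose gives
#' no wave.
#'
#' @param lattice a `"stem_lattice"`.
#' @param dose H2O2 bolus (uM, >= 0).
#' @param distance sensor distance from the injection site (cm).
#' @param entry `"xylem"` (default) or `"apoplast"`.
#' @param t_end simulation time (s).
#' @param noise_floor assumed instrument fluctuation of the VP channel (mV),
#'   defining the 5x take-off threshold.
#' @param ... passed to [simulate_mechanism()].
#' @return A `"wave_features"` object for the VP channel.
#' @export
exogenous_h2o2_response <- function(lattice, dose, distance = 1,
                                    entry = c("xylem", "apoplast"),
                                    t_end = 60, noise_floor = 0.2, ...) {
  stopifnot(inherits(lattice, "stem_lattice"))
  check_nonnegative(dose, "dose")
  entry <- match.arg(entry)
  extent <- lattice$n * lattice$dx
  src <- extent / 3
  ev <- stress_event(position = src, time = 1, intensity = 1,
                     bolus_apo = if (entry == "apoplast") dose else 0,
                     bolus_xyl = if (entry == "xylem") dose else 0,
                     drive = 0)
  sim <- simulate_mechanism(lattice, ev, t_end = t_end,
                            sensors = src + distance, ...)
  wave_features(sim$vm[[1]], stimulus_time = 1,
                baseline = baseline_stats(mean = 0, fluctuation = noise_floor),
                window = t_end)
}

#' Pass a concentration trace through a virtual fOECT sensor
#'
#' Maps concentration through a calibration curve, applies the first-order
#' device lag (time constant `device_tau`, 0.11 s for the fibre devices),
#' and adds Gaussian instrument noise. Deterministic given the seed.
#' Concentrations are floored at `conc_floor` before the log-linear mapping
#' (the curve is undefined at zero concentration); the floor defaults to the
#' bottom of the curve's calibrated range.
#'
#' @param conc_trace a concentration `"trace"`.
#' @param curve a `"calibration_curve"`.
#' @param device_tau first-order response time constant (s, >= 0).
#' @param noise_sd Gaussian noise standard deviation (response units, >= 0).
#' @param seed integer seed or `NULL`.
#' @param conc_floor concentration floor (> 0).
#' @return A `"trace"` of sensor response at the same sample times.
#' @export
virtual_sensor <- function(conc_trace, curve, device_tau = 0.11,
                           noise_sd = 0, seed = NULL, conc_floor = NULL) {
  stopifnot(inherits(conc_trace, "trace"), inherits(curve, "calibration_curve"))
  check_nonnegative(device_tau, "device_tau")
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  if (is.null(conc_floor)) {
    conc_floor <- if (!is.null(curve$valid_range)) curve$valid_range[1] else
      curve$reference_concentration * 1e-3
  }
  conc <- pmax(conc_trace$values, conc_floor)
  resp <- suppressWarnings(predict(curve, conc))
  if (device_tau > 0) {
    tt <- conc_trace$times
    y <- numeric(length(resp))
    y[1] <- resp[1]
    for (i in 2:length(resp)) {
      a <- 1 - exp(-(tt[i] - tt[i - 1]) / device_tau)
      y[i] <- y[i - 1] + a * (resp[i] - y[i - 1])
    }
    resp <- y
  }
  resp <- with_seed(seed, resp + if (noise_sd > 0)
    stats::rnorm(length(resp), 0, noise_sd) else 0)
  trace(conc_trace$times, resp, position = conc_trace$position,
        kind = conc_trace$kind, units = curve$response_units)
}
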