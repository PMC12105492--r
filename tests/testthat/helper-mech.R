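# shared mechanistic simulations, computed once per test run; the lattice
# dynamics are deterministic, so these are fixtures built in code
.mech_cache <- new.env(parent = emptyenv())

mech_sim_cached <- function(key, builder) {
  if (is.null(.mech_cache[[key]])) .mech_cache[[key]] <- builder()
  .mech_cache[[key]]
}

# wound mid-lattice; sensor positions on cell centres so that the u = 0
# layout is exactly mirror-symmetric
wound_sim <- function(u, sensors, t_end = 200, intensity = 1, ...) {
  lat <- stem_lattice(length_cm = 16, u = u, ...)
  simulate_mechanism(lat,
                     stress_event(position = 8.05, time = 1,
                                  intensity = intensity),
                     t_end = t_end, sensors = sensors)
}

sim_symmetric_u0 <- function() {
  mech_sim_cached("u0", function() wound_sim(0, c(6.05, 7.05, 9.05, 10.05)))
}

sim_flow <- function() {
  mech_sim_cached("flow", function() wound_sim(0.35, c(6.05, 7.05, 9.05, 10.05)))
}

sim_downstream_far <- function() {
  mech_sim_cached("far", function() {
    wound_sim(0.35, c(9.05, 10.05, 11.05, 12.05))
  })
}
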