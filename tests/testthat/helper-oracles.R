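# independent oracles used across tests

# closed-form ordinary least squares of y on x (no lm)
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

# closed-form inverse of erfc(z) = f via the normal quantile
erfc_inv <- function(f) -qnorm(f / 2) / sqrt(2)

# explicit finite-difference solver for 1D semi-infinite diffusion with a
# constant-concentration boundary, used as an independent check of the
# closed-form solution
fd_diffusion <- function(D, source, L, nx, t_end, x_query) {
  dx <- L / nx
  dt <- 0.2 * dx^2 / D
  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  lam <- D * dt / dx^2
  c0 <- rep(0, nx + 1)
  c0[1] <- source
  for (i in seq_len(nt)) {
    interior <- 2:nx
    c0[interior] <- c0[interior] +
      lam * (c0[interior - 1] + c0[interior + 1] - 2 * c0[interior])
    c0[1] <- source
    c0[nx + 1] <- c0[nx]
  }
  stats::approx(seq(0, L, by = dx), c0, xout = x_query)$y
}

# sensor noise floors assumed for analysing the (noise-free) mechanistic
# simulator outputs: instrument fluctuation of the H2O2 channel (uM) and of
# the membrane-potential channel (mV); take-off = 5x these floors
SIG_H <- 0.15
SIG_V <- 0.3

mech_feat <- function(tr, floor, stimulus_time = 1) {
  wave_features(tr, stimulus_time,
                baseline = baseline_stats(mean = 0, fluctuation = floor),
                window = 1e5)
}
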