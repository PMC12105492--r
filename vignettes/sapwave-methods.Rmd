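---
title: "Models and methods behind sapwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sapwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapwave)
```

`sapwave` analyses stem-implanted biosensor recordings of plant systemic
signalling and simulates the propagation mechanism those recordings
suggest. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data tests
do and do not demonstrate about real recordings.

## Sensor calibration

Organic electrochemical transistors respond to analyte concentration
log-linearly over several decades, so the calibration model is

$$R(C) = R_0 + S \log_{10}(C / C_{\mathrm{ref}}),$$

with sensitivity $S$ in response units per decade. `fit_calibration()`
is ordinary least squares of response on $\log_{10} C$; the package fits
whatever response column it is given (absolute current change or
percentage change) and stores the units label on the curve, since both
conventions are common for these devices.

Two conventions required a decision:

* **Reference and blank.** The fitted curve is re-referenced to the
  lowest measured concentration, so its intercept is the fitted response
  at the bottom of the calibrated range. That intercept doubles as the
  blank level for the detection limit; with no separately measured blank
  this is the natural operational choice.
* **Detection limit.** `detection_limit()` returns the concentration at
  which the response exceeds the blank by `snr` (default 3) times the
  blank noise: $C_{\mathrm{ref}} \cdot 10^{\,snr\,\sigma/|S|}$. This is an
  extrapolation, deliberately: evaluation outside the calibrated range
  warns but does not fail, because extrapolated limits are exactly how
  such figures of merit are quoted. A zero noise level returns the blank
  reference itself, flagged as degenerate.

## Xylem transport

A cut stem standing in a solute bath takes up solution through the
transpiration stream. Sensors report the stem-average concentration
while transport happens inside xylem vessels occupying an area fraction
$r$ of the cross-section, and radial exchange is fast; the stem-average
concentration then obeys the hyperbolic equation

$$\frac{\partial C}{\partial t} = -(u\,r)\,\frac{\partial C}{\partial x},$$

whose front advances at the *reduced* speed $u r$ (for the defaults
$u = 0.35$ cm/s and $r = 0.012$, about 0.0042 cm/s, i.e. ~238 s to reach
a sensor 1 cm up). The alternative reading of the coefficient, $u/r$,
would predict front arrival in well under a second at 1 cm, inconsistent
with the minutes-scale equilibration such experiments show, so $u r$ is
the implemented form.

Numerics: the equation is solved by the method of characteristics, which
is exact for piecewise-constant $u(t)$ — the front arrival time at $x$
solves $\int_0^t u(\tau) r\,d\tau = x$. No gridded solver is used in the
implementation; an explicit finite-difference scheme exists only inside
the test suite, as an independent oracle for the diffusion model.

Pure plug flow produces a discontinuous front, but measured rises are
smooth. A single first-order relaxation constant `lateral_tau` (default
60 s) smooths the front: after arrival the concentration approaches the
source as $1 - e^{-(t - t_{\mathrm{arr}})/\tau}$. This is a
phenomenological stand-in for the radial equilibration the averaging
argument assumes; 60 s is of the order of radial diffusion across a
millimetre-scale stem and reproduces the smooth sigmoidal onsets seen in
such recordings.

The diffusion null model is semi-infinite 1D diffusion from a constant
boundary, $C/C_0 = \mathrm{erfc}(x/2\sqrt{Dt})$. Its default
$D = 1.96\times10^{-5}$ cm²/s is the aqueous K⁺ diffusivity at 25 °C.
`diffusion_timescale()` root-finds the time to reach a fraction of the
source (default 0.632, the $1 - 1/e$ criterion); at $x = 1$ cm this gives
≈1.3 days, the benchmark that rules diffusion out as the transport
mechanism. The choice of 1 cm and the 63.2% criterion reproduces that
benchmark; neither is uniquely dictated, so both are explicit arguments.

`fit_flow_rate()` estimates a single constant $u$ by bounded scalar
least squares over all sensors jointly (`stats::optimize` on
$[0, u_{\max}]$). Flat traces raise a non-identifiability error; a
solution at the bound warns. The fit reports per-sensor front arrivals
and the time for the modelled concentration to reach 63.2% of the
source; how the equilibration constant of such experiments was defined
is not standardised, so the package reports both per-sensor values and
their mean.

`detect_flow_events()` classifies stomatal events in an inferred flow
trace: a departure of more than `k` (default 5) times the pre-stimulus
fluctuation, sustained for `persistence` (default 10 s), is an
acceleration (opening) or suppression (closure); a sustained return into
the band is a recovery. The 5× threshold mirrors the wave take-off
convention; no separate criterion for stomatal events is established in
the field.

## Wave kinetics

The kinetic vocabulary for H₂O₂ and variation-potential (VP) waves:

* **Baseline fluctuation** — standard deviation of the *linearly
  detrended* pre-stimulus window (slow drift should not raise the
  detection threshold), floored at $10^{-12}$ trace units. A robust
  variant (scaled MAD) is available via `method = "mad"`.
* **Take-off** — first post-stimulus sample whose absolute departure
  from the baseline mean reaches 5× the fluctuation, sustained for
  `hold` seconds (default three consecutive samples). The sustained-hold
  requirement suppresses single-sample noise spikes; the reported time
  is the first qualifying sample, which keeps a step input's take-off
  exactly at the step.
* **Amplitude** — the largest absolute departure within a post-stimulus
  window (default 300 s, excluding late drift). VP depolarizations are
  recorded as negative deflections; using the absolute departure makes
  amplitude positive for both channels.
* **Rise time** — take-off to the first crossing of 63.2% of the peak
  departure, with the crossing linearly interpolated between samples
  (sampling rates differ across experiments; interpolation removes most
  of the grid quantisation).
* **Velocity** — sensor separation over take-off time difference.

`fit_exponential_decay()` fits $y = y_0 e^{-x/\lambda}$ by least squares
on $\log y$ with a nonlinear refinement pass (`minpack.lm::nlsLM`); on
noiseless exponential data the log-linear step is already exact. A
non-decaying series is returned flagged, with $\lambda \to \infty$ (or
negative for an increasing series) rather than an error, so that scans
over conditions can proceed.

`fit_risetime_floor()` fits
$\mathrm{rise} = \mathrm{floor} + a\,e^{-A/b}$ with the floor bounded at
zero, by `nlsLM` from a log-linearised start (several fallback starting
floors are tried). The functional form — exponential approach to a
positive kinetic floor — is an assumption: extrapolations of rise time
against amplitude are reported in this shape, but the generating law is
not established, which is why the fit object carries its residual RMS.

## The mechanistic simulator

The simulator embodies the proposed mutual-reinforcement loop between
H₂O₂ production and membrane depolarization as a 1D chain of tissue
slabs (default `dx` = 0.1 cm — a slab is a mesoscale patch of tissue,
not a single cell). Per-slab state: apoplastic and xylem H₂O₂,
cytosolic and vacuolar Ca²⁺, and membrane-potential deviation from rest.
The update terms, all package-defined since no rate equations accompany
the proposed mechanism:

1. RBOHD production of apoplastic H₂O₂, Hill-activated by cytosolic
   Ca²⁺ *above rest* and multiplied by a transient wound drive; zero in
   DPI-blocked slabs.
2. Ca²⁺ influx gated by apoplastic H₂O₂ above a threshold
   $\theta_h$, with saturating gain; zero in Gd³⁺-blocked slabs.
3. TPC1 vacuolar release above a cytosolic Ca²⁺ threshold, draining the
   finite store.
4. Depolarization follows Ca²⁺ through a saturating tanh relation
   (H⁺-ATPase inhibition and anion efflux lumped into one gain).
5. First-order antioxidant degradation of H₂O₂; symmetric
   apoplast–xylem exchange; upwind advection of xylem H₂O₂ at the flow
   rate $u$; conservative plasmodesmal (PD) diffusion of Ca²⁺ between
   neighbouring slabs; first-order recovery of every species.

Activating production and depolarization on Ca²⁺ *above rest* makes the
resting lattice an exact fixed point of the discrete update — a property
the test suite asserts directly.

**Why a sub-critical, quasi-linear regime.** With hard thresholds and
steep gains the chain behaves like a classical excitable medium: a wave
either settles to a fixed-amplitude travelling pulse or dies within a
slab or two. Recorded stem waves do neither — their amplitude and
velocity decay roughly exponentially over centimetres. The defaults
therefore put the loop in a quasi-linear regime (large Hill constants,
small gating thresholds) with amplification gain slightly *below*
self-sustaining. A wound then launches a decremental wave whose
amplitude profile decays with length scale
$\lambda \approx \sqrt{d_{pd}/(k_{rec} - \gamma p / k_{ao})}$ (~1.5–2 cm
for the defaults), amplitude scales linearly with stimulus intensity,
and velocity falls with distance as the decaying front crosses the fixed
detection threshold ever later. Downstream, the advected xylem H₂O₂
plume triggers the loop ahead of the PD relay, so downstream velocity
exceeds counterstream velocity, approaching the flow rate — with
`u = 0.35` cm/s the emergent take-off velocities span ≈0.15–0.45 cm/s,
inside the observed 0.1–0.7 cm/s range.

Consequences of this design, which the tests assert: wound responses in
still water (`u = 0`) are mirror-symmetric; flow breaks the symmetry in
the downstream direction for both variables; VP take-off precedes H₂O₂
take-off at the 1–2 cm sensors used in dual-recording layouts (the
membrane responds to Ca²⁺ within `tau_vm` = 0.3 s, while measurable
H₂O₂ accumulates over seconds — the same ordering that makes the VP
kinetic floor sub-second while the H₂O₂ floor is ~10 s); DPI or Gd³⁺
zones silence both waves beyond the zone while the unblocked side is
unaffected; exogenous xylem H₂O₂ elicits dose-ordered VP with no
response at zero dose.

**Parameters that matter most.** `d_pd` (default 0.45 cm²/s) is the
effective symplastic dispersion between slabs — much larger than a
molecular diffusivity because each hop already includes the sub-slab
relay; together with the recovery and gain rates it sets both the decay
length and the counterstream speed. `g_h`/`K_gh` and `k_rboh`/`K_ca` set
the loop gain (defaults put it at ~90% of critical). `theta_h` (0.02 µM)
and `theta_ca` (1.5 µM) keep rest stable without impeding the graded
response. The wound maps intensity linearly to an H₂O₂ bolus (40 µM
apoplast, 3 µM xylem per unit intensity) and a transient RBOHD drive
over a 0.6-cm damage zone: a needle crushes a finite region, and a
single-slab source would drain diffusively before establishing the
propagating profile.

**Numerics.** Explicit Euler with first-order upwind advection, `dt`
default 0.01 s. The step refuses to run outside its stability region
(advective CFL $|u| dt \le dx$, diffusive $d_{pd} dt \le dx^2/2$, and a
rate-stiffness bound), raising a named error instead of silently
diverging; negative or non-finite states abort likewise. The slab width
0.1 cm was chosen together with `d_pd` so the diffusive bound holds at
the default `dt`; halving `dx` requires quartering `dt` or `d_pd`.
The single-slab subsystem is verified against `deSolve::lsoda` in the
tests; the lattice dynamics are fully deterministic — the only
stochastic element anywhere in the package is sensor noise, always under
an explicit seed.

When analysing simulator output, take-off detection needs a fluctuation
scale; the tests use fixed instrument floors (0.15 µM for the H₂O₂
channel, 0.3 mV for VP) rather than estimating them from the noise-free
traces.

## Synthetic data

`gen_wave_traces()` builds each sensor's trace from a saturating
exponential rise capped at five rise constants, followed by a slow
exponential tail (default 100 s), echoing the long-lasting tails of
recorded waves; no waveform equation for the real traces is established,
so this template is a package choice. The generator programs the
*measurable* features directly: take-off at
$t_{\mathrm{stim}} + d/v(\mathrm{direction})$, amplitude
$A_0 e^{-d/\lambda_A}$, rise time $\mathrm{floor} + a e^{-A/b}$. Under
noise the onset is shifted so the mean signal crosses the 5σ threshold
exactly at the programmed take-off, removing a systematic bias from the
recovery loop. Defaults are the wound-response figures: 0.39/0.16 cm/s
down/counterstream, $\lambda_A$ = 1.53 cm, floor 9.9 s, 10 Hz sampling.
Noise is independent Gaussian per sample; no 1/f component is modelled
because none is characterised for these devices.

What recovery tests show — and what they do not: they demonstrate that
the analysis stages invert the generating models correctly at realistic
noise levels and sampling rates (closure), including the one-sample
quantisation of take-off times at 10 Hz. They cannot validate the
generating models against real tissue: multi-phase responses to heat or
peptide elicitors, baseline drift wander, device-to-device sensitivity
variation, and correlated noise are all outside the synthetic
structure.

## Problem sizes

The shipped tests and the acceptance script run on deliberately modest
problems: transport traces of ~300 samples per sensor, wave traces of a
few thousand samples, 50-seed Monte-Carlo loops for the noisy-recovery
medians, and mechanism lattices of 160 slabs integrated for 200–250 s of
model time. These sizes keep every recovery within its stated tolerance;
larger lattices or longer integrations change nothing structurally.

## Known limitations

* The transport model is 1D with a single constant `r` and no solute
  loss; the small equilibrium offset between bath and stem-average
  concentration seen in real immersions is not modelled.
* `fit_flow_rate()` assumes constant flow over the fitted window; for
  stomatal transients it should be applied piecewise between detected
  events.
* The rise-time-floor form is an assumed extrapolation law, as above.
* The simulator is phenomenological: it reproduces orderings and decay
  shapes, not absolute concentrations or potentials, and its acceptance
  surface is deliberately qualitative/ordinal.
* Whether counterstream regeneration runs through PD Ca²⁺ alone or also
  requires RBOHD relay is left open in the literature; the simulator
  exposes `d_pd` and the RBOHD coupling independently rather than
  asserting one route.
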