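---
title: "A reduced-order travelling-wave model of the katydid inner ear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order travelling-wave model of the katydid inner ear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katytw)
```

## The system and the model

The katydid inner ear (the auditory vesicle, AV) is a fluid-filled chamber
less than a millimetre long. Its hearing organ, the *crista acustica* (CA),
is a row of scolopidial sensory units sitting on the **dorsal wall** (DW), a
triangular cuticular plate that narrows and thickens toward its distal end.
Sound enters through the tympanal plates, becomes a pressure disturbance in
the AV fluid, and excites a travelling wave along the DW whose amplitude
peaks at a frequency-dependent place — high frequencies near the stiff
distal end, low frequencies near the compliant proximal end. This is the
same frequency-to-place (tonotopic) architecture as the mammalian basilar
membrane.

`katytw` reduces that three-dimensional fluid–structure problem to the
classical cochlear **transmission line**: a one-dimensional duct of height
$H(x)$ filled with water-like fluid, coupled at every position to a locally
reacting mechanical segment. Harmonic pressure $p(x)$ obeys

$$\frac{d}{dx}\!\left(\frac{H(x)}{\rho}\frac{dp}{dx}\right)
  = \frac{2\,i\omega}{Z(x,\omega)}\,p ,$$

with a prescribed-flux drive $dp/dx = -\rho\,a_0(\omega)$,
$a_0 = d_0\,\omega^2$ ($d_0 = 10\ \mu$m), at one end and a pressure release
($p = 0$) at the other. Each segment is the two-degree-of-freedom network
of the hearing organ: the DW (areal mass $m_{dw} = \rho_c t(x)$, bending
stiffness $k_{dw} \propto E\,t(x)^3/w(x)^4$) driven by the fluid pressure,
coupled through the scolopidial spring $k_{ca}$ to the tectorial membrane
(mass $m_{tm}$, grounded spring $k_{tm}$), with the fluid's Stokes
boundary-layer resistance $r_{visc} = 2\sqrt{\rho\mu\omega/2}$ as the only
loss channel (no material damping):

$$Z(\omega) = \frac{k_{dw} + k_{ca} - \omega^2 m_{dw}
  - k_{ca}^2/(k_{ca} + k_{tm} - \omega^2 m_{tm})}{i\omega} + r_{visc}.$$

The tapers produce a stiffness gradient of roughly two decades along the
600 µm transect, which is what maps each frequency to a place: the wave
propagates from the stiff end through the region where the partition is
stiffness-dominated, slows and peaks just before its local resonance place,
and is evanescent beyond it.

## Parameters

Material constants follow the published table: DW modulus 3 MPa (13 MPa
when the CA is removed), AV wall 15 GPa, cap cell 0.01 GPa, dendrite
0.02 GPa, tectorial membrane 0.05 GPa; DW thickness 4.84 → 4.10 µm and TM
thickness 3.47 → 3.08 µm (distal → proximal); water-like fluid (1000 kg/m³,
1.002 mPa·s). Quantities the source does not print, and our defaults:

* **Cuticle density** 1200 kg/m³ (typical insect cuticle) and **Poisson
  ratio** 0.3.
* **Width taper.** Only "triangular, increasing in width" is reported;
  default endpoints 40 → 120 µm, with the ratio a calibration parameter.
* **Duct height** $H$: default 100 µm; it scales the fluid coupling and is
  absorbed by calibration (see below).
* **Crista coupling** $k_{ca}$: dendrite and cap cell in series over a
  nominal 30 µm, derated by an effective area fraction (4 × 10⁻⁴) because
  the scolopidia are sparse, discrete structures. Neither the fill nor the
  spring geometry is printed. The level was set by a qualitative parametric
  sweep — the same procedure the original study used for its moduli —
  against the reported intact-organ behaviour: a monotone tonotopic map
  that flattens at high frequency, CA displacement no larger than DW
  displacement, and a crista stiffening contribution consistent with the
  13 MPa override needed after CA removal. It is exposed for calibration
  (`kca_scale`, `k_ca_profile`).
* **Tectorial-membrane stiffness** $k_{tm}$: plate formula with the TM
  thickness taper over **half** the DW width (`tm_width_fraction = 0.5`),
  because the TM is slung between its two support bands and spans only the
  crista band. This places the TM-branch resonance above the 10–80 kHz
  band; with it inside the band, the uniform-DW experiment would show a
  spurious mid-transect CA resonance instead of the reported
  proximally-pinned maximum.

### Why the drive sits at the distal end

The source model prescribes the drive amplitude but not where on the
transect it acts; the tympanal plates adjoin the vesicle near the proximal
region, and a first instinct is to drive there. In a one-dimensional
incompressible line, however, energy only propagates where the partition is
stiffness-dominated, i.e. distal of a frequency's resonance place. Driven
from the proximal (compliant) end, an 80 kHz wave would have to tunnel
~470 µm of evanescent cutoff (about 100 nepers) to form its distal peak —
the response would instead pin at the drive for every frequency. The
three-dimensional vesicle has no such constraint: its fluid delivers
pressure to the distal region through the bulk. The 1D reduction represents
that delivery path by the flux boundary at the distal (stiff) end — exactly
as the stapes drives the stiff base of the cochlear transmission line.
`drive_end = "proximal"` remains available, and a solver test documents the
pinning behaviour.

## Calibration and validation

Two printed peak positions anchor the model: 470 µm from the distal end at
20 kHz and 130 µm at 80 kHz (both from crista-removed runs, which is why
the anchor fit uses the `no_ca` variant). Three unprinted quantities are
fitted to them by deterministic bounded least squares (coarse log/linear
grid, then Nelder–Mead): the global stiffness scale, the width-taper ratio,
and the duct height. The printed 40 kHz position (336 µm) is deliberately
held out as a genuine prediction.

```{r calibrate}
res <- calibrate(calibration_problem())
res
predict_heldout(res, 40e3)   # printed: 336 um
```

The fit reaches machine-zero residuals; the held-out 40 kHz prediction
lands within ~16% of the printed value (within one sixth of the transect).
A recovery property (tested) regenerates anchors from known parameter
vectors and recovers them to better than 1%.

## Travelling-wave diagnostics

The time-domain solver (Crank–Nicolson on the method-of-lines system, 80
samples per period, drive ramped over 10 cycles, viscous resistance frozen
at the drive frequency since each run is monochromatic) feeds the
diagnostics used to characterize a travelling wave:

```{r travelling-wave}
m <- build_ear_model(stiffness_scale = res$parameters[["stiffness_scale"]],
                     width_ratio = res$parameters[["width_ratio"]],
                     duct_height = res$parameters[["duct_height_um"]],
                     ablation = "no_ca")
ts <- solve_time(m$profile, m$network, m$drive, 40e3)
env <- envelope(ts)
peak <- peak_distance_from_distal(env, ts$x)
asymmetry_ratio(env, ts$x, as.numeric(peak), drive_end = "distal")
```

* **Envelope asymmetry.** The ratio compares the average dB/µm slope on the
  side the wave arrives from (toward the drive) with the slope beyond the
  peak. A travelling wave builds up gradually and cuts off sharply past its
  best place, so the signature is a ratio **below 1** (the model gives
  0.3–0.5 at 20/40/80 kHz). Statements that the "leading slope is steeper"
  refer to the wavefront side — the side ahead of the travel direction —
  which is this same steep cutoff flank.
* **Phase accumulation.** The unwrapped phase of the DW displacement lags
  increasingly along the transect; at and above 30 kHz the lag accumulated
  at the peak exceeds 180°, more than any simple resonator.
* **Passive amplification.** The only energy source is the boundary drive;
  `dissipated_power()` integrates (over both fluid-loaded faces) to the
  boundary input power to better than 1%, and free-decay runs are strictly
  dissipative.

### Where the 1D reduction fails: the phase surface

The printed endpoint-to-endpoint phase lags are 52° at 10 kHz, 580° at
30 kHz, rising monotonically to ~1000° at 80 kHz. The calibrated line gives
203°, 967° and 934°: the right order of magnitude at the top of the band
(−7% at 80 kHz) but far too much lag at 10 kHz, and the sweep peaks near
40–50 kHz instead of rising monotonically. Both discrepancies are
structural, not numerical:

* At low frequency the locally reacting line still develops short
  wavelengths near the compliant proximal end (the 10 kHz resonance place
  sits just beyond the transect), whereas the 3D vesicle fluid responds
  nearly in phase there. A 52° total lag at 10 kHz is unattainable in any
  locally reacting line whose 20 kHz place is mid-transect.
* Above ~50 kHz the propagating path shortens with frequency faster than
  the wavenumber grows (for smooth maps the endpoint lag behaves like an
  arcsecant), while in 3D the fluid keeps accumulating phase beyond the
  best place.

The measurement points P1 and P2 default to the transect endpoints; the
source marks them on a figure without printing coordinates, and a P2 placed
mid-transect would restore monotonicity. We keep the endpoints and report
the disagreement rather than tune the measurement to the target.

## Ablation experiments

Two in-silico manipulations identify the DW as the driver of tonotopy, run
with the calibrated parameters:

* `no_ca` removes the crista (its stiffening is compensated by raising the
  DW modulus to 13 MPa). The tonotopic map survives and is close to linear
  in frequency.
* `uniform_dw` removes the thickness taper (uniform 15 µm, vesicle-wall
  modulus) while keeping the crista and the triangular planform — the
  planform is the physical footprint; only the thickness gradient was
  removed in the original experiment. The maximum, read off the crista
  surface as in the original, stays pinned in the proximal third at every
  frequency: tonotopy is gone.

The intact map is monotone but flattens at high frequency, so its linear
fit is worse than the crista-removed map's ($R^2$ 0.86 vs 0.96 at the
calibrated defaults) — the crista components tune the map's shape without
driving it.

## Microrheology of the vesicle fluid

The AV-fluid characterization is reimplemented end-to-end on synthetic
data: 1.02 µm beads observed at 50 Hz undergoing 2D Brownian motion
($\mathrm{msd} = 4D\tau$, $D = k_BT/6\pi\eta a$), rendered as Gaussian
spots, localized by thresholded intensity-weighted centroids, linked by
gated mutual-nearest-neighbour association (ambiguous links terminate
tracks rather than guess), and summarized by the time-and-ensemble MSD.
The viscosity fit is a weighted straight line over the lag window matching
the probed 10⁻²–25 Hz band, with an additive offset absorbing the static
localization error $4\sigma^2$; the power-law exponent $\alpha$ is the raw
log-log slope (subtracting the fitted offset would disguise genuine
anomalous curvature as noise, and with 20 nm localization noise the raw
slope is biased by under 2%).

```{r rheology}
bead <- bead_spec()
traj <- simulate_trajectories(100, 2000, bead, viscosity = 1.002e-3,
                              seed = 1)
fit_viscosity(msd(traj, 25), bead)
```

At the study's scale (100 particles × 2000 frames) the recovery bias is
~0.02% with ~0.5% RMSE over 20 seeds, and $\alpha = 1.00 \pm 0.01$; a
constructed fractional walk with $\alpha = 0.7$ is correctly flagged
non-Newtonian. The full image round trip (simulate → render → localize →
link → MSD → fit) recovers viscosity within 15%; its test fixture keeps
generous frame margins because particles that wander off-frame censor large
displacements and bias the MSD low — a caveat that applies equally to real
recordings.

What the synthetic data do *not* emulate: bead polydispersity,
heterogeneous or viscoelastic fluid, photobleaching and background
structure, motion blur within an exposure, and out-of-plane motion. Passing
these tests therefore validates the estimator chain, not the biology.

## Numerical choices

* Second-order central differences on a uniform grid (default 201 points
  over 600 µm); complex tridiagonal (Thomas) solve, checked against a dense
  solve of the same operator.
* Crank–Nicolson (A-stable) time stepping at 80 samples per period; 30
  cycles with a 10-cycle half-Hann ramp; the last 8 cycles form the steady
  state. The 20 kHz steady-state envelope matches the frequency-domain
  magnitude to 0.3%.
* Peak positions are refined by 3-point parabolic interpolation (printed
  positions are finer than any affordable grid); argmax ties at a boundary
  are flagged, never fabricated.
* The displacement at the pressure-release node is exactly zero, so its
  phase is taken as the limit from the interior (the pressure crosses zero
  linearly there).
* Calibration is deterministic: fixed coarse grid, Nelder–Mead with one
  restart (the peak-position objective is piecewise smooth because the
  argmax can hop between envelope lobes), clamped bounds.
* All randomness (microrheology only) flows from explicit integer seeds.

## Known limitations

The 1D incompressible, locally reacting reduction cannot reproduce the
low-frequency phase surface or its monotone growth (see above); the
pressure-release facilitator is an ideal $p=0$ end rather than a compliant
membrane; dendrite and cap-cell masses are folded into the coupling spring;
the tympanal plates and acoustic trachea are outside the model (the drive
is prescribed); material damping is absent by design, so the wave does not
fully die beyond the peak. Peak *positions* and the qualitative ablation
surface are robust to these choices; absolute displacement magnitudes and
phase totals are not.
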