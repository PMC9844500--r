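---
title: "Velocity-selective neck MRA: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-selective neck MRA: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmra)
```

## The physical model

Everything in this package rests on the rotating-frame Bloch equation
under the hard-pulse approximation: RF and gradient waveforms are
piecewise constant on a raster (default 0.05 ms), and each raster step
applies the exact rotation generated by the effective field — the
B1-scaled RF in the transverse plane plus `f0 + γ̄·G·x(t)` along z, with
`γ̄ = 42.577` kHz/mT. Handedness is pinned by one convention: a 90°
pulse of phase 0 takes equilibrium magnetization to +y. Spin position
advances linearly, `x(t) = x0 + v·t`, evaluated at each sample centre;
for linear motion the midpoint rule makes the accrued gradient phase
exact, so halving the raster changes the simulated response only at
round-off level. Velocity is held constant within one preparation pulse
(tens of milliseconds against a ~900 ms cardiac cycle); pulsatility
enters only at the protocol level through the flow curve. Relaxation,
when enabled, uses rotate-then-relax operator splitting per step, which
is second-order accurate in the step size. Diffusion, flow acceleration
and exchange are out of scope.

## The VS saturation pulse

The VS preparation is a train of `n_sub` hard sub-pulses (default 9,
total flip 100°) whose eight intervals each perform one unit of velocity
encoding. The interval layout is

    lobe(G, τ) — 90x·180y·90x — lobe(G, τ) — 90x·180y·90x

with unipolar rectangular lobes. Two properties motivated this layout
over the alternatives the schematic leaves open. First, with the
composite after each lobe, a static spin's gradient and off-resonance
phase cancels within the interval exactly (the composite is an exact
180° about y at ideal fields). Second — and decisively — the *even*
number of refocusing pulses per interval leaves the rotating frame
untoggled across intervals, so the per-interval velocity phase
`Δφ = 2πv/FOV_v` accrues monotonically along the train and the
excitation profile is the Dirichlet kernel
`flip(v) ∝ |sin(nΔφ/2)/sin(Δφ/2)|`: narrow saturation bands at
multiples of the velocity FOV and a wide pass band between. We
verified by simulation that a single composite per interval toggles the
effective phase sign, collapsing the profile to only two phase states
and producing a qualitatively wrong (far too wide) stop band that would
saturate venous and even arterial velocities.

The lobe amplitude is solved from the phase contract:
`G = 1e5 / (γ̄ · τ · (τ + c) · FOV_v)` mT/m with `τ` the lobe duration
and `c` the composite duration. With the defaults (τ = 0.7 ms,
c = 1.0 ms) the reference design needs 28.2 mT/m, inside the 40 mT/m
default cap; an infeasible request errors rather than silently
clipping. Sub-pulse amplitudes are uniform (plain hard pulses, no
window): the stop-band side-lobe ripple this causes is visible in the
pass band and is reported honestly by the simulation.

Two cut-off numbers are reported deliberately. The constructor reports
the design convention `FOV_v / (2(n_sub + 1))` — 3.5 cm/s for the
default design — which is exact arithmetic; `stopband_halfwidth()`
reports the Bloch-simulated velocity at which Mz(v) actually crosses a
chosen level, because the convention and the simulated truth need not
coincide and the literature does not fix the threshold.

### Pre-compensation

Field errors enter the pulse as a B1 amplitude scale `s` and an
off-resonance `f0`. The pre-compensation multiplies the RF by
`A·e^{j2πft}` with `A = 1/s` and `f = f0`: the amplitude factor undoes
the scale exactly, and the phase ramp makes the RF track the
off-resonant precession. Internally the ramp is applied with the
handedness of the package's rotating frame — the sign that we verified
cancels (rather than doubles) the precession. Calibration reduces a
mapped ROI to `(A, f)` by the median of the 5%-outlier-trimmed values;
the trimming is interpreted as 2.5% per tail (symmetric trimming being
the standard reading), and the median was chosen as the representative
statistic because the measurement protocol reports ranges without
naming one — both the statistic and the trim fraction are exposed as
arguments.

### The shifted shot set

Under B1 error the composites are imperfect and the residual coupling
to the per-lobe gradient phase `2πγ̄·G·τ·x` makes the static response
spatially periodic (stripes, period ≈ 1.2 mm for the default design).
Four shots whose patterns are mutually shifted by quarter periods
average the stripes out. The shift is realised exactly: adding a
constant `c = 2πk/n_shots` to every lobe's accrued phase is
operator-identical to translating the spin coordinate by
`c/(2πγ̄·G·τ)`, and a spin phase offset in turn equals an RF phase
offset on everything played afterwards. So shot `k` offsets the phase
of each RF sample by `k/n_shots` turns per completed gradient lobe. A
literal per-lobe gradient-area offset was considered and rejected: it
rescales the stripe pattern about the isocentre instead of translating
it, so the quarter-period property would hold only locally.

## The slab-selective inversion

The SS inversion is a 30 ms hyperbolic-secant adiabatic pulse,
`A(t') = B1max·sech(βt')`, `Δf(t') = −μβ·tanh(βt')/2π`, with β = 300
rad/s and μ = 14, giving a sweep of ±668 Hz and an inversion bandwidth
μβ/π = 1336.9 Hz (the rounded figure 1338 Hz commonly quoted for this
parameter set differs by 0.08%; both are honoured within tolerance). The sweep is realised
as phase modulation — single-channel, hardware-faithful, and equivalent
in the rotating frame. The slab gradient maps the band onto the slab:
`G = bandwidth/(γ̄·thickness)`. The peak amplitude default is the
adiabatic threshold: the smallest amplitude, searched in 0.5 µT steps,
that reaches Mz < −0.97 on resonance (7 µT for the default pulse);
above threshold the inversion is insensitive to B1 overdrive, which is
the point of using an adiabatic pulse for the slab. The slab covers the
imaging volume plus a superior margin (162/115 mm for stations 1/2) so
that upstream venous blood is inverted before it flows down into the
volume.

## Timing calibration

Systole detection defines the peak as the velocity maximum and the
onset as the crossing of `baseline + 10%` of the upstroke height
(baseline = pre-peak minimum), linearly interpolated. The 10% threshold
and the lead times (inversion 20 ms before onset, VS pulse 15 ms before
peak, rounded half-up to 10 ms) were chosen because they map the mean
systolic timings of both stations (58.15/126.32 and 90.23/150.38 ms)
onto the reference trigger delays 40/110 and 70/140 ms — they are
configuration, not constants. On 20.05 ms cine grids the threshold
rule biases the onset by roughly a tenth of the upstroke duration,
which stays inside one time step for carotid-like curves; the recovery
test quantifies this over 100 seeded curves.

## Sampling schedule

The ky–kz plane is traversed in a square spiral from the origin:
Chebyshev rings in increasing order, each ring counter-clockwise
starting toward +ky (the turning direction is not physically
constrained; it is fixed for determinism). Indices are DC-centred with
the half-open convention (even sizes put the extra index on the
negative side) so masks are bit-exact. Inside the calibration core
every point is acquired; outside, every R-th visited point — decimation
counts spiral steps, not rings, giving uniform 1/R density along the
walk. Whether calibration points advance the decimation counter is
genuinely unspecified; it is exposed as a flag (default: they do not).
The acquired sequence is chunked into segments of `views_per_segment`,
so early segments hold the k-space centre along both axes.

## The digital phantom and protocol simulator

The phantom stands in for subjects, which are outside what a simulation
can reproduce. It is a labelled voxel volume: two vertical arterial
trunks, one horizontal branch emulating a subclavian artery, two
vertical veins, an elliptical muscle body with a fat rim, and air. The
study conditions are its defaults: arterial peak velocities 66.18/46.88
cm/s and venous 9.45/18.01 cm/s for stations 1/2, systolic onset/peak
58.15/126.32 ms (station 1) and 90.23/150.38 ms (station 2), field maps
spanning −145.3…346.9 Hz and 0.57…1.17 (station 1). T1/T2 default to
3 T literature conventions (blood 1650/150 ms, muscle 900/50 ms, fat
370/130 ms) since the protocol does not state them; all are arguments.
The horizontal branch is assigned 70% of the arterial speed along the
encoding axis as a stand-in for its oblique flow.

The protocol simulator evolves Mz analytically per voxel: recovery to
the inversion trigger, inversion by the simulated HS efficiency at the
voxel's off-resonance, recovery across one R-R to the VS trigger,
replacement of arterial voxels by fully relaxed magnetization (the two
systolic inflows between the triggers bring upstream blood that never
saw the inversion — the exact replacement bookkeeping between the two
triggers is not physically pinned down, so the rule is
config-selectable), VS scaling by
the simulated velocity response at the voxel's velocity (and local
B0/B1, quantised to share Bloch runs), TI recovery, the GRE echo train,
and recovery to the cycle end, iterated to periodic steady state
(tolerance 1e-6 on the per-cycle change). The rendered signal is the
pre-readout Mz × sin(flip) × proton density at the first, centre-of-k-
space view: with center-out ordering the first view dominates contrast,
and full echo-train k-space filtering was judged not worth its cost for
a desk-scale simulator. Fat is treated as perfectly suppressed.

What the phantom does **not** emulate: coil sensitivities and spatially
varying noise, parallel-imaging reconstruction, partial-volume and
pulsatility artifacts, patient motion, or realistic vascular geometry.
Passing its tests shows that the contrast *mechanisms* behave as
designed (venous suppression needs the SS pulse; pre-compensation
recovers arterial signal where field errors are large; arteries stay
contiguous in the projection) — not that in-vivo contrast values are
reproduced. In-vivo relative CR values (around 0.78 for this kind of
protocol) depend on subject anatomy and noise and are deliberately not
a simulation target;
the phantom's noise-free CR is higher (~0.96 with the default
geometry).

## Problem sizes and numerical choices

Default rasters (0.05 ms), grids (0.5 cm/s velocity steps, 10–20 Hz
offset steps) and phantom sizes (24–40 voxels per axis, 3 mm) were
chosen so every simulation in the test suite runs in seconds on one
core while the quantities of interest are converged at far better than
their stated tolerances; the acceptance computations use the same
sizes. Degenerate inputs error early and explicitly: non-uniform or
mismatched time grids, infeasible gradient amplitudes, flat flow
curves, zero-radius tubes, empty ROIs, non-positive arterial signal in
the contrast ratio.
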