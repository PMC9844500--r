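# vsmra

Pulse design, calibration and Bloch simulation for velocity-selective
(VS) magnetization-prepared non-contrast MR angiography of the neck.

Velocity-selective MRA creates artery-to-background contrast without a
contrast agent: a VS saturation preparation knocks down the longitudinal
magnetization of spins moving slower than a cut-off speed while sparing
fast arterial flow, and an adiabatic slab-selective (SS) inversion played
one cardiac cycle earlier pre-suppresses venous blood that is too fast
for the VS stop band. Because many RF and gradient elements are chained,
the VS pulse is sensitive to B0 and B1 field errors; the package designs
the pulse with a field-error pre-compensation
`B1comp(t) = A · B1(t) · e^{j2πft}` whose parameters come from trimmed
ROI statistics of measured field maps.

The package provides:

* **Bloch core** — a rotating-frame, hard-pulse (piecewise-constant)
  simulator for isochromats with position, velocity, off-resonance, B1
  scale and T1/T2 (`simulate_piecewise()`, `hard_pulse_rotation()`).
* **VS preparation** — the double-refocused VS saturation pulse: `n`
  hard sub-pulses (total flip θ) separated by velocity-encoding
  intervals of two unipolar gradient lobes and two 90°x–180°y–90°x
  composite refocusing pulses, so a spin at velocity `v` accrues
  `2πv/FOV_v` of phase per interval and the Mz(v) response is periodic
  with the velocity field of view. Includes the pre-compensation, the
  nominal cut-off `FOV_v / (2(n+1))` and the four-shot spatially
  shifted set that averages away stripe artifacts
  (`design_vs_pulse()`, `velocity_response()`, `make_shot_set()`).
* **SS preparation** — the hyperbolic-secant adiabatic inversion
  (β, μ parameterisation, bandwidth μβ/π) and its slab geometry with a
  superior venous margin (`design_hs_inversion()`, `slab_geometry()`).
* **Calibration** — trimmed field-map ROI statistics to
  pre-compensation parameters, and systole detection on time-velocity
  curves to ECG trigger delays (`derive_precomp()`, `detect_systole()`,
  `derive_trigger_delays()`).
* **Sampling** — the center-out square-spiral ky–kz ordering with a
  fully sampled calibration core, outer-region under-sampling and
  segment assignment (`build_schedule()`).
* **Phantom simulation** — a digital neck phantom, synthetic flow
  curves and field maps, and an ECG-gated protocol simulator scored by
  the relative contrast ratio `CR = (S_A − S_M)/S_A`
  (`make_neck_phantom()`, `simulate_protocol()`, `relative_cr()`).

## Worked example

```r
library(vsmra)

spec <- vs_pulse_spec(n_sub = 9, flip_total = 100, fov_v = 70)
pulse <- design_vs_pulse(spec)
pulse
#> preparation pulse (VS saturation): 580 samples, dt = 0.05 ms, duration = 29 ms
#>   n_sub = 9, flip = 100 deg, FOV_v = 70 cm/s, cut-off = 3.5 cm/s, G = 28.20 mT/m

velocity_response(pulse, c(0, 35))
#> [1] -0.1736482  0.9812553
```

At zero velocity the pulse acts as a 100° saturation
(`cos 100° = -0.174`); at half the velocity FOV the interval phases
alternate by π and the train collapses to a single 11.1° sub-pulse, so
fast spins keep almost all their magnetization. The response repeats
every 70 cm/s.

Field-error pre-compensation from measured ranges and the two-pulse
protocol on the phantom:

```r
pc <- precomp_params(A = 1 / 1.15, f = 100)   # station-1 calibration
shots <- make_shot_set(spec, 4, precomp = pc)
hs <- design_hs_inversion(hs_pulse_spec(duration = 30, beta = 300, mu = 14))

ph <- make_neck_phantom(station = 1, seed = 7)
img <- simulate_protocol(ph, protocol_config(TD_ss = 40, TD_vs = 110),
                         shots, hs)
relative_cr(img, phantom_roi(ph, "artery"), phantom_roi(ph, "muscle"))
#> [1] 0.9637345
```

The simulated relative contrast ratio of ~0.96 reflects the phantom's
noise-free, perfectly fat-suppressed conditions; muscle is doubly
suppressed by the SS and VS preparations while fresh arterial inflow
reads out nearly fully relaxed.

A thin command-line front end over the same functions ships in
`inst/cli/vsmra.R` (subcommands `design-vs`, `design-ss`,
`make-trajectory`, `simulate-phantom`, `compute-cr`).

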