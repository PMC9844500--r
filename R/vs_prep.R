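#' Specification of the velocity-selective saturation pulse
#'
#' Design parameters of the double-refocused VS saturation preparation: a
#' train of `n_sub` hard RF sub-pulses (total flip `flip_total`) whose
#' inter-pulse intervals each carry two unipolar velocity-encoding gradient
#' lobes straddled by two 90x-180y-90x composite refocusing pulses. The
#' per-interval gradient first moment is solved so that a spin moving at
#' velocity v accrues a phase of 2*pi*v/`fov_v` per interval, making the
#' velocity response periodic with period `fov_v`.
#'
#' @param n_sub Number of hard sub-pulses (>= 2; an odd count keeps the
#'   composite refocusing pairs balanced across the train).
#' @param flip_total Total on-resonance flip in degrees (0 < flip < 180).
#' @param fov_v Velocity field of view in cm/s (> 0), the period of the
#'   velocity response.
#' @param sub_pulse_dur Duration of each hard sub-pulse, ms.
#' @param grad_lobe_dur Duration of each rectangular gradient lobe, ms.
#' @param t90 Duration of the 90 degree element of each composite
#'   refocusing pulse, ms (the 180 element lasts `2 * t90` at the same
#'   amplitude).
#' @param dt Simulation/raster time step, ms; all durations must be
#'   integer multiples of it.
#' @param grad_max Hardware gradient amplitude cap, mT/m; the design
#'   signals an error if the solved lobe amplitude exceeds it.
#' @param shot_index Which member of the spatially shifted shot set this
#'   pulse is (0-based; see [make_shot_set()]).
#' @param n_shots Size of the shot set `shot_index` refers to.
#' @return Object of class `vs_pulse_spec`.
#' @export
vs_pulse_spec <- function(n_sub = 9, flip_total = 100, fov_v = 70,
                          sub_pulse_dur = 0.2, grad_lobe_dur = 0.7,
                          t90 = 0.25, dt = 0.05, grad_max = 40,
                          shot_index = 0, n_shots = 4) {
  if (n_sub < 2) stop("n_sub must be at least 2")
  if (fov_v <= 0) stop("fov_v must be positive")
  if (flip_total <= 0 || flip_total >= 180)
    stop("flip_total must lie in (0, 180) degrees")
  for (d in c(sub_pulse_dur, grad_lobe_dur, t90, dt))
    if (d <= 0) stop("all durations must be positive")
  for (d in c(sub_pulse_dur, grad_lobe_dur, t90)) {
    k <- d / dt
    if (abs(k - round(k)) > 1e-9)
      stop("sub_pulse_dur, grad_lobe_dur and t90 must be multiples of dt")
  }
  if (shot_index < 0 || shot_index >= n_shots)
    stop("shot_index must lie in [0, n_shots)")
  structure(list(n_sub = as.integer(n_sub), flip_total = flip_total,
                 fov_v = fov_v, sub_pulse_dur = sub_pulse_dur,
                 grad_lobe_dur = grad_lobe_dur, t90 = t90, dt = dt,
                 grad_max = grad_max, shot_index = as.integer(shot_index),
                 n_shots = as.integer(n_shots)),
            class = "vs_pulse_spec")
}

#' Nominal cut-off velocity of a VS pulse design
#'
#' Returns the design-convention cut-off `fov_v / (2 * (n_sub + 1))`, the
#' nominal boundary between the saturated (slow) and preserved (fast)
#' velocity bands. For nine sub-pulses and a 70 cm/s velocity field of
#' view this is 3.5 cm/s. The Bloch-simulated stop-band half-width, which
#' need not coincide with the convention, is available from
#' [stopband_halfwidth()].
#'
#' @param spec A [vs_pulse_spec] (or anything with `fov_v` and `n_sub`).
#' @return Cut-off velocity in cm/s.
#' @export
cutoff_velocity <- function(spec) {
  spec$fov_v / (2 * (spec$n_sub + 1))
}

#' Pre-compensation parameters for field errors
#'
#' Amplitude factor `A` (the inverse of the representative measured B1
#' scale) and frequency `f` in Hz (the representative off-resonance) used
#' to pre-distort the VS pulse RF as `A * B1(t) * exp(j 2 pi f t)`.
#'
#' @param A Dimensionless amplitude factor (> 0).
#' @param f Off-resonant frequency, Hz.
#' @return Object of class `precomp_params`.
#' @export
precomp_params <- function(A = 1, f = 0) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("A must be a positive finite scalar")
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
    stop("f must be a finite scalar (Hz)")
  structure(list(A = A, f = f), class = "precomp_params")
}

#' Apply field-error pre-compensation to an RF waveform
#'
#' Multiplies every RF sample by `A * exp(j 2 pi f t)` with `t` the
#' sample-centre time, scaling the amplitude by `A` and adding a linear
#' phase ramp of `f` Hz. The ramp is applied with the handedness of the
#' package's rotating frame, so that a ramp of `f` Hz tracks (and thereby
#' cancels) the precession of spins that are off-resonant by `f` Hz.
#' Duration and gradient are unchanged.
#'
#' @param rf An [rf_waveform].
#' @param p A [precomp_params].
#' @return The pre-compensated [rf_waveform].
#' @export
precompensate_rf <- function(rf, p) {
  if (!inherits(p, "precomp_params")) p <- do.call(precomp_params, as.list(p))
  tmid <- (seq_along(rf$samples) - 0.5) * rf$dt
  rf_waveform(rf$samples * p$A * exp(-1i * 2 * pi * p$f * tmid * 1e-3), rf$dt)
}

# Internal: element-by-element plan of the VS pulse. Each interval between
# sub-pulses is [lobe][composite][lobe][composite]; the pair of composites
# keeps the rotating frame untoggled across the interval, so the velocity
# phase accrues monotonically over the train and all sub-pulses share
# phase 0.
vs_pulse_plan <- function(spec) {
  th_sub <- spec$flip_total / spec$n_sub
  # hard-pulse nutation amplitude (Hz) for a given flip (deg) and duration (ms)
  amp_hz <- function(flip, dur) flip / 360 / (dur * 1e-3)
  sub_amp <- amp_hz(th_sub, spec$sub_pulse_dur)
  comp_amp <- amp_hz(90, spec$t90)
  tau <- spec$grad_lobe_dur
  comp_dur <- 4 * spec$t90
  # per-interval velocity phase 2*pi*v/fov_v  =>  lobe amplitude
  G <- 1e5 / (gamma_bar() * tau * (tau + comp_dur) * spec$fov_v)
  els <- list()
  add <- function(els, type, dur, amp, phase = 0, grad = 0)
    c(els, list(list(type = type, dur = dur, amp = amp, phase = phase,
                     grad = grad)))
  for (k in seq_len(spec$n_sub)) {
    els <- add(els, "sub", spec$sub_pulse_dur, sub_amp, 0)
    if (k < spec$n_sub) {
      for (half in 1:2) {
        els <- add(els, "lobe", tau, 0, 0, G)
        els <- add(els, "comp90a", spec$t90, comp_amp, 0)
        els <- add(els, "comp180", 2 * spec$t90, comp_amp, pi / 2)
        els <- add(els, "comp90b", spec$t90, comp_amp, 0)
      }
    }
  }
  list(elements = els, grad_amp = G, sub_amp = sub_amp, comp_amp = comp_amp,
       comp_dur = comp_dur,
       interval_first_moment = G * tau * (tau + comp_dur),
       lobe_cycles_per_mm = gamma_bar() * G * tau * 1e-3)
}

#' Design the double-refocused velocity-selective saturation pulse
#'
#' Builds the RF and gradient waveforms of the VS saturation preparation:
#' `n_sub` uniform hard sub-pulses of `flip_total / n_sub` degrees each,
#' separated by velocity-encoding intervals. Each interval holds two
#' unipolar rectangular gradient lobes, each followed by a 90x-180y-90x
#' composite refocusing pulse, so that (a) a static on-resonance spin
#' accrues zero net phase per interval, (b) a spin at velocity v accrues
#' `2*pi*v/fov_v` per interval (the lobe amplitude is solved from the
#' gyromagnetic ratio, lobe duration and lobe spacing), and (c) the even
#' number of refocusing pulses per interval leaves the rotating frame
#' untoggled, so the zero-velocity effective flip equals `flip_total`.
#'
#' A non-zero `shot_index` produces the member of the spatially shifted
#' shot set whose stripe pattern is translated by
#' `shot_index / n_shots` of one stripe period (see [make_shot_set()]).
#'
#' @param spec A [vs_pulse_spec].
#' @param precomp Optional [precomp_params]; when given, the assembled RF
#'   is passed through [precompensate_rf()].
#' @return Object of class `preparation_pulse`: list with `rf`
#'   ([rf_waveform]), `grad` ([gradient_waveform], z axis) and `meta`
#'   (design spec plus solved amplitudes, the per-interval gradient first
#'   moment in mT*ms^2/m, and the stripe period in mm).
#' @export
design_vs_pulse <- function(spec, precomp = NULL) {
  if (!inherits(spec, "vs_pulse_spec")) stop("spec must be a vs_pulse_spec")
  plan <- vs_pulse_plan(spec)
  if (plan$grad_amp > spec$grad_max)
    stop(sprintf(paste0("infeasible spec: required gradient amplitude ",
                        "%.2f mT/m exceeds the %.2f mT/m cap"),
                 plan$grad_amp, spec$grad_max))
  dt <- spec$dt
  ns <- vapply(plan$elements, function(e) round(e$dur / dt), numeric(1))
  total <- sum(ns)
  rf <- complex(real = numeric(total), imaginary = numeric(total))
  gr <- numeric(total)
  lobes_before <- numeric(total)
  pos <- 0L
  lobe_count <- 0L
  for (j in seq_along(plan$elements)) {
    e <- plan$elements[[j]]
    idx <- pos + seq_len(ns[j])
    if (e$amp > 0) rf[idx] <- e$amp * exp(1i * e$phase)
    gr[idx] <- e$grad
    lobes_before[idx] <- lobe_count
    if (e$type == "lobe") lobe_count <- lobe_count + 1L
    pos <- pos + ns[j]
  }
  # Spatially shifted shot: translating the stripe pattern by dx adds a
  # constant phase c = 2*pi*k_lobe*dx to every lobe's z rotation; that is
  # realised exactly by offsetting the phase of all RF played after each
  # completed lobe by -c (frame bookkeeping; the final global z rotation
  # does not affect Mz).
  if (spec$shot_index != 0L) {
    cshift <- 2 * pi * spec$shot_index / spec$n_shots
    rf <- rf * exp(1i * cshift * lobes_before)
  }
  rfw <- rf_waveform(rf, dt)
  if (!is.null(precomp)) rfw <- precompensate_rf(rfw, precomp)
  meta <- c(unclass(spec),
            list(grad_amp = plan$grad_amp,
                 sub_amp = plan$sub_amp,
                 comp_amp = plan$comp_amp,
                 interval_first_moment = plan$interval_first_moment,
                 stripe_period_mm = 1 / plan$lobe_cycles_per_mm,
                 cutoff_velocity = cutoff_velocity(spec),
                 duration = total * dt,
                 precomp = precomp))
  structure(list(rf = rfw,
                 grad = gradient_waveform(gr, dt, "z"),
                 meta = meta),
            class = "preparation_pulse")
}

#' @export
print.preparation_pulse <- function(x, ...) {
  kind <- if (!is.null(x$meta$beta)) "adiabatic HS inversion" else
    "VS saturation"
  cat(sprintf("preparation pulse (%s): %d samples, dt = %g ms, duration = %g ms\n",
              kind, length(x$rf$samples), x$rf$dt,
              length(x$rf$samples) * x$rf$dt))
  if (!is.null(x$meta$fov_v))
    cat(sprintf("  n_sub = %d, flip = %g deg, FOV_v = %g cm/s, cut-off = %g cm/s, G = %.2f mT/m\n",
                x$meta$n_sub, x$meta$flip_total, x$meta$fov_v,
                x$meta$cutoff_velocity, x$meta$grad_amp))
  invisible(x)
}

#' Simulated velocity response of a preparation pulse
#'
#' Bloch-simulates the final longitudinal magnetization of equilibrium
#' spins over a velocity grid, the Mz(v) profile that defines the stop and
#' pass bands of the VS preparation.
#'
#' @param pulse A `preparation_pulse`.
#' @param velocities Velocity grid, cm/s.
#' @param off_resonance Off-resonance of the simulated spins, Hz.
#' @param b1_scale B1 scale of the simulated spins.
#' @param position Reference position along the gradient axis, mm.
#' @param relaxation Logical; default off (the pulse is short against T1).
#' @param T1,T2 Relaxation times (ms) when `relaxation` is on.
#' @return Numeric vector of final Mz, one per velocity.
#' @export
velocity_response <- function(pulse, velocities, off_resonance = 0,
                              b1_scale = 1, position = 0,
                              relaxation = FALSE, T1 = 1650, T2 = 150) {
  if (any(!is.finite(velocities))) stop("velocity grid must be finite")
  M <- bloch_run(pulse$rf, pulse$grad, position = position,
                 velocity = velocities, off_resonance = off_resonance,
                 b1_scale = b1_scale, relaxation = relaxation,
                 T1 = T1, T2 = T2)
  M[3, ]
}

#' Simulated spatial response of a preparation pulse
#'
#' Final Mz of static (or uniformly moving) spins over a position grid
#' along the gradient axis. Under field errors the VS pulse's residual
#' refocusing errors make this profile periodic in position (the stripe
#' artifact); the shifted shot set of [make_shot_set()] translates it.
#'
#' @param pulse A `preparation_pulse`.
#' @param positions Position grid, mm.
#' @param velocity Common velocity of the spins, cm/s.
#' @param off_resonance Off-resonance, Hz.
#' @param b1_scale B1 scale.
#' @return Numeric vector of final Mz, one per position.
#' @export
spatial_response <- function(pulse, positions, velocity = 0,
                             off_resonance = 0, b1_scale = 1) {
  M <- bloch_run(pulse$rf, pulse$grad, position = positions,
                 velocity = velocity, off_resonance = off_resonance,
                 b1_scale = b1_scale)
  M[3, ]
}

#' Bloch-simulated stop-band half-width
#'
#' The smallest velocity at which the simulated Mz(v) of the pulse rises
#' through `threshold`, i.e. the half-width of the saturated band around
#' v = 0. Reported separately from the design-convention
#' [cutoff_velocity()], which is exact arithmetic.
#'
#' @param pulse A `preparation_pulse` from [design_vs_pulse()].
#' @param threshold Mz level defining the stop-band edge.
#' @param dv Velocity grid step for the search, cm/s.
#' @return Half-width in cm/s.
#' @export
stopband_halfwidth <- function(pulse, threshold = 0.5, dv = 0.1) {
  vmax <- pulse$meta$fov_v / 2
  v <- seq(0, vmax, by = dv)
  mz <- velocity_response(pulse, v)
  i <- which(mz > threshold)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  # linear interpolation of the crossing
  v[i - 1] + dv * (threshold - mz[i - 1]) / (mz[i] - mz[i - 1])
}

#' Build the spatially shifted VS shot set
#'
#' Returns `n_shots` VS pulses whose striped spatial responses (present
#' under B0/B1 errors) are mutually translated by `1/n_shots` of one
#' stripe period, while the velocity response at the reference position is
#' unchanged. Alternating the shots across segments averages the stripe
#' pattern out of the final image.
#'
#' @param spec A [vs_pulse_spec] (its `shot_index` is ignored).
#' @param n_shots Number of shots (>= 1).
#' @param precomp Optional [precomp_params] applied to every shot.
#' @return List of `n_shots` `preparation_pulse` objects.
#' @export
make_shot_set <- function(spec, n_shots = 4, precomp = NULL) {
  if (n_shots < 1) stop("n_shots must be at least 1")
  lapply(seq_len(n_shots) - 1L, function(k) {
    s <- spec
    s$shot_index <- k
    s$n_shots <- as.integer(n_shots)
    design_vs_pulse(s, precomp = precomp)
  })
}
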