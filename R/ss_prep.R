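#' Specification of the hyperbolic-secant slab-selective inversion
#'
#' Adiabatic inversion with sech amplitude envelope and tanh frequency
#' sweep, parameterised by the modulation rate `beta` (rad/s) and the
#' dimensionless sharpness `mu`; its inversion bandwidth is `mu*beta/pi`
#' Hz. Played under a constant slab-select gradient whose amplitude maps
#' the bandwidth onto the requested slab thickness.
#'
#' @param duration Pulse duration, ms.
#' @param beta Modulation angular frequency, rad/s.
#' @param mu Dimensionless modulation parameter.
#' @param peak_b1 Peak nutation amplitude in Hz, or `NULL` to use the
#'   smallest amplitude (searched in 0.5 uT steps, about 21.3 Hz each)
#'   that achieves on-resonance Mz < -0.97 — the adiabatic threshold.
#' @param slab_thickness Slab thickness, mm.
#' @param dt Raster time step, ms.
#' @return Object of class `hs_pulse_spec`.
#' @export
hs_pulse_spec <- function(duration = 30, beta = 300, mu = 14,
                          peak_b1 = NULL, slab_thickness = 264, dt = 0.05) {
  for (v in c(duration, beta, mu, slab_thickness, dt))
    if (!is.numeric(v) || v <= 0 || !is.finite(v))
      stop("duration, beta, mu, slab_thickness and dt must be positive")
  if (!is.null(peak_b1) && peak_b1 <= 0) stop("peak_b1 must be positive")
  structure(list(duration = duration, beta = beta, mu = mu,
                 peak_b1 = peak_b1, slab_thickness = slab_thickness,
                 dt = dt),
            class = "hs_pulse_spec")
}

#' Bandwidth of a hyperbolic-secant inversion
#'
#' The full frequency sweep of the HS pulse, `mu * beta / pi` Hz, which is
#' the width of its inversion band. For beta = 300 rad/s and mu = 14 this
#' is 1336.9 Hz.
#'
#' @param beta Modulation angular frequency, rad/s.
#' @param mu Dimensionless modulation parameter.
#' @return Bandwidth in Hz.
#' @export
hs_bandwidth <- function(beta, mu) {
  if (beta < 0 || mu < 0) stop("beta and mu must be non-negative")
  mu * beta / pi
}

#' Design the adiabatic hyperbolic-secant slab-selective inversion
#'
#' Builds the HS pulse on a raster of step `dt`, time-symmetric about the
#' pulse centre (t' in [-duration/2, +duration/2]):
#' amplitude `A(t') = peak_b1 * sech(beta t')`, frequency sweep
#' `df(t') = -mu * beta * tanh(beta t') / (2 pi)` Hz realised as phase
#' modulation (`phi(t') = mu * log(cosh(beta t'))` in the package's frame
#' handedness, single-channel RF). The slab-select gradient is constant at
#' `bandwidth / (gamma_bar * slab_thickness)` mT/m so the inversion band
#' spans the requested thickness.
#'
#' @param spec An [hs_pulse_spec]. When `peak_b1` is `NULL` the adiabatic
#'   threshold amplitude is searched with [hs_adiabatic_threshold()].
#' @return Object of class `preparation_pulse` with `rf`, `grad` and
#'   `meta` (spec plus solved `peak_b1`, `grad_amp`, `bandwidth`).
#' @export
design_hs_inversion <- function(spec) {
  if (!inherits(spec, "hs_pulse_spec")) stop("spec must be an hs_pulse_spec")
  peak <- spec$peak_b1
  if (is.null(peak)) peak <- hs_adiabatic_threshold(spec)
  n <- round(spec$duration / spec$dt)
  tprime <- ((seq_len(n) - 0.5) * spec$dt - spec$duration / 2) * 1e-3  # s
  bt <- spec$beta * tprime
  amp <- peak / cosh(bt)
  # phase modulation equivalent of the tanh sweep: dphi/dt = -2*pi*df(t)
  # in the package's left-handed rotating frame (same handedness as the
  # precompensation ramp), phi(t') = mu * log(cosh(beta t')).
  phase <- spec$mu * log(cosh(bt))
  rf <- rf_waveform(amp * exp(1i * phase), spec$dt)
  bw <- hs_bandwidth(spec$beta, spec$mu)
  g <- bw / (gamma_bar() * spec$slab_thickness)
  grad <- gradient_waveform(rep(g, n), spec$dt, "z")
  meta <- c(unclass(spec),
            list(peak_b1 = peak, grad_amp = g, bandwidth = bw))
  structure(list(rf = rf, grad = grad, meta = meta),
            class = "preparation_pulse")
}

#' Adiabatic threshold amplitude of an HS pulse
#'
#' Smallest peak nutation amplitude, searched upward in steps of
#' `step` Hz (0.5 uT-equivalent by default), for which the simulated
#' on-resonance inversion reaches Mz < `target`.
#'
#' @param spec An [hs_pulse_spec] (its `peak_b1` is ignored).
#' @param target Required final Mz on resonance.
#' @param step Search step in Hz of nutation (default 0.5 uT, i.e.
#'   `0.5 * gamma_bar()` Hz).
#' @param max_steps Upper bound on the search.
#' @return Threshold amplitude in Hz.
#' @export
hs_adiabatic_threshold <- function(spec, target = -0.97,
                                   step = 0.5 * gamma_bar(),
                                   max_steps = 60) {
  for (k in seq_len(max_steps)) {
    s <- spec
    s$peak_b1 <- k * step
    p <- design_hs_inversion_fixed(s)
    mz <- inversion_profile(p, 0)
    if (mz < target) return(k * step)
  }
  stop("no adiabatic threshold found within the search range")
}

# design with peak_b1 taken as given (avoids recursion during the search)
design_hs_inversion_fixed <- function(spec) {
  if (is.null(spec$peak_b1)) stop("peak_b1 must be set")
  design_hs_inversion(spec)
}

#' Simulated inversion profile of a preparation pulse
#'
#' Final Mz of equilibrium spins over an off-resonance grid (equivalently,
#' over position along the slab gradient at
#' `x = offset / (gamma_bar * grad_amp)`).
#'
#' @param pulse A `preparation_pulse` (the slab gradient is ignored here;
#'   the offsets already parameterise position along it).
#' @param offsets Off-resonance grid, Hz.
#' @param peak_b1_scale B1 scale applied to the RF.
#' @return Numeric vector of final Mz, one per offset.
#' @export
inversion_profile <- function(pulse, offsets, peak_b1_scale = 1) {
  if (any(!is.finite(offsets))) stop("offset grid must be finite")
  grad0 <- gradient_waveform(rep(0, length(pulse$rf$samples)),
                             pulse$rf$dt, pulse$grad$axis)
  M <- bloch_run(pulse$rf, grad0, off_resonance = offsets,
                 b1_scale = peak_b1_scale)
  M[3, ]
}

#' Slab geometry of the spatially selective inversion
#'
#' The inversion slab covers the imaging volume and extends beyond it in
#' the superior direction by `margin_superior` mm to encompass upstream
#' venous blood; the inferior edges coincide.
#'
#' @param imaging_extent Length-2 numeric, the S-I interval of the imaging
#'   volume in mm (inferior, superior), or a single thickness in mm
#'   (taken as (0, thickness)).
#' @param margin_superior Superior overhang, mm (>= 0).
#' @return Object of class `slab_geometry` with `imaging_extent`,
#'   `margin_superior`, `slab_extent` and `slab_thickness`.
#' @export
slab_geometry <- function(imaging_extent, margin_superior) {
  if (length(imaging_extent) == 1L) imaging_extent <- c(0, imaging_extent)
  if (length(imaging_extent) != 2L || diff(imaging_extent) <= 0)
    stop("imaging_extent must be a positive interval (inferior, superior)")
  if (margin_superior < 0) stop("invalid geometry: negative superior margin")
  slab <- c(imaging_extent[1], imaging_extent[2] + margin_superior)
  structure(list(imaging_extent = imaging_extent,
                 margin_superior = margin_superior,
                 slab_extent = slab,
                 slab_thickness = diff(slab)),
            class = "slab_geometry")
}

#' @export
print.slab_geometry <- function(x, ...) {
  cat(sprintf("slab geometry: imaging [%g, %g] mm, superior margin %g mm -> slab [%g, %g] mm (%g mm thick)\n",
              x$imaging_extent[1], x$imaging_extent[2], x$margin_superior,
              x$slab_extent[1], x$slab_extent[2], x$slab_thickness))
  invisible(x)
}
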