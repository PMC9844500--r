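#' ECG-gated VS-MRA protocol configuration
#'
#' Timing and readout parameters of one imaging station. The
#' slab-selective inversion plays at `TD_ss` ms after the first ECG
#' trigger; the VS saturation at `TD_vs` ms after the second trigger
#' (one R-R interval later) unless `same_rr` is set; the segmented GRE
#' readout starts `TI` ms after the VS pulse; the sequence repeats every
#' `repetition` R-R intervals.
#'
#' @param TD_ss Trigger delay of the inversion, ms.
#' @param TD_vs Trigger delay of the VS saturation, ms.
#' @param TI Inversion-to-acquisition interval, ms (>= 0).
#' @param RR R-R interval, ms (857 ms at 70 bpm).
#' @param repetition Repetition time in R-R intervals.
#' @param readout_flip GRE readout flip angle, degrees.
#' @param TR GRE repetition time, ms.
#' @param views_per_segment Views per segmented acquisition.
#' @param station 1 or 2.
#' @param station_offset S-I iso-centre offset of this station, mm
#'   (-48.5 / +65 for stations 1/2 of a 232 mm two-station coverage).
#' @param slab_margin Superior margin of the inversion slab, mm
#'   (162 / 115 for stations 1/2).
#' @param inversion_duration Duration of the SS inversion pulse, ms
#'   (used only for timing validation).
#' @param same_rr If `TRUE` the VS pulse plays in the same R-R interval
#'   as the inversion (single-trigger timing).
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(TD_ss = 40, TD_vs = 110, TI = 100, RR = 857,
                            repetition = 3, readout_flip = 14, TR = 7.6,
                            views_per_segment = 71, station = 1L,
                            station_offset = -48.5, slab_margin = 162,
                            inversion_duration = 30, same_rr = FALSE) {
  for (v in c(TD_ss, TD_vs, TI))
    if (v < 0) stop("trigger delays and TI must be non-negative")
  for (v in c(RR, repetition, readout_flip, TR, views_per_segment))
    if (v <= 0) stop("RR, repetition, readout parameters must be positive")
  gap <- if (same_rr) TD_vs - TD_ss else RR + TD_vs - TD_ss
  if (TD_ss + inversion_duration > TD_ss + gap)
    stop("inversion overlaps the VS pulse: check TD_ss/TD_vs timing")
  if (!same_rr && TD_ss + inversion_duration > TD_vs + RR)
    stop("inversion must finish within one R-R of the VS trigger")
  structure(list(TD_ss = TD_ss, TD_vs = TD_vs, TI = TI, RR = RR,
                 repetition = repetition, readout_flip = readout_flip,
                 TR = TR, views_per_segment = views_per_segment,
                 station = as.integer(station),
                 station_offset = station_offset,
                 slab_margin = slab_margin,
                 inversion_duration = inversion_duration,
                 same_rr = same_rr),
            class = "protocol_config")
}

# quantise field-map values so Bloch runs are shared across voxels
quantise <- function(x, step) round(x / step) * step

#' Simulate the ECG-gated VS-MRA protocol on a phantom
#'
#' Evolves the longitudinal magnetization of every phantom voxel
#' analytically across repetitions until periodic steady state, then
#' renders a synthetic 3D angiogram. Per cycle: T1 recovery to the
#' inversion trigger; slab-selective inversion (its simulated efficiency
#' at the voxel's off-resonance) applied to voxels inside the slab; T1
#' recovery to the VS trigger; for inflow classes (arteries, whose
#' upstream blood enters from below the slab during the two systolic
#' inflows between triggers) replacement with fully relaxed
#' magnetization; VS saturation scaling by the pulse's simulated velocity
#' response at the voxel's velocity at the VS trigger (and local B0/B1 if
#' field maps are supplied), averaged over the shot set; T1 recovery over
#' TI; the segmented GRE echo train; and recovery over the remainder of
#' the repetition. The rendered signal is the pre-readout Mz times
#' sin(readout flip) times proton density, taken at the first
#' (centre-of-k-space) view of the center-out ordering. Fat is treated
#' as perfectly suppressed by the fat-saturation pulse.
#'
#' @param phantom A [make_neck_phantom()] phantom.
#' @param protocol A [protocol_config].
#' @param vs_pulses A `preparation_pulse` or list of them (the shot set
#'   from [make_shot_set()]); `NULL` disables VS saturation.
#' @param ss_pulse A `preparation_pulse` from [design_hs_inversion()];
#'   `NULL` disables the inversion (VS-only protocol).
#' @param field_maps Optional list with arrays `b0` (Hz) and `b1`
#'   (scale) on the phantom grid, as from [synth_field_maps()].
#' @param flow Optional [flow_curve] for the pulsatile classes; default
#'   is the station's [synth_flow_curve()] with the measured landmarks.
#' @param inflow `"fresh"` (default: inflow classes arrive uninverted
#'   and fully relaxed at the VS pulse) or `"none"` (all classes keep
#'   their in-slab history).
#' @param cycles `NULL` to iterate to periodic steady state (tolerance
#'   `tol`), or an integer number of cycles from equilibrium.
#' @param tol Steady-state tolerance on the per-cycle Mz change.
#' @param b0_step,b1_step Field-map quantisation steps used to share
#'   Bloch simulations across voxels.
#' @return Numeric 3D array of simulated signal with attributes
#'   `mz_readout` (pre-readout Mz array) and `voxel`.
#' @export
simulate_protocol <- function(phantom, protocol, vs_pulses, ss_pulse,
                              field_maps = NULL, flow = NULL,
                              inflow = c("fresh", "none"),
                              cycles = NULL, tol = 1e-6,
                              b0_step = 20, b1_step = 0.05) {
  inflow <- match.arg(inflow)
  if (!inherits(phantom, "neck_phantom")) stop("phantom must be a neck_phantom")
  cls <- phantom$classes
  if (any(!phantom$labels %in% cls$code)) stop("labels outside class table")
  if (inherits(vs_pulses, "preparation_pulse")) vs_pulses <- list(vs_pulses)
  lab <- phantom$labels
  if (is.null(flow)) {
    st <- phantom$station
    art <- cls$velocity[cls$name == "artery"]
    flow <- if (st == 1L)
      synth_flow_curve(58.15, 126.32, art, period = protocol$RR)
    else synth_flow_curve(90.23, 150.38, art, period = protocol$RR)
  }

  # velocity of each class at the VS trigger (time within the cycle)
  t_vs <- protocol$TD_vs %% (max(flow$time))
  v_at <- function(peak_v, pulsatile) {
    if (!pulsatile || peak_v == 0) return(peak_v)
    scale <- peak_v / max(flow$velocity)
    stats::approx(flow$time, flow$velocity, xout = t_vs, rule = 2)$y * scale
  }
  cls$v_vs <- mapply(v_at, cls$velocity, cls$pulsatile)
  if (any(cls$pd > 0 & is.na(cls$v_vs)))
    stop("incomplete phantom: missing tissue velocity")

  nvox <- length(lab)
  b0 <- if (is.null(field_maps)) rep(0, nvox) else
    quantise(as.numeric(field_maps$b0), b0_step)
  b1 <- if (is.null(field_maps)) rep(1, nvox) else
    quantise(as.numeric(field_maps$b1), b1_step)

  # group voxels sharing (class, B0, B1): one Bloch evaluation per group
  key <- paste(as.integer(lab), b0, b1, sep = "|")
  groups <- !duplicated(key)
  gi <- match(key, key[groups])
  g_lab <- as.integer(lab)[groups]
  g_b0 <- b0[groups]; g_b1 <- b1[groups]
  g_cls <- match(g_lab, cls$code)

  # VS saturation factor: mean over shots of the velocity response
  W <- rep(1, length(g_lab))
  if (!is.null(vs_pulses)) {
    acc <- 0
    for (p in vs_pulses)
      acc <- acc + velocity_response(p, cls$v_vs[g_cls],
                                     off_resonance = g_b0, b1_scale = g_b1)
    W <- acc / length(vs_pulses)
  }

  # SS inversion factor: simulated profile at the voxel's off-resonance
  # (all phantom voxels lie inside the slab: the superior margin is what
  # keeps upstream venous blood inside it too)
  Q <- rep(1, length(g_lab))
  if (!is.null(ss_pulse)) {
    ub0 <- sort(unique(g_b0))
    prof <- inversion_profile(ss_pulse, ub0)
    Q <- prof[match(g_b0, ub0)]
  }

  T1 <- cls$T1[g_cls]
  rec <- function(m, dt) ifelse(is.finite(T1), 1 - (1 - m) * exp(-dt / T1), m)
  gap_ss_vs <- if (protocol$same_rr) protocol$TD_vs - protocol$TD_ss else
    protocol$RR + protocol$TD_vs - protocol$TD_ss
  cycle_len <- protocol$repetition * protocol$RR
  t_readout_end <- protocol$TD_ss + gap_ss_vs + protocol$TI +
    protocol$views_per_segment * protocol$TR
  t_rest <- max(0, cycle_len - t_readout_end)
  alpha <- protocol$readout_flip * pi / 180
  E1tr <- ifelse(is.finite(T1), exp(-protocol$TR / T1), 1)
  fresh <- inflow == "fresh" & cls$inflow[g_cls]

  m <- rep(1, length(g_lab))
  m_read <- m
  n_iter <- if (is.null(cycles)) 60L else as.integer(cycles)
  for (it in seq_len(n_iter)) {
    m_prev <- m
    m <- rec(m, protocol$TD_ss)
    m <- Q * m
    m <- rec(m, gap_ss_vs)
    m[fresh] <- 1
    m <- W * m
    m <- rec(m, protocol$TI)
    m_read <- m
    for (v in seq_len(protocol$views_per_segment))
      m <- (m * cos(alpha)) * E1tr + (1 - E1tr)
    m <- rec(m, t_rest)
    if (is.null(cycles) && max(abs(m - m_prev)) < tol) break
  }

  sig_g <- m_read * sin(alpha) * cls$pd[g_cls]
  sig_g[cls$fat_sat[g_cls]] <- 0
  img <- array(sig_g[gi], dim(lab))
  mz <- array(m_read[gi], dim(lab))
  attr(img, "mz_readout") <- mz
  attr(img, "voxel") <- phantom$voxel
  img
}

#' Relative artery-to-muscle contrast ratio
#'
#' `(S_A - S_M) / S_A` with `S_A` and `S_M` the mean signal intensities
#' over the arterial and muscle regions of interest.
#'
#' @param image Numeric array (e.g. from [simulate_protocol()]).
#' @param artery_roi,muscle_roi Logical arrays on the image grid.
#' @return Dimensionless relative contrast ratio.
#' @export
relative_cr <- function(image, artery_roi, muscle_roi) {
  if (!any(artery_roi) || !any(muscle_roi)) stop("ROIs must be non-empty")
  s_a <- mean(image[artery_roi])
  s_m <- mean(image[muscle_roi])
  if (s_a <= 0) stop("undefined CR: non-positive arterial signal")
  (s_a - s_m) / s_a
}

#' Maximum intensity projection
#'
#' @param image 3D numeric array.
#' @param axis Axis to project along (1, 2 or 3).
#' @return 2D matrix of per-ray maxima.
#' @export
mip <- function(image, axis = 2) {
  if (length(dim(image)) != 3L) stop("image must be 3D")
  apply(image, setdiff(1:3, axis), max)
}

#' Write a volume as NIfTI
#'
#' @param image 3D array (a voxel-size attribute or `voxel` argument
#'   sets the pixel dimensions).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel Voxel size in mm.
#' @export
write_image_nifti <- function(image, path,
                              voxel = attr(image, "voxel") %||% c(1, 1, 1)) {
  arr <- RNifti::asNifti(array(as.numeric(image), dim(image)))
  RNifti::pixdim(arr) <- rep_len(voxel, 3)
  RNifti::writeNifti(arr, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
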