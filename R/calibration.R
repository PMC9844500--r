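#' ROI sample of a field-map quantity
#'
#' Scalar values collected over a region of interest of a B0 (Hz) or B1
#' (dimensionless scale) map, tagged with the tissue label and imaging
#' station they came from.
#'
#' @param values Numeric vector (non-empty).
#' @param label Tissue label, e.g. `"artery"` or `"muscle"`.
#' @param station Imaging station, 1 (inferior) or 2 (superior).
#' @return Object of class `roi_sample`.
#' @export
roi_sample <- function(values, label = "artery", station = 1L) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("ROI values must be finite and non-empty")
  if (!station %in% c(1L, 2L)) stop("station must be 1 or 2")
  structure(list(values = values, label = label,
                 station = as.integer(station)),
            class = "roi_sample")
}

#' Extract an ROI sample from a NIfTI map and mask
#'
#' Reads a scalar volume and a binary mask on the same grid (paths or
#' `RNifti` images) and returns the masked voxel values as an
#' [roi_sample].
#'
#' @param map NIfTI path or image: the scalar map (B0 in Hz or B1 scale).
#' @param mask NIfTI path or image: non-zero voxels define the ROI.
#' @param label,station Passed to [roi_sample()].
#' @return An [roi_sample].
#' @export
roi_from_nifti <- function(map, mask, label = "artery", station = 1L) {
  m <- if (is.character(map)) RNifti::readNifti(map) else map
  k <- if (is.character(mask)) RNifti::readNifti(mask) else mask
  if (!all(dim(m) == dim(k)))
    stop("map and mask must share the same grid")
  roi_sample(as.numeric(m[k != 0]), label, station)
}

#' Trimmed range of ROI values
#'
#' Removes the 5 percent most extreme observations (interpreted as 2.5
#' percent per tail, `floor(trim_fraction/2 * n)` values at each end of
#' the sorted sample) and returns the extrema of the remainder. This is
#' the outlier rule used to turn mapped field values into design ranges.
#'
#' @param values Numeric vector (n >= 3).
#' @param trim_fraction Total fraction to remove (default 0.05).
#' @return Named numeric vector `c(min, max)`.
#' @export
trimmed_range <- function(values, trim_fraction = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("insufficient data: need at least 3 values")
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("trim_fraction must lie in [0, 1)")
  k <- floor(trim_fraction / 2 * length(values))
  s <- sort(values)
  kept <- s[(k + 1):(length(s) - k)]
  c(min = kept[1], max = kept[length(kept)])
}

# trimmed values (the surviving set used for the representative statistic)
trimmed_values <- function(values, trim_fraction = 0.05) {
  k <- floor(trim_fraction / 2 * length(values))
  s <- sort(as.numeric(values))
  s[(k + 1):(length(s) - k)]
}

#' Derive pre-compensation parameters from mapped field errors
#'
#' The representative B1 scale is the median of the outlier-trimmed B1
#' ROI values and the representative off-resonance the median of the
#' trimmed B0 values; the pre-compensation uses their inverse and value
#' respectively: `A = 1 / median(B1)`, `f = median(B0)` Hz.
#'
#' @param b0_roi [roi_sample] of off-resonance values (Hz).
#' @param b1_roi [roi_sample] of B1 scale values.
#' @param trim_fraction Outlier fraction removed before the median.
#' @return A [precomp_params].
#' @export
derive_precomp <- function(b0_roi, b1_roi, trim_fraction = 0.05) {
  if (!inherits(b0_roi, "roi_sample") || !inherits(b1_roi, "roi_sample"))
    stop("inputs must be roi_sample objects")
  b1_med <- stats::median(trimmed_values(b1_roi$values, trim_fraction))
  if (b1_med <= 0) stop("invalid B1 map: non-positive representative scale")
  f <- stats::median(trimmed_values(b0_roi$values, trim_fraction))
  precomp_params(A = 1 / b1_med, f = f)
}

#' Time-velocity curve from cine phase-contrast flow imaging
#'
#' @param time Sample times in ms post ECG trigger, uniformly spaced and
#'   increasing (>= 5 samples).
#' @param velocity Velocities in cm/s.
#' @return Object of class `flow_curve`.
#' @export
flow_curve <- function(time, velocity) {
  if (length(time) < 5L) stop("flow curve needs at least 5 samples")
  if (length(time) != length(velocity))
    stop("time and velocity must have the same length")
  d <- diff(time)
  if (any(d <= 0)) stop("times must be increasing")
  if (max(d) - min(d) > 1e-6 * stats::median(d))
    stop("times must be uniformly spaced")
  structure(list(time = as.numeric(time), velocity = as.numeric(velocity)),
            class = "flow_curve")
}

#' Read a flow curve from CSV
#'
#' Expects columns `time_ms` and `velocity_cm_s`.
#'
#' @param path File path.
#' @return A [flow_curve].
#' @export
read_flow_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "velocity_cm_s") %in% names(df)))
    stop("flow curve CSV must have columns time_ms, velocity_cm_s")
  flow_curve(df$time_ms, df$velocity_cm_s)
}

#' Detect systolic timing on a flow curve
#'
#' The systolic peak is the time of maximum velocity. The onset is the
#' earliest time at which the velocity exceeds
#' `baseline + onset_threshold * (peak - baseline)`, where the baseline is
#' the pre-upstroke minimum (the minimum velocity at or before the peak),
#' with linear interpolation between samples.
#'
#' @param curve A [flow_curve].
#' @param onset_threshold Fraction of the upstroke height defining the
#'   onset crossing (default 0.1).
#' @param min_upstroke Minimum peak-minus-baseline (cm/s) below which the
#'   curve is declared flat.
#' @return Object of class `systole_timing` with `onset` (ms), `peak`
#'   (ms) and `peak_velocity` (cm/s).
#' @export
detect_systole <- function(curve, onset_threshold = 0.1,
                           min_upstroke = 1e-3) {
  if (!inherits(curve, "flow_curve")) stop("curve must be a flow_curve")
  t <- curve$time; v <- curve$velocity
  ip <- which.max(v)
  ib <- which.min(v[seq_len(ip)])
  baseline <- v[ib]
  if (v[ip] - baseline < min_upstroke)
    stop("no systole detected: flat flow curve")
  thr <- baseline + onset_threshold * (v[ip] - baseline)
  onset <- NA_real_
  for (i in seq(ib, ip - 1L)) {
    if (v[i] <= thr && v[i + 1L] > thr) {
      onset <- t[i] + (t[i + 1L] - t[i]) * (thr - v[i]) / (v[i + 1L] - v[i])
      break
    }
  }
  if (is.na(onset)) onset <- t[ib]
  structure(list(onset = onset, peak = t[ip], peak_velocity = v[ip]),
            class = "systole_timing")
}

#' @export
print.systole_timing <- function(x, ...) {
  cat(sprintf("systole: onset %.2f ms, peak %.2f ms (%.2f cm/s)\n",
              x$onset, x$peak, x$peak_velocity))
  invisible(x)
}

#' ECG trigger delays from systolic timing
#'
#' The slab-selective inversion is synchronised to the onset of systolic
#' flow and the VS saturation to its peak: `TD_ss = onset - lead_ss` and
#' `TD_vs = peak - lead_vs`, each rounded half-up to the nearest
#' `round_to` ms. Negative results clamp to zero with a warning.
#'
#' @param timing A [systole_timing] (or list with `onset`, `peak` in ms).
#' @param lead_ss Lead of the inversion before flow onset, ms.
#' @param lead_vs Lead of the VS pulse before peak flow, ms.
#' @param round_to Rounding granularity, ms.
#' @return Named numeric vector `c(TD_ss, TD_vs)` in ms.
#' @export
derive_trigger_delays <- function(timing, lead_ss = 20, lead_vs = 15,
                                  round_to = 10) {
  if (is.null(timing$onset) || is.null(timing$peak))
    stop("timing must provide onset and peak")
  if (timing$onset >= timing$peak) stop("onset must precede peak")
  half_up <- function(x) floor(x / round_to + 0.5) * round_to
  td <- c(TD_ss = half_up(timing$onset - lead_ss),
          TD_vs = half_up(timing$peak - lead_vs))
  if (any(td < 0)) {
    warning("negative trigger delay clamped to 0")
    td[td < 0] <- 0
  }
  td
}

#' Write a protocol card
#'
#' Serialises derived protocol parameters (trigger delays,
#' pre-compensation values, pulse design parameters) as JSON.
#'
#' @param params Named list.
#' @param path Output path.
#' @export
write_protocol_card <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
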