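#' RF waveform on a uniform time grid
#'
#' An RF waveform is a vector of complex nutation-rate samples (Hz) on a
#' uniform grid of step `dt` milliseconds. The modulus of a sample is the
#' instantaneous nutation rate gamma*B1/(2*pi); its argument is the RF phase
#' in radians.
#'
#' @param samples Complex (or numeric) vector of nutation samples in Hz.
#' @param dt Time step in ms (> 0).
#' @return An object of class `rf_waveform` with fields `samples` and `dt`.
#' @export
rf_waveform <- function(samples, dt) {
  samples <- as.complex(samples)
  if (length(samples) < 1L || any(!is.finite(Re(samples))) ||
      any(!is.finite(Im(samples))))
    stop("RF samples must be finite and non-empty")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive scalar (ms)")
  structure(list(samples = samples, dt = dt), class = "rf_waveform")
}

#' Gradient waveform paired with an RF waveform
#'
#' Gradient samples in mT/m on the same time grid as the paired RF. The
#' zeroth and first moments (`m0`, area in mT*ms/m; `m1` in mT*ms^2/m,
#' taken about t = 0 with sample-centre timing) are computed on
#' construction.
#'
#' @param samples Numeric vector, mT/m.
#' @param dt Time step in ms.
#' @param axis Gradient axis, one of `"x"`, `"y"`, `"z"`.
#' @return An object of class `gradient_waveform` with fields `samples`,
#'   `dt`, `axis`, `m0`, `m1`.
#' @export
gradient_waveform <- function(samples, dt, axis = "z") {
  if (!is.numeric(samples) || length(samples) < 1L || any(!is.finite(samples)))
    stop("gradient samples must be finite and non-empty")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive scalar (ms)")
  axis <- match.arg(axis, c("x", "y", "z"))
  tmid <- (seq_along(samples) - 0.5) * dt
  structure(list(samples = as.numeric(samples), dt = dt, axis = axis,
                 m0 = sum(samples) * dt,
                 m1 = sum(samples * tmid) * dt),
            class = "gradient_waveform")
}

#' @export
print.rf_waveform <- function(x, ...) {
  cat(sprintf("RF waveform: %d samples, dt = %g ms, duration = %g ms, peak = %.1f Hz\n",
              length(x$samples), x$dt, length(x$samples) * x$dt,
              max(Mod(x$samples))))
  invisible(x)
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("Gradient waveform (%s): %d samples, dt = %g ms, peak = %.2f mT/m, m0 = %.3f mT*ms/m, m1 = %.3f mT*ms^2/m\n",
              x$axis, length(x$samples), x$dt, max(abs(x$samples)), x$m0, x$m1))
  invisible(x)
}

check_paired <- function(rf, grad) {
  if (length(rf$samples) != length(grad$samples))
    stop("RF and gradient waveforms must have the same number of samples")
  if (abs(rf$dt - grad$dt) > 1e-12)
    stop("RF and gradient waveforms must share the same time step")
  invisible(TRUE)
}

#' Write a pulse (RF + gradient) as delimited text
#'
#' Columns: time (ms, sample centres), RF real (Hz), RF imaginary (Hz),
#' gradient (mT/m). Comma-separated with a header line.
#'
#' @param rf An [rf_waveform].
#' @param grad A [gradient_waveform] on the same grid.
#' @param path Output file path.
#' @export
write_waveform <- function(rf, grad, path) {
  check_paired(rf, grad)
  tmid <- (seq_along(rf$samples) - 0.5) * rf$dt
  df <- data.frame(time_ms = tmid,
                   rf_real_hz = Re(rf$samples),
                   rf_imag_hz = Im(rf$samples),
                   grad_mt_m = grad$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pulse written by [write_waveform()]
#'
#' @param path File path.
#' @param axis Gradient axis label to attach.
#' @return List with elements `rf` and `grad`.
#' @export
read_waveform <- function(path, axis = "z") {
  df <- utils::read.csv(path)
  need <- c("time_ms", "rf_real_hz", "rf_imag_hz", "grad_mt_m")
  if (!all(need %in% names(df)))
    stop("waveform file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) < 2L) {
    dt <- 2 * df$time_ms[1]
  } else {
    dt <- stats::median(diff(df$time_ms))
  }
  list(rf = rf_waveform(complex(real = df$rf_real_hz,
                                imaginary = df$rf_imag_hz), dt),
       grad = gradient_waveform(df$grad_mt_m, dt, axis))
}
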