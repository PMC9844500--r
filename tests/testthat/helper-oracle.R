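# Independent brute-force oracle: propagates an isochromat by an explicit
# product of per-sample 3x3 rotation matrices (plus diagonal relaxation),
# sharing only the physical conventions with the package implementation.

oracle_rotmat <- function(axis, angle) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)   # K %*% M = n x M
  diag(3) * cos(angle) - K * sin(angle) +
    (1 - cos(angle)) * (n %o% n)
}

oracle_simulate <- function(rf, grad, spin, relaxation = FALSE) {
  M <- spin$M
  dt <- rf$dt
  gb <- vsmra::gamma_bar()
  for (i in seq_along(rf$samples)) {
    tmid <- (i - 0.5) * dt
    x <- spin$position + spin$velocity * 0.01 * tmid
    f <- c(spin$b1_scale * Re(rf$samples[i]),
           spin$b1_scale * Im(rf$samples[i]),
           spin$off_resonance + gb * grad$samples[i] * x)
    fn <- sqrt(sum(f^2))
    if (fn > 0) M <- oracle_rotmat(f, 2 * pi * fn * dt * 1e-3) %*% M
    if (relaxation) {
      E2 <- exp(-dt / spin$T2); E1 <- exp(-dt / spin$T1)
      M <- c(M[1] * E2, M[2] * E2, M[3] * E1 + (1 - E1))
    }
  }
  as.numeric(M)
}

random_waveform_pair <- function(n = 20, dt = 0.1) {
  rf <- rf_waveform(complex(real = stats::rnorm(n, 0, 300),
                            imaginary = stats::rnorm(n, 0, 300)), dt)
  gr <- gradient_waveform(stats::rnorm(n, 0, 10), dt)
  list(rf = rf, grad = gr)
}

# slice out one velocity-encoding interval (everything between the ends of
# two consecutive sub-pulses) of a designed VS pulse
vs_interval_slice <- function(pulse) {
  m <- pulse$meta
  n_sub_samp <- round(m$sub_pulse_dur / m$dt)
  n_int_samp <- 2 * round(m$grad_lobe_dur / m$dt) + 2 * round(4 * m$t90 / m$dt)
  idx <- n_sub_samp + seq_len(n_int_samp)
  list(rf = rf_waveform(pulse$rf$samples[idx], m$dt),
       grad = gradient_waveform(pulse$grad$samples[idx], m$dt, "z"),
       meta = m)
}
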