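ref_spec <- vs_pulse_spec(n_sub = 9, flip_total = 100, fov_v = 70)

test_that("VS design meets its flip contract at v = 0 and half-FOV", {
  p <- design_vs_pulse(ref_spec)
  expect_equal(velocity_response(p, 0), cos(100 * pi / 180),
               tolerance = 1e-6)
  # at half the velocity FOV the intervals alternate phase by pi and the
  # train collapses to a single sub-pulse's flip
  expect_equal(velocity_response(p, 35), cos(100 / 9 * pi / 180),
               tolerance = 1e-6)
})

test_that("off-resonant static spins are refocused by ideal refocusing", {
  # lobe - (exact 180y) - lobe - (exact 180y), the idealised interval:
  # the accrued off-resonance and gradient phase must cancel exactly
  p <- design_vs_pulse(ref_spec)
  m <- p$meta
  nlobe <- round(m$grad_lobe_dur / m$dt)
  lobe_rf <- rf_waveform(rep(0 + 0i, nlobe), m$dt)
  lobe_gr <- gradient_waveform(rep(m$grad_amp, nlobe), m$dt, "z")
  for (f0 in c(-400, 123, 400)) {
    M <- c(1, 0, 0)
    for (half in 1:2) {
      s <- isochromat(M = M, position = 2.3, off_resonance = f0)
      M <- simulate_piecewise(lobe_rf, lobe_gr, s)$M
      M <- hard_pulse_rotation(180, pi / 2, M)
    }
    expect_lt(abs(atan2(M[2], M[1])), 1e-6)
  }
})

test_that("per-interval velocity phase is linear with slope 2*pi/fov_v", {
  p <- design_vs_pulse(ref_spec)
  iv <- vs_interval_slice(p)
  vgrid <- seq(-30, 30, by = 5)  # keeps the accrued phase inside (-pi, pi)
  ph <- vapply(vgrid, function(v) {
    out <- simulate_piecewise(iv$rf, iv$grad,
                              isochromat(M = c(1, 0, 0), velocity = v))
    atan2(out$M[2], out$M[1])
  }, numeric(1))
  ph <- ph - ph[vgrid == 0]
  fit <- stats::lm(unwrapped ~ vgrid,
                   data = data.frame(unwrapped = ph, vgrid = vgrid))
  expect_equal(abs(unname(stats::coef(fit)[2])), 2 * pi / 70,
               tolerance = 1e-9)
  expect_lt(max(abs(stats::residuals(fit))), 1e-6)
})

test_that("velocity response is FOV-periodic, symmetric and B1-sensitive", {
  p <- design_vs_pulse(ref_spec)
  v <- seq(-70, 70, by = 3.5)
  mz <- velocity_response(p, v)
  expect_lt(max(abs(mz - velocity_response(p, v + 70))), 1e-6)
  expect_lt(max(abs(mz - rev(mz))), 1e-9)
  # worst measured B1 scale moves Mz(0) well away from the ideal design
  expect_gt(abs(velocity_response(p, 0, b1_scale = 0.57) -
                  velocity_response(p, 0)), 0.1)
})

test_that("cut-off velocity follows the design convention", {
  expect_identical(cutoff_velocity(vs_pulse_spec(n_sub = 9, fov_v = 70)), 3.5)
  expect_identical(cutoff_velocity(vs_pulse_spec(n_sub = 9, fov_v = 140)), 7)
  expect_identical(cutoff_velocity(vs_pulse_spec(n_sub = 4, fov_v = 70)), 7)
  # the Bloch-simulated stop-band half-width is reported separately and is
  # a finite positive velocity inside the first period
  hw <- stopband_halfwidth(design_vs_pulse(ref_spec))
  expect_true(is.finite(hw) && hw > 0 && hw < 35)
})

test_that("doubling the velocity FOV halves the encoding first moment", {
  p1 <- design_vs_pulse(vs_pulse_spec(fov_v = 70))
  p2 <- design_vs_pulse(vs_pulse_spec(fov_v = 140))
  expect_equal(p2$meta$interval_first_moment,
               p1$meta$interval_first_moment / 2, tolerance = 1e-12)
})

test_that("infeasible gradient demands are signalled", {
  expect_error(design_vs_pulse(vs_pulse_spec(grad_max = 5)), "infeasible")
})

test_that("pre-compensation scales amplitude and ramps phase as specified", {
  p <- design_vs_pulse(ref_spec)
  # identity
  expect_equal(precompensate_rf(p$rf, precomp_params(1, 0))$samples,
               p$rf$samples, tolerance = 1e-12)
  # amplitude doubling leaves phases untouched
  r2 <- precompensate_rf(p$rf, precomp_params(2, 0))
  expect_equal(Mod(r2$samples), 2 * Mod(p$rf$samples), tolerance = 1e-12)
  nz <- Mod(p$rf$samples) > 0
  expect_equal(Arg(r2$samples[nz]), Arg(p$rf$samples[nz]), tolerance = 1e-12)
  # the measured station-1 parameters: A = 1/1.15, f = 100 Hz
  rc <- precompensate_rf(p$rf, precomp_params(1 / 1.15, 100))
  expect_equal(Mod(rc$samples), Mod(p$rf$samples) / 1.15, tolerance = 1e-9)
  ramp <- rc$samples[nz] / (p$rf$samples[nz] / 1.15)
  tmid <- ((seq_along(p$rf$samples) - 0.5) * p$rf$dt)[nz]
  dphi <- diff(Arg(ramp))
  dphi <- (dphi + pi) %% (2 * pi) - pi       # wrap each increment
  dphase <- dphi / diff(tmid)                # rad/ms
  expect_equal(abs(dphase), rep(2 * pi * 100 * 1e-3, length(dphase)),
               tolerance = 1e-6)
  expect_error(precomp_params(-1, 0), "positive")
})

test_that("pre-compensation strictly reduces response error at every measured field corner", {
  v <- seq(-35, 35, by = 5)
  ideal <- velocity_response(design_vs_pulse(ref_spec), v)
  for (s in c(0.57, 0.83, 1.17, 1.27)) {
    for (f0 in c(-202.7, 100, 346.9)) {
      raw <- velocity_response(design_vs_pulse(ref_spec), v,
                               off_resonance = f0, b1_scale = s)
      comp <- velocity_response(
        design_vs_pulse(ref_spec, precomp = precomp_params(1 / s, f0)),
        v, off_resonance = f0, b1_scale = s)
      expect_lt(mean(abs(comp - ideal)), mean(abs(raw - ideal)))
    }
  }
})

test_that("shot set shifts the stripe pattern by quarter periods", {
  expect_identical(make_shot_set(ref_spec, 1)[[1]]$rf$samples,
                   design_vs_pulse(ref_spec)$rf$samples)
  shots <- make_shot_set(ref_spec, 4)
  X0 <- shots[[1]]$meta$stripe_period_mm
  x <- seq(0, 2 * X0, by = X0 / 16)
  # a B1 error makes the composites imperfect and the pattern striped
  prof <- lapply(shots, spatial_response, positions = x, b1_scale = 0.8)
  n <- length(x)
  for (k in 1:3) {
    sh <- 4 * k   # k quarter-periods on a period/16 grid
    expect_lt(max(abs(prof[[k + 1]][seq_len(n - sh)] -
                        prof[[1]][seq_len(n - sh) + sh])), 1e-3)
  }
  # the velocity response at the reference position is unchanged
  v <- seq(-35, 35, by = 7)
  ref <- velocity_response(shots[[1]], v)
  for (k in 2:4)
    expect_lt(max(abs(velocity_response(shots[[k]], v) - ref)), 1e-3)
  # averaging the shifted patterns flattens the stripes
  xp <- seq(0, X0, by = X0 / 16)
  profs <- vapply(shots, spatial_response, numeric(length(xp)),
                  positions = xp, b1_scale = 0.8)
  ripple <- function(z) diff(range(z))
  expect_lt(ripple(rowMeans(profs)), min(apply(profs, 2, ripple)))
})
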