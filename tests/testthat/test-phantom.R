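# shared fixtures: reference-design pulses on a small phantom
vs_shots <- make_shot_set(vs_pulse_spec(), 4)
hs_pulse <- design_hs_inversion(hs_pulse_spec(peak_b1 = 298))
small_dim <- c(24, 24, 16)

test_that("phantom generation is deterministic and complete", {
  a <- make_neck_phantom(dim = small_dim, seed = 3)
  b <- make_neck_phantom(dim = small_dim, seed = 3)
  expect_identical(a$labels, b$labels)
  c2 <- make_neck_phantom(dim = small_dim, seed = 4)
  expect_false(identical(a$labels, c2$labels))
  present <- sort(unique(as.integer(a$labels)))
  expect_true(all(a$classes$code %in% present))
  expect_error(make_neck_phantom(tube_radius = 0), "zero-radius")
})

test_that("phantom tissue velocities default to the measured station values", {
  t1 <- tissue_table(1L)
  expect_equal(t1$velocity[t1$name == "artery"], 66.18)
  expect_equal(t1$velocity[t1$name == "vein"], 9.45)
  t2 <- tissue_table(2L)
  expect_equal(t2$velocity[t2$name == "artery"], 46.88)
  expect_equal(t2$velocity[t2$name == "vein"], 18.01)
  expect_true(all(t1$T1 >= t1$T2))
})

test_that("noiseless flow curves carry their landmarks and round-trip", {
  # landmarks on the sampling grid are exact for the triangular shape
  fc <- synth_flow_curve(60, 140, 66, baseline = 10, dt = 20,
                         shape = "triangular")
  expect_equal(fc$velocity[fc$time == 140], 66)
  expect_equal(fc$velocity[fc$time == 60], 10)
  expect_equal(max(fc$velocity), 66)
  # gamma-variate peak value is exact at the peak time
  g <- synth_flow_curve(58.15, 126.32, 66.18, baseline = 10, dt = 0.01)
  expect_equal(max(g$velocity), 66.18, tolerance = 1e-6)
  expect_lt(abs(g$time[which.max(g$velocity)] - 126.32), 0.011)
  # seeded noise is reproducible
  n1 <- synth_flow_curve(60, 140, 66, noise_sd = 2, seed = 9)
  n2 <- synth_flow_curve(60, 140, 66, noise_sd = 2, seed = 9)
  expect_identical(n1$velocity, n2$velocity)
  expect_error(synth_flow_curve(100, 90, 66), "onset < peak")
})

test_that("synthetic field maps span the requested ranges", {
  fm <- synth_field_maps(dim = c(16, 16, 10), seed = 5)
  expect_lt(abs(min(fm$b0) - (-145.3)) / 145.3, 0.01)
  expect_lt(abs(max(fm$b0) - 346.9) / 346.9, 0.01)
  expect_equal(range(fm$b1), c(0.57, 1.17), tolerance = 1e-9)
  const <- synth_field_maps(dim = c(8, 8, 4), b0_range = c(50, 50),
                            b1_range = c(1, 1), seed = 1)
  expect_true(all(const$b0 == 50) && all(const$b1 == 1))
  expect_identical(synth_field_maps(dim = c(8, 8, 4), seed = 2)$b0,
                   synth_field_maps(dim = c(8, 8, 4), seed = 2)$b0)
})

test_that("relative contrast ratio follows its definition", {
  img <- array(0, c(4, 4, 2))
  a <- array(FALSE, dim(img)); m <- array(FALSE, dim(img))
  a[1:2, 1, 1] <- TRUE; m[3:4, 1, 1] <- TRUE
  img[a] <- 1; img[m] <- 0
  expect_equal(relative_cr(img, a, m), 1)
  img[m] <- 1
  expect_equal(relative_cr(img, a, m), 0)
  img[a] <- 0.9; img[m] <- 0.2
  expect_equal(relative_cr(img, a, m), 0.7778, tolerance = 1e-4)
  img[a] <- 0
  expect_error(relative_cr(img, a, m), "undefined CR")
  expect_error(relative_cr(img, array(FALSE, dim(img)), m), "non-empty")
})

test_that("static tissue follows the inversion-recovery-saturation chain", {
  # one cycle, single-trigger timing: invert, recover 100 ms, VS, read out
  ph <- make_neck_phantom(dim = small_dim, seed = 3)
  prot <- protocol_config(TD_ss = 0, TD_vs = 100, TI = 0, same_rr = TRUE)
  img <- simulate_protocol(ph, prot, vs_shots[[1]], hs_pulse, cycles = 1)
  mz <- attr(img, "mz_readout")
  muscle <- phantom_roi(ph, "muscle")
  q <- inversion_profile(hs_pulse, 0)
  w <- velocity_response(vs_shots[[1]], 0)
  chain <- (1 - (1 - q) * exp(-100 / 900)) * w
  expect_equal(mean(mz[muscle]), chain, tolerance = 1e-6)
  # with a perfect inversion this is the (1 - 2 exp(-TI/T1)) cos(100 deg)
  # closed form, approximately +0.137
  expect_lt(abs(chain - (1 - 2 * exp(-100 / 900)) * cos(100 * pi / 180)),
            0.01)
})

test_that("arteries stay bright while veins are suppressed only with SS + VS", {
  for (vein_v in c(9.45, 18.01)) {
    cls <- tissue_table(1L, vein_velocity = vein_v)
    ph <- make_neck_phantom(dim = small_dim, seed = 3, classes = cls)
    art <- phantom_roi(ph, "artery"); vn <- phantom_roi(ph, "vein")
    both <- simulate_protocol(ph, protocol_config(), vs_shots, hs_pulse)
    expect_lt(mean(both[vn]) / mean(both[art]), 0.25)
    vs_only <- simulate_protocol(ph, protocol_config(), vs_shots, NULL)
    expect_gt(mean(vs_only[vn]) / mean(vs_only[art]), 0.25)
    # fresh inflowing arterial blood reads out nearly fully relaxed
    mz <- attr(both, "mz_readout")
    expect_gt(mean(mz[art]), 0.8)
  }
})

test_that("pre-compensation lifts arterial signal in high-offset regions", {
  ph <- make_neck_phantom(dim = small_dim, seed = 3)
  fm <- synth_field_maps(dim = small_dim, seed = 5)
  prot <- protocol_config()
  spec <- vs_pulse_spec()
  art <- phantom_roi(ph, "artery") | phantom_roi(ph, "artery_branch")
  # high-offset arterial voxels: upper quartile of |B0| within the arteries
  hi <- art & abs(fm$b0) > stats::quantile(abs(fm$b0[art]), 0.75)
  expect_gt(sum(hi), 0)
  pc <- derive_precomp(roi_sample(fm$b0[art]), roi_sample(fm$b1[art]))
  img_raw <- simulate_protocol(ph, prot, make_shot_set(spec, 4), hs_pulse,
                               field_maps = fm)
  img_cmp <- simulate_protocol(ph, prot, make_shot_set(spec, 4, precomp = pc),
                               hs_pulse, field_maps = fm)
  expect_gt(mean(img_cmp[hi]), mean(img_raw[hi]))
})

test_that("arterial tubes are contiguous in the maximum intensity projection", {
  ph <- make_neck_phantom(dim = small_dim, seed = 3)
  img <- simulate_protocol(ph, protocol_config(), vs_shots, hs_pulse)
  proj <- mip(img, axis = 2)          # project over y: x-z coronal MIP
  half <- 0.5 * max(proj)
  for (tb in ph$tubes) {
    if (!is.null(tb$cx) && tb$name == "artery") {
      ix <- which.min(abs(ph$coords$x - tb$cx))
      expect_true(all(proj[ix, ] > half))   # no gaps along the tube axis
    }
  }
})

test_that("simulated volumes round-trip through NIfTI", {
  ph <- make_neck_phantom(dim = c(12, 12, 8), seed = 1)
  img <- simulate_protocol(ph, protocol_config(), vs_shots[[1]], NULL)
  f <- tempfile(fileext = ".nii.gz")
  write_image_nifti(img, f)
  back <- RNifti::readNifti(f)
  expect_lt(max(abs(as.array(back) - array(as.numeric(img), dim(img)))),
            1e-6)
  expect_equal(RNifti::pixdim(back), ph$voxel, tolerance = 1e-6)
})
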