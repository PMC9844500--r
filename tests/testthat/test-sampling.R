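test_that("square spiral visits every grid point once, centre-out", {
  expect_equal(square_spiral_order(1, 1),
               cbind(ky = 0L, kz = 0L))
  # 3x3: enumerated expectation, counter-clockwise from (0,0) toward +ky
  expect_equal(square_spiral_order(3, 3),
               cbind(ky = c(0L, 1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
                     kz = c(0L, 0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)))
  for (d in list(c(4, 4), c(5, 4), c(2, 7), c(9, 5), c(12, 12))) {
    p <- square_spiral_order(d[1], d[2])
    expect_equal(nrow(p), prod(d))                 # permutation of the grid
    expect_equal(nrow(unique(p)), prod(d))         # no duplicates
    r <- pmax(abs(p[, "ky"]), abs(p[, "kz"]))
    expect_true(all(diff(r) >= 0))                 # Chebyshev radius grows
    # half-open DC-centred bounds: even sizes put the extra index negative
    lo <- ifelse(d %% 2 == 0, -d / 2, -(d - 1) / 2)
    expect_equal(range(p[, "ky"]), c(lo[1], lo[1] + d[1] - 1))
    expect_equal(range(p[, "kz"]), c(lo[2], lo[2] + d[2] - 1))
  }
})

test_that("full sampling acquires every point in spiral order", {
  s <- build_schedule(trajectory_spec(8, 6, R = 1, calib = 0,
                                      views_per_segment = 10))
  expect_equal(nrow(s$samples), 48)
  expect_equal(s$n_segments, ceiling(48 / 10))
  expect_true(all(s$mask))
})

test_that("the illustrated configuration yields 72 samples in 3 segments", {
  # 12x12 grid, R = 3, 6x6 core, 26 views per segment
  s <- build_schedule(trajectory_spec(12, 12, R = 3, calib = 6,
                                      views_per_segment = 26))
  expect_equal(nrow(s$samples), 36 + (144 - 36) / 3)   # 72
  expect_equal(s$n_segments, 3)
  expect_equal(sum(s$mask), 72)
  # the fully sampled core is entirely acquired
  core <- s$samples$ky >= -3 & s$samples$ky <= 2 &
    s$samples$kz >= -3 & s$samples$kz <= 2
  expect_equal(sum(core), 36)
})

test_that("acquired fraction follows the counting identity", {
  for (cfg in list(c(10, 10, 2, 4), c(16, 12, 3, 6), c(21, 15, 3, 5))) {
    s <- build_schedule(trajectory_spec(cfg[1], cfg[2], R = cfg[3],
                                        calib = cfg[4],
                                        views_per_segment = 20))
    outer_n <- cfg[1] * cfg[2] - cfg[4]^2
    expect_equal(nrow(s$samples), cfg[4]^2 + ceiling(outer_n / cfg[3]))
    expect_false(any(duplicated(s$samples[c("ky", "kz")])))
    # chunked segments reproduce the acquisition order
    expect_equal(s$samples$segment,
                 (seq_len(nrow(s$samples)) - 1) %/% 20 + 1)
    expect_true(all(table(s$samples$segment) <= 20))
  }
})

test_that("centre-out weighting puts DC and the calibration core first", {
  s <- build_schedule(trajectory_spec(240, 71, R = 3, calib = 24,
                                      views_per_segment = 71))
  expect_equal(nrow(s$samples), 576 + ceiling((240 * 71 - 576) / 3))
  dc <- s$samples$ky == 0 & s$samples$kz == 0
  expect_equal(s$samples$segment[dc], 1L)
  core <- s$samples$ky >= -12 & s$samples$ky <= 11 &
    s$samples$kz >= -12 & s$samples$kz <= 11
  expect_equal(sum(core), 576)
  # the 24x24 core sits inside Chebyshev radius 12, whose rings hold at
  # most 25^2 points, so it must be complete within the first
  # ceiling(625 / 71) = 9 of the 86 segments
  expect_lte(max(s$samples$segment[core]), ceiling(25^2 / 71))
})

test_that("the decimation-phase flag changes only the outer region", {
  a <- build_schedule(trajectory_spec(12, 12, R = 3, calib = 6,
                                      views_per_segment = 26))
  b <- build_schedule(trajectory_spec(12, 12, R = 3, calib = 6,
                                      views_per_segment = 26),
                      count_calib_in_phase = TRUE)
  core_mask <- function(s) {
    m <- s$mask
    m[rownames(m) %in% as.character(-3:2),
      colnames(m) %in% as.character(-3:2)]
  }
  expect_true(all(core_mask(a)) && all(core_mask(b)))
  expect_equal(abs(nrow(a$samples) - nrow(b$samples)) <= 1, TRUE)
})

test_that("schedule and mask exports round-trip", {
  s <- build_schedule(trajectory_spec(12, 12, R = 3, calib = 6,
                                      views_per_segment = 26))
  f <- tempfile(fileext = ".csv")
  write_schedule(s, f)
  back <- utils::read.csv(f)
  expect_equal(back$ky, s$samples$ky)
  fm <- tempfile(fileext = ".csv")
  write_mask(s, fm)
  m <- as.matrix(utils::read.csv(fm, header = FALSE))
  expect_equal(sum(m), nrow(s$samples))
})
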