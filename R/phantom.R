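#' Synthetic pulsatile flow curve
#'
#' Generates a time-velocity curve emulating cine phase-contrast
#' measurements in a neck vessel over one cardiac cycle: a baseline
#' (diastolic) velocity, a systolic upstroke beginning at `onset` and
#' peaking at `peak` with velocity `peak_velocity`, and a smooth return
#' to baseline. Optional seeded Gaussian noise.
#'
#' @param onset Systolic onset time, ms post trigger.
#' @param peak Systolic peak time, ms (onset < peak < period).
#' @param peak_velocity Peak velocity, cm/s.
#' @param baseline Diastolic velocity, cm/s.
#' @param period Cardiac period, ms.
#' @param dt Temporal resolution, ms (default matches a 20.05 ms cine).
#' @param shape `"gamma"` (gamma-variate upstroke/decay) or
#'   `"triangular"` (piecewise linear).
#' @param k Gamma-variate sharpness (shape `"gamma"` only).
#' @param noise_sd Standard deviation of additive noise, cm/s.
#' @param seed Optional seed for the noise.
#' @return A [flow_curve].
#' @export
synth_flow_curve <- function(onset = 58.15, peak = 126.32,
                             peak_velocity = 66.18, baseline = 10,
                             period = 857, dt = 20.05,
                             shape = c("gamma", "triangular"), k = 2.5,
                             noise_sd = 0, seed = NULL) {
  shape <- match.arg(shape)
  if (!(onset < peak && peak < period))
    stop("need onset < peak < period")
  t <- seq(0, period, by = dt)
  amp <- peak_velocity - baseline
  if (shape == "gamma") {
    r <- pmax(0, (t - onset) / (peak - onset))
    v <- baseline + amp * r^k * exp(k * (1 - r))
  } else {
    fall_end <- min(period, peak + 1.5 * (peak - onset))
    v <- rep(baseline, length(t))
    up <- t >= onset & t <= peak
    v[up] <- baseline + amp * (t[up] - onset) / (peak - onset)
    dn <- t > peak & t < fall_end
    v[dn] <- baseline + amp * (fall_end - t[dn]) / (fall_end - peak)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  flow_curve(t, v)
}

#' Tissue class table of the digital neck phantom
#'
#' Relaxation times, relative proton densities and velocity models of the
#' phantom's tissue classes at 3 T (literature conventions; the package
#' exposes them all as arguments). Arterial classes reference the
#' station's pulsatile flow curve; veins carry the station's measured
#' constant velocity; static tissues have velocity zero. The `inflow`
#' flag marks classes whose upstream spins enter the imaging volume from
#' below the inversion slab and therefore arrive uninverted and fully
#' relaxed.
#'
#' @param station 1 (inferior volume) or 2 (superior volume); selects the
#'   measured arterial/venous velocities and systolic timings.
#' @param blood_t1,blood_t2,muscle_t1,muscle_t2,fat_t1,fat_t2 Relaxation
#'   times, ms.
#' @param artery_peak_velocity,vein_velocity Velocities in cm/s; defaults
#'   are the station's measured values (66.18/46.88 arterial peak,
#'   9.45/18.01 venous).
#' @param branch_velocity_scale Fraction of the arterial velocity
#'   assigned to the horizontal (subclavian-like) branch along the
#'   velocity-encoding axis.
#' @return Data frame with one row per class.
#' @export
tissue_table <- function(station = 1L,
                         blood_t1 = 1650, blood_t2 = 150,
                         muscle_t1 = 900, muscle_t2 = 50,
                         fat_t1 = 370, fat_t2 = 130,
                         artery_peak_velocity = NULL,
                         vein_velocity = NULL,
                         branch_velocity_scale = 0.7) {
  if (!station %in% c(1L, 2L)) stop("station must be 1 or 2")
  if (is.null(artery_peak_velocity))
    artery_peak_velocity <- if (station == 1L) 66.18 else 46.88
  if (is.null(vein_velocity))
    vein_velocity <- if (station == 1L) 9.45 else 18.01
  data.frame(
    name = c("background", "artery", "artery_branch", "vein", "muscle", "fat"),
    code = 0:5,
    T1 = c(Inf, blood_t1, blood_t1, blood_t1, muscle_t1, fat_t1),
    T2 = c(Inf, blood_t2, blood_t2, blood_t2, muscle_t2, fat_t2),
    pd = c(0, 1, 1, 1, 0.75, 0.9),
    velocity = c(0, artery_peak_velocity,
                 artery_peak_velocity * branch_velocity_scale,
                 vein_velocity, 0, 0),
    pulsatile = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    inflow = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    fat_sat = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Digital neck phantom
#'
#' Builds a labelled 3D volume emulating a neck station: an elliptical
#' muscle body with a thin fat rim, two vertical (S-I) arterial trunks,
#' one horizontal arterial branch emulating a subclavian artery, two
#' vertical jugular-like veins, and air background. Tube centres are
#' jittered deterministically from `seed`.
#'
#' @param dim Integer length-3 voxel grid (x, y, z), z being S-I.
#' @param voxel Voxel size in mm (scalar or length 3).
#' @param station 1 or 2; forwarded to [tissue_table()].
#' @param tube_radius Vessel radius, mm.
#' @param jitter_mm Maximum centre jitter, mm.
#' @param seed Integer seed (the phantom is deterministic given it).
#' @param classes Optional replacement for [tissue_table()].
#' @return Object of class `neck_phantom`: list with `labels` (integer
#'   array), `classes` (tissue table), `voxel` (mm), `coords` (list of
#'   axis coordinate vectors, mm, z centred on the volume), `station`,
#'   and `tubes` (per-tube geometry for downstream checks).
#' @export
make_neck_phantom <- function(dim = c(40, 40, 32), voxel = 3,
                              station = 1L, tube_radius = 4.5,
                              jitter_mm = 1.5, seed = 1L,
                              classes = NULL) {
  if (tube_radius <= 0) stop("invalid params: zero-radius tube")
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 8L)) stop("dim must be 3 sizes >= 8")
  voxel <- rep_len(voxel, 3L)
  if (is.null(classes)) classes <- tissue_table(station)
  set.seed(seed)
  ext <- dim * voxel
  xc <- (seq_len(dim[1]) - 0.5) * voxel[1] - ext[1] / 2
  yc <- (seq_len(dim[2]) - 0.5) * voxel[2] - ext[2] / 2
  zc <- (seq_len(dim[3]) - 0.5) * voxel[3] - ext[3] / 2
  lab <- array(0L, dim)
  code <- function(nm) classes$code[classes$name == nm]

  # muscle body: elliptical cylinder filling most of the field of view
  a <- 0.44 * ext[1]; b <- 0.42 * ext[2]
  X <- outer(xc, yc, function(x, y) (x / a)^2 + (y / b)^2)
  body <- X <= 1
  rim <- X <= 1 & X > 0.82
  for (k in seq_len(dim[3])) {
    sl <- lab[, , k]
    sl[body] <- code("muscle")
    sl[rim] <- code("fat")
    lab[, , k] <- sl
  }

  jit <- function() stats::runif(1, -jitter_mm, jitter_mm)
  tubes <- list(
    list(name = "artery", cx = -0.20 * ext[1] + jit(), cy = 0.08 * ext[2] + jit()),
    list(name = "artery", cx = 0.20 * ext[1] + jit(), cy = 0.08 * ext[2] + jit()),
    list(name = "vein", cx = -0.30 * ext[1] + jit(), cy = -0.05 * ext[2] + jit()),
    list(name = "vein", cx = 0.30 * ext[1] + jit(), cy = -0.05 * ext[2] + jit()))
  for (tb in tubes) {
    iy <- which((outer(xc, yc, function(x, y)
      (x - tb$cx)^2 + (y - tb$cy)^2)) <= tube_radius^2, arr.ind = TRUE)
    for (k in seq_len(dim[3]))
      lab[cbind(iy, k)] <- code(tb$name)
  }
  # horizontal arterial branch (subclavian-like): along x in a low slice
  bz <- max(2L, round(dim[3] * 0.12))
  by <- round(dim[2] * 0.35)
  rad_vox <- max(1L, round(tube_radius / voxel[2]))
  branch_x <- seq(round(dim[1] * 0.18), round(dim[1] * 0.82))
  for (ix in branch_x)
    for (jy in (by - rad_vox):(by + rad_vox))
      for (kz in (bz - rad_vox + 1L):(bz + rad_vox - 1L))
        if (jy >= 1 && jy <= dim[2] && kz >= 1 && kz <= dim[3])
          lab[ix, jy, kz] <- code("artery_branch")

  tubes <- c(tubes, list(list(name = "artery_branch", z_index = bz,
                              y_index = by, x_range = range(branch_x))))
  structure(list(labels = lab, classes = classes, voxel = voxel,
                 coords = list(x = xc, y = yc, z = zc),
                 station = as.integer(station), seed = seed,
                 tubes = tubes),
            class = "neck_phantom")
}

#' @export
print.neck_phantom <- function(x, ...) {
  cat(sprintf("neck phantom: %s voxels of %s mm, station %d\n",
              paste(dim(x$labels), collapse = " x "),
              paste(signif(x$voxel, 3), collapse = " x "), x$station))
  tab <- table(factor(x$labels, levels = x$classes$code,
                      labels = x$classes$name))
  print(tab)
  invisible(x)
}

#' Logical mask of one phantom tissue class
#'
#' @param phantom A `neck_phantom`.
#' @param class_name Tissue class name.
#' @return Logical array matching the label volume.
#' @export
phantom_roi <- function(phantom, class_name) {
  code <- phantom$classes$code[phantom$classes$name == class_name]
  if (length(code) != 1L) stop("unknown tissue class: ", class_name)
  phantom$labels == code
}

#' Synthetic smooth B0 and B1 field maps
#'
#' Low-order random polynomial fields over the volume, rescaled affinely
#' so their sample minimum and maximum equal the requested ranges
#' exactly. Deterministic for a fixed seed.
#'
#' @param dim Length-3 voxel grid.
#' @param b0_range Off-resonance range, Hz (default: measured station-1
#'   range).
#' @param b1_range B1 scale range (default: measured station-1 range).
#' @param order Polynomial order (1 or 2).
#' @param seed Integer seed.
#' @return List with arrays `b0` (Hz) and `b1` (scale).
#' @export
synth_field_maps <- function(dim = c(40, 40, 32),
                             b0_range = c(-145.3, 346.9),
                             b1_range = c(0.57, 1.17),
                             order = 2, seed = 1L) {
  dim <- as.integer(dim)
  set.seed(seed)
  u <- list(seq(-1, 1, length.out = dim[1]),
            seq(-1, 1, length.out = dim[2]),
            seq(-1, 1, length.out = dim[3]))
  poly_field <- function() {
    f <- array(0, dim)
    terms <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
    terms <- terms[rowSums(terms) <= order & rowSums(terms) > 0, ]
    for (r in seq_len(nrow(terms))) {
      cf <- stats::rnorm(1)
      f <- f + cf * outer(outer(u[[1]]^terms$i[r], u[[2]]^terms$j[r]),
                          u[[3]]^terms$k[r])
    }
    f
  }
  rescale <- function(f, rng) {
    lo <- min(f); hi <- max(f)
    if (diff(range(rng)) == 0) return(array(rng[1], dim))
    if (hi - lo < 1e-12) return(array(mean(rng), dim))
    rng[1] + (f - lo) / (hi - lo) * (rng[2] - rng[1])
  }
  list(b0 = rescale(poly_field(), b0_range),
       b1 = rescale(poly_field(), b1_range))
}
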