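#' Specification of the segmented square-spiral trajectory
#'
#' Phase/partition-encode (ky-kz) ordering parameters: grid size,
#' acceleration factor of the outer region, fully sampled self-calibration
#' core size and the number of views acquired per segmented acquisition.
#'
#' @param ny,nz Grid sizes (>= 1).
#' @param R Acceleration factor of the outer region (>= 1).
#' @param calib Side length of the fully sampled square core
#'   (<= min(ny, nz); 0 disables it).
#' @param views_per_segment Views per segmented acquisition (>= 1).
#' @return Object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(ny, nz, R = 3, calib = 24,
                            views_per_segment = 71) {
  if (ny < 1 || nz < 1) stop("grid sizes must be at least 1")
  if (R < 1) stop("acceleration factor must be at least 1")
  if (calib < 0 || calib > min(ny, nz))
    stop("calib core must fit inside the grid")
  if (views_per_segment < 1) stop("views_per_segment must be at least 1")
  structure(list(ny = as.integer(ny), nz = as.integer(nz),
                 R = as.integer(R), calib = as.integer(calib),
                 views_per_segment = as.integer(views_per_segment)),
            class = "trajectory_spec")
}

# DC-centred index bounds with the half-open convention: for even n the
# negative side gets the extra index, i.e. -n/2 .. n/2 - 1.
grid_bounds <- function(n) {
  lo <- -ceiling(n / 2)
  if (n %% 2L == 1L) lo <- -(n - 1L) %/% 2L
  c(lo, lo + n - 1L)
}

#' Center-out square-spiral ordering of a ky-kz grid
#'
#' Visits every point of the DC-centred `ny x nz` grid exactly once,
#' starting at the origin and expanding outward ring by ring (the
#' Chebyshev radius `max(|ky|, |kz|)` is non-decreasing along the path).
#' Each ring is traversed counter-clockwise starting toward +ky. Grid
#' indices use the half-open convention: for even sizes the negative side
#' carries the extra index.
#'
#' @param ny,nz Grid sizes.
#' @return Integer matrix with columns `ky`, `kz`, one row per point, in
#'   visit order.
#' @export
square_spiral_order <- function(ny, nz) {
  by <- grid_bounds(ny); bz <- grid_bounds(nz)
  rmax <- max(abs(by), abs(bz))
  total <- ny * nz
  ky <- integer(total); kz <- integer(total)
  cnt <- 0L
  push <- function(y, z) {
    if (y >= by[1] && y <= by[2] && z >= bz[1] && z <= bz[2]) {
      cnt <<- cnt + 1L
      ky[cnt] <<- y; kz[cnt] <<- z
    }
  }
  push(0L, 0L)
  r <- 0L
  while (cnt < total && r < rmax) {
    r <- r + 1L
    # CCW starting toward +ky: enter ring at (r, 0)
    for (z in 0:r) push(r, z)                       # up the right edge
    if (r >= 1L) for (y in (r - 1L):(-r)) push(y, r)    # along the top
    for (z in (r - 1L):(-r)) push(-r, z)            # down the left edge
    for (y in (-r + 1L):r) push(y, -r)              # along the bottom
    if (r >= 2L) for (z in (-r + 1L):(-1L)) push(r, z)  # close the ring
  }
  cbind(ky = ky[seq_len(cnt)], kz = kz[seq_len(cnt)])
}

#' Build the under-sampled segmented acquisition schedule
#'
#' Walks the square-spiral order of the full grid, acquiring every point
#' inside the fully sampled calibration core and every `R`-th visited
#' point outside it, then chunks the acquired sequence into consecutive
#' segments of `views_per_segment` views. Because the walk is center-out,
#' early segments carry the centre of k-space along both ky and kz.
#'
#' @param spec A [trajectory_spec].
#' @param count_calib_in_phase Logical; if `TRUE` the decimation counter
#'   of the outer region also advances while walking through calibration
#'   points (the acquired set is unchanged in size inside the core either
#'   way; only the phase of the outer decimation differs).
#' @return Object of class `acquisition_schedule`: list with `samples`
#'   (data frame: `order`, `ky`, `kz`, `segment`), `mask` (ny x nz
#'   logical matrix, row/col names giving the DC-centred indices),
#'   `n_segments`, and the originating `spec`.
#' @export
build_schedule <- function(spec, count_calib_in_phase = FALSE) {
  if (!inherits(spec, "trajectory_spec")) stop("spec must be a trajectory_spec")
  path <- square_spiral_order(spec$ny, spec$nz)
  if (spec$calib > 0L) {
    cy <- grid_bounds(spec$calib); cz <- grid_bounds(spec$calib)
    in_core <- path[, "ky"] >= cy[1] & path[, "ky"] <= cy[2] &
      path[, "kz"] >= cz[1] & path[, "kz"] <= cz[2]
  } else {
    in_core <- rep(FALSE, nrow(path))
  }
  counter <- if (count_calib_in_phase) seq_len(nrow(path)) - 1L else {
    cumsum(!in_core) - 1L   # 0-based index among outer points
  }
  acquired <- in_core | (!in_core & counter %% spec$R == 0L)
  acq <- path[acquired, , drop = FALSE]
  n <- nrow(acq)
  seg <- (seq_len(n) - 1L) %/% spec$views_per_segment + 1L
  by <- grid_bounds(spec$ny); bz <- grid_bounds(spec$nz)
  mask <- matrix(FALSE, spec$ny, spec$nz,
                 dimnames = list(ky = by[1]:by[2], kz = bz[1]:bz[2]))
  mask[cbind(acq[, "ky"] - by[1] + 1L, acq[, "kz"] - bz[1] + 1L)] <- TRUE
  structure(list(samples = data.frame(order = seq_len(n),
                                      ky = acq[, "ky"], kz = acq[, "kz"],
                                      segment = seg),
                 mask = mask,
                 n_segments = max(seg),
                 spec = spec),
            class = "acquisition_schedule")
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  s <- x$spec
  cat(sprintf("acquisition schedule: %d x %d grid, R = %d, calib %d, %d acquired (%.1f%%), %d segments of <= %d views\n",
              s$ny, s$nz, s$R, s$calib, nrow(x$samples),
              100 * nrow(x$samples) / (s$ny * s$nz),
              x$n_segments, s$views_per_segment))
  invisible(x)
}

#' Export a schedule as CSV
#'
#' Columns: `order`, `ky`, `kz`, `segment`.
#'
#' @param schedule An `acquisition_schedule`.
#' @param path Output path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule$samples, path, row.names = FALSE)
  invisible(path)
}

#' Export a sampling mask
#'
#' Writes the binary ky-kz mask as CSV (0/1 matrix) and optionally as PNG
#' (requires the `png` package).
#'
#' @param schedule An `acquisition_schedule`.
#' @param path Output path; extension `.png` selects image output.
#' @export
write_mask <- function(schedule, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG export requires the png package")
    png::writePNG(t(schedule$mask[, rev(seq_len(ncol(schedule$mask)))]) * 1,
                  path)
  } else {
    utils::write.table(schedule$mask * 1L, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
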