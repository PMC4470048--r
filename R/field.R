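#' Time-resolved three-component velocity field
#'
#' The core container of the package: a periodic, time-resolved,
#' three-component velocity volume as produced by a 4D flow
#' phase-contrast CMR reconstruction. Velocities are stored in cm/s on a
#' regular grid with the voxel-center convention: the world position
#' (mm) of voxel `(x = i, y = j, z = k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`. Time is periodic with period
#' `nt * timeframe_duration` ms; the time of frame `t` is
#' `(t - 1) * timeframe_duration`.
#'
#' @param velocities numeric 5-d array, dim `(nt, nz, ny, nx, 3)`, cm/s.
#'   Component order is (vx, vy, vz) in world axes.
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm.
#' @param timeframe_duration duration of one timeframe in ms
#'   (cycle length / nt).
#' @param venc velocity-encoding limit in cm/s. Stored velocities may
#'   exceed `venc` in magnitude only after phase unwrapping.
#' @param origin world position (mm) of the center of voxel (1,1,1).
#' @return An object of class `velocity_field`.
#' @seealso [sample_velocity()], [trace()], [read_dataset()]
#' @export
velocity_field <- function(velocities, spacing, timeframe_duration, venc,
                           origin = c(0, 0, 0)) {
  d <- dim(velocities)
  if (is.null(d) || length(d) != 5L || d[5] != 3L)
    stop("`velocities` must be a 5-d array with dim (nt, nz, ny, nx, 3)")
  if (d[1] < 2L) stop("need at least 2 timeframes, got ", d[1])
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel edge lengths in mm")
  if (!is.numeric(timeframe_duration) || timeframe_duration <= 0)
    stop("`timeframe_duration` must be a positive duration in ms")
  if (!is.numeric(venc) || venc <= 0)
    stop("`venc` must be a positive velocity in cm/s")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must be a length-3 world position in mm")
  storage.mode(velocities) <- "double"
  structure(
    list(velocities = velocities, spacing = spacing,
         timeframe_duration = as.numeric(timeframe_duration),
         venc = as.numeric(venc), origin = origin),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$velocities)
  cat(sprintf(
    "<velocity_field> %d frames, grid %d x %d x %d (x,y,z), spacing %s mm\n",
    d[1], d[4], d[3], d[2],
    paste(format(x$spacing, trim = TRUE), collapse = " x ")))
  cat(sprintf("  timeframe %.3g ms (cycle %.4g ms), VENC %.4g cm/s, voxel %.4g mm^3\n",
              x$timeframe_duration, cycle_length(x), x$venc, voxel_volume(x)))
  invisible(x)
}

#' Number of timeframes of a velocity field
#' @param field a [velocity_field()]
#' @export
n_timeframes <- function(field) dim(field$velocities)[1]

#' Cardiac cycle length (ms) of a velocity field
#' @param field a [velocity_field()]
#' @export
cycle_length <- function(field) n_timeframes(field) * field$timeframe_duration

#' Voxel volume (mm^3) of a velocity field
#'
#' Product of the three voxel edge lengths; e.g. 27 mm^3 for the typical
#' 3 x 3 x 3 mm acquisition.
#' @param field a [velocity_field()]
#' @export
voxel_volume <- function(field) prod(field$spacing)

#' Times (ms) of the timeframe centers
#' @param field a [velocity_field()]
#' @export
frame_times <- function(field)
  (seq_len(n_timeframes(field)) - 1) * field$timeframe_duration

# grid dims as (nx, ny, nz)
grid_shape <- function(field) dim(field$velocities)[c(4, 3, 2)]

#' World coordinates (mm) of all voxel centers
#'
#' Returns the voxel-center positions of a 3D grid, ordered to match
#' `which(mask)` on an array of dim `(nz, ny, nx)`.
#'
#' @param field a [velocity_field()]
#' @param mask optional logical array of dim `(nz, ny, nx)`; only centers
#'   of `TRUE` voxels are returned.
#' @return n x 3 matrix of world positions (x, y, z) in mm.
#' @export
voxel_centers <- function(field, mask = NULL) {
  d <- dim(field$velocities)
  nz <- d[2]; ny <- d[3]; nx <- d[4]
  if (is.null(mask)) {
    idx <- as.matrix(expand.grid(z = seq_len(nz), y = seq_len(ny),
                                 x = seq_len(nx)))
  } else {
    if (!identical(dim(mask), c(nz, ny, nx)))
      stop("mask dim ", paste(dim(mask), collapse = "x"),
           " does not match grid ", paste(c(nz, ny, nx), collapse = "x"))
    idx <- which(mask, arr.ind = TRUE)
    colnames(idx) <- c("z", "y", "x")
    if (nrow(idx) == 0L) return(matrix(numeric(0), 0, 3))
  }
  cbind(field$origin[1] + (idx[, "x"] - 1) * field$spacing[1],
        field$origin[2] + (idx[, "y"] - 1) * field$spacing[2],
        field$origin[3] + (idx[, "z"] - 1) * field$spacing[3])
}
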