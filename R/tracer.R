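#' Sample a velocity field at arbitrary positions and times
#'
#' Trilinear interpolation in space between the eight surrounding voxel
#' centers and linear interpolation in time between the two surrounding
#' timeframes, with periodic wrap between the last and first frame.
#' Positions outside the voxel-center bounding box return `NA` rows
#' (the sentinel consumed by the tracer).
#'
#' @param field a [velocity_field()].
#' @param pos n x 3 matrix (or length-3 vector) of world positions, mm.
#' @param time time(s) in ms, length 1 or n; mapped into the cycle by
#'   periodic wrap.
#' @param units `"mm_ms"` (default, the tracer's unit; 1 mm/ms = 100
#'   cm/s) or `"cm_s"`.
#' @return n x 3 matrix of velocities.
#' @export
sample_velocity <- function(field, pos, time, units = c("mm_ms", "cm_s")) {
  units <- match.arg(units)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  out <- sample_velocity_cpp(field$velocities,
                             as.integer(dim(field$velocities)),
                             field$spacing, field$origin,
                             field$timeframe_duration, pos,
                             as.numeric(time))
  if (units == "cm_s") out <- out * 100
  colnames(out) <- c("vx", "vy", "vz")
  out
}

#' Particle-trace integration configuration
#'
#' @param t_start,t_end start and end times within the cycle, ms; must
#'   differ modulo the cycle. For `direction = "backward"` the
#'   integration runs from `t_start` backward (decreasing time, wrapping
#'   across the cycle seam) until it reaches `t_end`.
#' @param timestep constant integration step, ms (default 5).
#' @param direction `"forward"` or `"backward"`.
#' @param record_trajectories keep positions at every step (needed for
#'   export/visualization; final positions suffice for volumetry).
#' @export
integration_config <- function(t_start, t_end, timestep = 5,
                               direction = c("forward", "backward"),
                               record_trajectories = FALSE) {
  direction <- match.arg(direction)
  if (!is.numeric(timestep) || timestep <= 0)
    stop("`timestep` must be a positive duration in ms")
  structure(list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                 timestep = as.numeric(timestep), direction = direction,
                 record_trajectories = isTRUE(record_trajectories)),
            class = "integration_config")
}

#' Trace particles through a velocity field
#'
#' Classic fourth-order Runge-Kutta integration with a constant
#' timestep, the final partial step shortened so trajectories end
#' exactly at `t_end`. The velocity is sampled from the measured field
#' everywhere (masks play no role here). A particle whose update leaves
#' the grid is frozen at its last in-grid position and flagged
#' `left_grid`, so carried volume is conserved and fates stay auditable.
#'
#' @param field a [velocity_field()].
#' @param seeds n x 3 matrix of seed positions, world mm.
#' @param cfg an [integration_config()].
#' @return A `particle_set`: list with `seeds`, `positions` (final),
#'   `status` (factor active/left_grid), `carried_volume` (mm^3 per
#'   particle, the source voxel volume), `times`, `trajectories`
#'   (array steps+1 x n x 3 when recorded) and the config.
#' @export
trace <- function(field, seeds, cfg) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(cfg, "integration_config"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  seeds <- as.matrix(seeds)
  storage.mode(seeds) <- "double"
  cyc <- cycle_length(field)
  dir <- if (cfg$direction == "forward") 1L else -1L
  duration <- if (dir > 0) (cfg$t_end - cfg$t_start) %% cyc
              else (cfg$t_start - cfg$t_end) %% cyc
  if (duration == 0) {
    if (cfg$t_end == cfg$t_start)
      stop("t_start and t_end must differ modulo the cycle length")
    duration <- cyc  # a window spanning exactly one full cycle
  }
  res <- trace_cpp(field$velocities, as.integer(dim(field$velocities)),
                   field$spacing, field$origin, field$timeframe_duration,
                   seeds, cfg$t_start, duration, dir, cfg$timestep,
                   cfg$record_trajectories)
  structure(list(seeds = seeds, positions = res$positions,
                 status = factor(ifelse(res$status == 0L, "active",
                                        "left_grid"),
                                 levels = c("active", "left_grid")),
                 carried_volume = rep(voxel_volume(field), nrow(seeds)),
                 times = res$times, trajectories = res$trajectories,
                 config = cfg),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles (%s), %d left grid, %.4g mm^3 each\n",
              nrow(x$positions), x$config$direction,
              sum(x$status == "left_grid"), x$carried_volume[1]))
  invisible(x)
}

#' Emit particles for visualization export
#'
#' Seeds particles at the voxel centers of a region at regular emission
#' times inside a window (e.g. every 25-30 ms during diastole, in the
#' left atrium) and traces each emission forward to the window end.
#'
#' @param field a [velocity_field()].
#' @param region logical 3D mask (nz, ny, nx) of the emission region.
#' @param window length-2 times (ms), emission window start/end.
#' @param interval emission interval, ms (25-30 by convention).
#' @param timestep RK4 step, ms.
#' @return list of `particle_set`s, one per emission time, each with
#'   recorded trajectories and an `emission_time` attribute.
#' @export
emit_particles <- function(field, region, window, interval = 25,
                           timestep = 5) {
  seeds <- voxel_centers(field, region)
  if (nrow(seeds) == 0L) return(list())
  times <- seq(window[1], window[2], by = interval)
  times <- times[times < window[2]]
  if (length(times) == 0L) times <- window[1]
  lapply(times, function(t0) {
    ps <- trace(field, seeds,
                integration_config(t0, window[2], timestep = timestep,
                                   direction = "forward",
                                   record_trajectories = TRUE))
    attr(ps, "emission_time") <- t0
    ps
  })
}

#' Export particle trajectories
#'
#' Writes either a CSV (particle id, step, t, x, y, z) or a legacy
#' ASCII VTK polyline file for rendering.
#'
#' @param ps a `particle_set` with recorded trajectories.
#' @param path output file.
#' @param format `"csv"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(ps, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  traj <- ps$trajectories
  if (is.null(traj)) stop("particle set has no recorded trajectories")
  ns <- dim(traj)[1]; n <- dim(traj)[2]
  if (format == "csv") {
    df <- data.frame(
      particle = rep(seq_len(n), each = ns),
      step = rep(seq_len(ns) - 1L, times = n),
      t = rep(ps$times, times = n),
      x = as.vector(traj[, , 1]),
      y = as.vector(traj[, , 2]),
      z = as.vector(traj[, , 3]))
    write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0",
                 "cardioflow4d particle trajectories", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", ns * n)), con)
    pts <- matrix(NA_real_, ns * n, 3)
    for (i in seq_len(n))
      pts[((i - 1) * ns + 1):(i * ns), ] <- traj[, i, ]
    writeLines(apply(pts, 1, function(p)
      sprintf("%.6g %.6g %.6g", p[1], p[2], p[3])), con)
    writeLines(sprintf("LINES %d %d", n, n * (ns + 1)), con)
    for (i in seq_len(n))
      writeLines(paste(c(ns, ((i - 1) * ns):((i * ns) - 1)),
                       collapse = " "), con)
  }
  invisible(path)
}

#' Read trajectories exported as CSV
#' @param path CSV written by [export_trajectories()].
#' @return data.frame with particle, step, t, x, y, z.
#' @export
read_trajectories <- function(path) read.csv(path)
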