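#' Finite-time Lyapunov exponent field
#'
#' Seeds a particle at every voxel center, computes the flow map over
#' the window with the RK4 tracer, differentiates it by central
#' differences over the seed grid, and returns
#' `FTLE = ln(lambda_max(F'F)) / (2 |t1 - t0|)` in 1/s. Ridges of the
#' backward-time field approximate attracting Lagrangian coherent
#' structures such as the boundary of the diastolic vortex ring.
#' Voxels whose finite-difference stencil involves a particle that left
#' the grid, or grid-boundary voxels, are flagged `NA`.
#'
#' @param field a [velocity_field()].
#' @param t0,t1 window start/end, ms (`t0 < t1`; must differ).
#' @param direction `"forward"` (seeds advected t0 -> t1) or
#'   `"backward"` (seeds advected t1 -> t0 against the flow).
#' @param timestep RK4 step, ms.
#' @return An object of class `ftle_field`: `values` (nz x ny x nx,
#'   1/s), direction, window, grid metadata.
#' @export
ftle <- function(field, t0, t1, direction = c("forward", "backward"),
                 timestep = 5) {
  direction <- match.arg(direction)
  if (t1 == t0) stop("FTLE window must have |t1 - t0| > 0")
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$velocities)
  nz <- d[2]; ny <- d[3]; nx <- d[4]
  seeds <- voxel_centers(field)
  cfg <- if (direction == "forward")
    integration_config(t0, t1, timestep, "forward")
  else integration_config(t1, t0, timestep, "backward")
  ps <- trace(field, seeds, cfg)

  phi <- lapply(1:3, function(c) array(ps$positions[, c], dim = c(nz, ny, nx)))
  ok <- array(ps$status == "active", dim = c(nz, ny, nx))

  iz <- 2:(nz - 1); iy <- 2:(ny - 1); ix <- 2:(nx - 1)
  sp <- field$spacing
  # F[k, i] = d phi_k / d x_i, central differences on the seed lattice
  Fk <- vector("list", 9)
  dim(Fk) <- c(3, 3)
  for (k in 1:3) {
    p <- phi[[k]]
    Fk[[k, 1]] <- (p[iz, iy, ix + 1] - p[iz, iy, ix - 1]) / (2 * sp[1])
    Fk[[k, 2]] <- (p[iz, iy + 1, ix] - p[iz, iy - 1, ix]) / (2 * sp[2])
    Fk[[k, 3]] <- (p[iz + 1, iy, ix] - p[iz - 1, iy, ix]) / (2 * sp[3])
  }
  C <- function(i, j)
    Fk[[1, i]] * Fk[[1, j]] + Fk[[2, i]] * Fk[[2, j]] + Fk[[3, i]] * Fk[[3, j]]
  c11 <- C(1, 1); c22 <- C(2, 2); c33 <- C(3, 3)
  c12 <- C(1, 2); c13 <- C(1, 3); c23 <- C(2, 3)
  lmax <- eigmax_sym3(c11, c22, c33, c12, c13, c23)

  Tsec <- abs(t1 - t0) / 1000
  vals <- log(pmax(lmax, .Machine$double.eps)) / (2 * Tsec)

  valid <- ok[iz, iy, ix] &
    ok[iz, iy, ix + 1] & ok[iz, iy, ix - 1] &
    ok[iz, iy + 1, ix] & ok[iz, iy - 1, ix] &
    ok[iz + 1, iy, ix] & ok[iz - 1, iy, ix]
  vals[!valid] <- NA_real_

  out <- array(NA_real_, dim = c(nz, ny, nx))
  out[iz, iy, ix] <- vals
  structure(list(values = out, direction = direction, window = c(t0, t1),
                 spacing = sp, origin = field$origin),
            class = "ftle_field")
}

# largest eigenvalue of a symmetric 3x3, vectorized over arrays
eigmax_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  small <- p < 1e-300
  ps <- ifelse(small, 1, p)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  out <- q + 2 * p * cos(phi)
  out[small] <- q[small]
  out
}

#' @export
print.ftle_field <- function(x, ...) {
  cat(sprintf("<ftle_field> %s, window %.4g-%.4g ms, max %.3g 1/s\n",
              x$direction, x$window[1], x$window[2],
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Vortex-ring volume by slice-wise delineation
#'
#' The vortex ring is delineated in parallel short-axis slices a fixed
#' distance apart (4 mm by convention) and the total volume is the
#' summed volume of all slices. The enclosed region per slice is the
#' outermost closed FTLE ridge contour, operationalized as the largest
#' connected component of `FTLE >= threshold * max(FTLE)` after
#' morphological closing and hole filling. Manual per-slice polygon
#' contours may be supplied instead, in which case their areas are used
#' directly.
#'
#' @param ftle_field an [ftle()] result (typically backward-time over
#'   the rapid-filling window).
#' @param ftle_fwd optional forward-time [ftle()] field seeded at the
#'   same reference time. A translating ring's attracting (backward)
#'   ridge is strong on its leading side and weak on its trailing side,
#'   where the repelling (forward) ridge takes over; when supplied, the
#'   per-slice ridge mask is the union of both thresholded fields, each
#'   relative to its own maximum.
#' @param slice_axis `"x"`, `"y"` or `"z"`: the short-axis normal.
#' @param slice_spacing distance between delineated slices, mm.
#' @param threshold ridge threshold as a fraction of the maximal finite
#'   FTLE.
#' @param min_area smallest component area treated as vortex, mm^2.
#' @param closing radius (pixels) of the morphological closing brush.
#' @param contours optional list of manual polygons (n x 2 in-slice mm),
#'   one per delineated slice (`NULL` entries allowed).
#' @return An object of class `vortex_volume_result`: per-slice areas
#'   (mm^2), slice positions (mm), total volume (ml), threshold used.
#' @export
vortex_volume <- function(ftle_field, ftle_fwd = NULL, slice_axis = "z",
                          slice_spacing = 4, threshold = 0.6, min_area = 30,
                          closing = 1, contours = NULL) {
  ax <- match(slice_axis, c("x", "y", "z"))
  vals <- ftle_field$values
  d <- dim(vals)                      # (nz, ny, nx)
  n_ax <- d[c(3, 2, 1)][ax]
  sp <- ftle_field$spacing
  d_ax <- sp[ax]
  stride <- max(1L, round(slice_spacing / d_ax))
  slices <- seq(1L, n_ax, by = stride)
  pos <- ftle_field$origin[ax] + (slices - 1) * d_ax
  px_area <- prod(sp[-ax])

  if (!is.null(contours)) {
    areas <- vapply(seq_along(slices), function(i) {
      if (i > length(contours) || is.null(contours[[i]])) 0
      else polygon_area(as.matrix(contours[[i]]))
    }, numeric(1))
    total <- sum(areas) * slice_spacing / 1000
    return(structure(list(slice_areas = areas, slice_positions = pos,
                          total_volume = total, threshold = NA_real_,
                          slice_spacing = slice_spacing, manual = TRUE),
                     class = "vortex_volume_result"))
  }

  vals_f <- NULL
  if (!is.null(ftle_fwd)) {
    vals_f <- ftle_fwd$values
    if (!identical(dim(vals_f), d))
      stop("forward FTLE grid does not match the backward field")
  }
  finite_max <- suppressWarnings(max(vals, na.rm = TRUE))
  if (!is.finite(finite_max) || finite_max <= 0) {
    warning("FTLE field has no positive finite values; vortex volume 0")
    return(structure(list(slice_areas = rep(0, length(slices)),
                          slice_positions = pos, total_volume = 0,
                          threshold = threshold,
                          slice_spacing = slice_spacing, manual = FALSE),
                     class = "vortex_volume_result"))
  }
  thr <- threshold * finite_max
  thr_f <- if (!is.null(vals_f))
    threshold * suppressWarnings(max(vals_f, na.rm = TRUE)) else Inf
  brush <- EBImage::makeBrush(2 * closing + 1, shape = "box")
  get_slice <- function(a3, k) {
    m2 <- switch(ax,
                 a3[, , k],      # x slice -> (nz, ny)
                 a3[, k, ],      # y slice -> (nz, nx)
                 a3[k, , ])      # z slice -> (ny, nx)
    m2[!is.finite(m2)] <- -Inf
    m2
  }
  areas <- vapply(slices, function(k) {
    bw <- (get_slice(vals, k) >= thr) * 1
    if (!is.null(vals_f))
      bw <- pmax(bw, (get_slice(vals_f, k) >= thr_f) * 1)
    if (!any(bw > 0)) return(0)
    bw <- EBImage::closing(bw, brush)
    lab <- EBImage::bwlabel(bw)
    sizes <- tabulate(lab[lab > 0])
    if (length(sizes) == 0L) return(0)
    comp <- (lab == which.max(sizes)) * 1
    filled <- EBImage::fillHull(comp)
    # the ridge band straddles the enclosing LCS crest: counting the
    # filled region to the band's outer edge overestimates the area by
    # about half the band, so that half is subtracted
    a <- (sum(filled) - sum(comp) / 2) * px_area
    if (a < min_area) 0 else a
  }, numeric(1))
  if (all(areas == 0))
    warning("no slice component exceeded min_area; vortex volume 0")
  total <- sum(areas) * slice_spacing / 1000
  structure(list(slice_areas = areas, slice_positions = pos,
                 total_volume = total, threshold = threshold,
                 slice_spacing = slice_spacing, manual = FALSE),
            class = "vortex_volume_result")
}

#' @export
print.vortex_volume_result <- function(x, ...) {
  cat(sprintf("<vortex_volume_result> %.2f ml over %d slices (%g mm apart)%s\n",
              x$total_volume, sum(x$slice_areas > 0), x$slice_spacing,
              if (x$manual) ", manual contours"
              else sprintf(", threshold %.2f", x$threshold)))
  invisible(x)
}

#' Detect the rapid-filling window from mitral inflow
#'
#' Finds the diastolic timeframe of peak flux through a mitral-plane
#' ROI and returns a window of the requested width around it, for use
#' as the backward-FTLE integration window.
#'
#' @param field a [velocity_field()].
#' @param mitral_roi a [planar_roi()] on the mitral plane.
#' @param width window width, ms.
#' @param frames optional candidate frames (e.g. diastole only).
#' @return length-2 window (ms), clamped to the cycle.
#' @export
rapid_filling_window <- function(field, mitral_roi, width = 150,
                                 frames = NULL) {
  series <- resample_plane_from_4d(field, mitral_roi)
  fs <- flux_2d(series, mitral_roi)
  flux <- fs$flux
  if (!is.null(frames)) {
    keep <- rep(FALSE, length(flux)); keep[frames] <- TRUE
    flux[!keep] <- Inf
  }
  # mitral inflow is anti-basal: most negative flux along the basal normal
  k <- which.min(flux)
  tpk <- (k - 1) * field$timeframe_duration
  c(max(0, tpk - width / 2), min(cycle_length(field), tpk + width / 2))
}
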