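#' Two-dimensional through-plane flow series
#'
#' Container for a time-resolved through-plane velocity image, either
#' acquired directly (2D phase contrast) or resampled from 4D data by
#' [resample_plane_from_4d()]. `u`/`v` are regular in-plane pixel
#' center coordinates (mm) in the deterministic basis of the plane
#' ([plane_basis()]); `vthrough` holds the through-plane velocity
#' component in cm/s, positive along the plane normal.
#'
#' @param vthrough numeric array (nt, nv, nu), cm/s.
#' @param u,v pixel-center coordinate vectors, mm.
#' @param timeframe_duration ms.
#' @param plane optional list(point, normal) of the source plane.
#' @export
flow_series_2d <- function(vthrough, u, v, timeframe_duration,
                           plane = NULL) {
  d <- dim(vthrough)
  if (length(d) != 3L || d[2] != length(v) || d[3] != length(u))
    stop("`vthrough` must be (nt, length(v), length(u))")
  structure(list(vthrough = vthrough, u = as.numeric(u),
                 v = as.numeric(v),
                 timeframe_duration = as.numeric(timeframe_duration),
                 plane = plane),
            class = "flow_series_2d")
}

#' Through-plane flux and stroke volume from a 2D flow series
#'
#' Flux per timeframe is the sum of the through-plane velocity over the
#' pixels whose centers fall inside the ROI contour of that timeframe,
#' times the pixel area; the stroke volume is the rectangle-rule time
#' integral with timeframe-duration weights (matching retrospective
#' reconstruction semantics) over the full cycle.
#'
#' @param series a [flow_series_2d()].
#' @param roi a [planar_roi()] with contours in the same in-plane
#'   coordinates. A single contour is recycled over timeframes; with
#'   multiple contours every timeframe must have one.
#' @param shift in-plane rigid shift (mm) applied to the ROI contours
#'   (manual position correction).
#' @return An object of class `flux_series`: `flux` (ml/s per frame),
#'   `roi_area` (mm^2 per frame), `sv` (ml, full cycle).
#' @export
flux_2d <- function(series, roi, shift = c(0, 0)) {
  stopifnot(inherits(series, "flow_series_2d"), inherits(roi, "planar_roi"))
  nt <- dim(series$vthrough)[1]
  ncont <- length(roi$contours)
  if (ncont > 1L && ncont < nt)
    stop("ROI contour missing for timeframe(s): ",
         paste((ncont + 1L):nt, collapse = ", "))
  du <- if (length(series$u) > 1) diff(series$u)[1] else 1
  dv <- if (length(series$v) > 1) diff(series$v)[1] else 1
  px_area <- du * dv
  pts <- cbind(rep(series$u, each = length(series$v)),
               rep(series$v, times = length(series$u)))
  inside_for <- function(contour) {
    cc <- sweep(contour, 2, -as.numeric(shift))
    matrix(mgcv::in.out(rbind(cc, cc[1, ]), pts),
           nrow = length(series$v))
  }
  flux <- numeric(nt); area <- numeric(nt)
  inside <- inside_for(roi_contour(roi, 1L))
  for (t in seq_len(nt)) {
    if (ncont > 1L && t > 1L) inside <- inside_for(roi_contour(roi, t))
    vt <- series$vthrough[t, , ]
    sel <- inside & is.finite(vt)
    if (any(inside & !is.finite(vt)))
      stop("ROI extends outside the sampled plane at timeframe ", t)
    flux[t] <- sum(vt[sel]) * 10 * px_area / 1000  # cm/s*mm^2 -> ml/s
    area[t] <- sum(inside) * px_area
  }
  sv <- sum(flux * series$timeframe_duration) / 1000
  structure(list(flux = flux, roi_area = area, sv = sv,
                 timeframe_duration = series$timeframe_duration),
            class = "flux_series")
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("<flux_series> %d frames, SV %.2f ml, peak flux %.1f ml/s\n",
              length(x$flux), x$sv, max(abs(x$flux))))
  invisible(x)
}

#' Stroke volume over a frame subset
#'
#' Rectangle-rule integral of the flux over selected timeframes, e.g.
#' the systolic window of a valve-plane series where diastolic
#' through-plane flow is not part of the ejected volume.
#'
#' @param fs a `flux_series` from [flux_2d()].
#' @param frames 1-based timeframe indices; `NULL` = full cycle.
#' @return stroke volume, ml.
#' @export
flux_stroke_volume <- function(fs, frames = NULL) {
  if (is.null(frames)) return(fs$sv)
  sum(fs$flux[frames] * fs$timeframe_duration) / 1000
}

#' Resample a 2D through-plane series from 4D data
#'
#' Samples the 4D velocity field on a regular in-plane lattice at every
#' timeframe (trilinear interpolation via [sample_velocity()]) and
#' projects onto the plane normal, reproducing the plane of an acquired
#' 2D flow scan so its ROI can be copied across.
#'
#' @param field a [velocity_field()].
#' @param roi a [planar_roi()]; the lattice covers its contours plus a
#'   margin.
#' @param lattice_spacing in-plane sample spacing, mm (default 1, finer
#'   than the voxel so polygon rasterization is not the dominant error).
#' @param margin extra extent beyond the contour bounding box, mm.
#' @return a [flow_series_2d()] with `NA` where the lattice leaves the
#'   grid; an error if the plane lies wholly outside the grid.
#' @export
resample_plane_from_4d <- function(field, roi, lattice_spacing = 1,
                                   margin = 2) {
  stopifnot(inherits(field, "velocity_field"), inherits(roi, "planar_roi"))
  basis <- plane_basis(roi$normal)
  allc <- do.call(rbind, roi$contours)
  ur <- range(allc[, 1]) + c(-margin, margin)
  vr <- range(allc[, 2]) + c(-margin, margin)
  u <- seq(ur[1], ur[2], by = lattice_spacing)
  v <- seq(vr[1], vr[2], by = lattice_spacing)
  pts <- cbind(rep(u, each = length(v)), rep(v, times = length(u)))
  world <- outer(pts[, 1], basis$e1) + outer(pts[, 2], basis$e2)
  world <- sweep(world, 2, -roi$point)
  nt <- n_timeframes(field)
  tt <- frame_times(field)
  vth <- array(NA_real_, dim = c(nt, length(v), length(u)))
  for (t in seq_len(nt)) {
    vel <- sample_velocity(field, world, tt[t], units = "cm_s")
    vth[t, , ] <- matrix(vel %*% roi$normal, nrow = length(v))
  }
  if (all(!is.finite(vth[1, , ])))
    stop("ROI plane lies outside the velocity grid")
  flow_series_2d(vth, u, v, field$timeframe_duration,
                 plane = list(point = roi$point, normal = roi$normal))
}
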