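#' Phantom generators
#'
#' The package validates the quantification pipeline on analytic
#' velocity-field phantoms with known ground truth: a plug-flow tube
#' (stroke volume, kinetic energy, flux), a contracting ellipsoidal
#' ventricle (particle-trace inflow/outflow), and a Hill spherical
#' vortex (vortex-ring volumetry). Default grids follow a typical
#' whole-heart acquisition: 3 mm isotropic voxels, 40 reconstructed
#' phases, VENC 100 cm/s.
#'
#' @name phantoms
NULL

#' Plug-flow tube phantom
#'
#' A straight tube along the x axis carrying a plug velocity profile
#' with a half-sine waveform over systole and zero flow in diastole.
#' The wall is a linear shear ramp of width `wall_width` mm, so the
#' effective lumen area has the closed form `pi * (radius^2 +
#' wall_width^2 / 12)` and the true stroke volume is
#' `area * (2/pi) * v_peak * systole_duration`.
#'
#' @param radius lumen radius (mid-ramp), mm.
#' @param v_peak peak plug velocity, cm/s.
#' @param systole_duration duration of the half-sine, ms.
#' @param wall_width shear-layer width, mm; 0 gives a sharp wall.
#' @param nt,cycle_length timeframes and cycle length (ms).
#' @param spacing isotropic voxel size, mm.
#' @param shape grid dimensions (nx, ny, nz); the tube is centered on a
#'   voxel center in y and z.
#' @param venc velocity-encoding limit recorded in the field, cm/s.
#' @param density blood density for the kinetic-energy ground truth,
#'   kg/m^3.
#' @return list with `field`, `truth` (true_sv_ml, effective_area_mm2,
#'   ke_curve_mJ, waveform), `seg` (lumen-core masks, edge voxels
#'   excluded), `roi` (a [planar_roi()] across the tube) and
#'   `series_2d` factory via [plug_tube_series_2d()].
#' @export
make_plug_tube <- function(radius = 15, v_peak = 50, systole_duration = 400,
                           wall_width = 6, nt = 40, cycle_length = 1000,
                           spacing = 3, shape = c(12, 17, 17), venc = 100,
                           density = 1060) {
  td <- cycle_length / nt
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  half <- wall_width / 2
  ctr <- c(((ny - 1) %/% 2) * spacing, ((nz - 1) %/% 2) * spacing)
  if (radius + half >= min(ctr[1], (ny - 1) * spacing - ctr[1],
                           ctr[2], (nz - 1) * spacing - ctr[2]))
    stop("tube radius larger than grid extent")
  yc <- (seq_len(ny) - 1) * spacing - ctr[1]
  zc <- (seq_len(nz) - 1) * spacing - ctr[2]
  r <- sqrt(outer(zc^2, yc^2, `+`))          # (nz, ny)
  S <- if (wall_width > 0) {
    pmin(1, pmax(0, (radius + half - r) / wall_width))
  } else {
    (r <= radius) * 1
  }
  tt <- (seq_len(nt) - 1) * td
  vt <- ifelse(tt < systole_duration,
               v_peak * sin(pi * tt / systole_duration), 0)

  vel <- array(0, dim = c(nt, nz, ny, nx, 3))
  prof <- aperm(array(S, dim = c(nz, ny, nt)), c(3, 1, 2))  # (nt,nz,ny)
  for (x in seq_len(nx)) vel[, , , x, 1] <- prof * vt
  field <- velocity_field(vel, rep(spacing, 3), td, venc)

  core <- r <= radius - half - 1e-9          # full-velocity voxels only
  masks <- array(FALSE, dim = c(nt, nz, ny, nx))
  for (t in seq_len(nt)) for (x in seq_len(nx)) masks[t, , , x] <- core
  seg <- segmentation_set(masks, ed_index = 1L, es_index = 2L)

  area_eff <- pi * (radius^2 + wall_width^2 / 12)
  true_sv <- area_eff * (2 / pi) * (v_peak * 10) * (systole_duration / 1000) / 1000
  lumen_len <- nx * spacing
  n_core <- sum(core) * nx
  # KE of the core region: uniform speed v(t) over n_core voxels
  ke <- 0.5 * density * n_core * voxel_volume(field) * vt^2 * 1e-10

  theta <- seq(0, 2 * pi, length.out = 97)[-97]
  rr <- radius + half + 2
  contour <- cbind(rr * cos(theta), rr * sin(theta))
  roi <- planar_roi(point = c(((nx - 1) %/% 2) * spacing, ctr[1], ctr[2]),
                    normal = c(1, 0, 0), contours = contour)

  support <- array(FALSE, dim = c(nz, ny, nx))
  for (x in seq_len(nx)) support[, , x] <- S > 0

  list(field = field, seg = seg, roi = roi, support_mask = support,
       truth = list(true_sv_ml = true_sv, effective_area_mm2 = area_eff,
                    ke_curve_mJ = ke, waveform_cms = vt, density = density,
                    radius = radius, wall_width = wall_width,
                    systole_duration = systole_duration, v_peak = v_peak,
                    core_voxels = n_core, lumen_length_mm = lumen_len))
}

#' Analytic 2D through-plane flow series of the tube phantom
#'
#' Emulates the separately acquired 2D phase-contrast series: the
#' analytic tube profile evaluated on a fine pixel lattice in the ROI
#' plane, independent of the 4D voxel grid.
#'
#' @param phantom result of [make_plug_tube()].
#' @param pixel pixel size of the 2D series, mm.
#' @return a `flow_series_2d` (see [flux_2d()]).
#' @export
plug_tube_series_2d <- function(phantom, pixel = 1) {
  tr <- phantom$truth
  half <- tr$wall_width / 2
  ext <- tr$radius + half + 4
  u <- seq(-ext, ext, by = pixel)
  v <- seq(-ext, ext, by = pixel)
  r <- sqrt(outer(v^2, u^2, `+`))
  S <- if (tr$wall_width > 0) {
    pmin(1, pmax(0, (tr$radius + half - r) / tr$wall_width))
  } else {
    (r <= tr$radius) * 1
  }
  nt <- length(tr$waveform_cms)
  vth <- array(0, dim = c(nt, length(v), length(u)))
  for (t in seq_len(nt)) vth[t, , ] <- S * tr$waveform_cms[t]
  flow_series_2d(vth, u, v, phantom$field$timeframe_duration)
}

#' Contracting-ellipsoid ventricle phantom
#'
#' An ellipsoidal left ventricle whose volume falls from `v_ed` to
#' `v_ed - target_sv` over systole and refills in diastole. The long
#' axis is tilted relative to the voxel grid (as hearts are relative to
#' scanner axes). The velocity field is spatially linear: a
#' time-varying piston flow along the long axis (ejection in systole,
#' filling in diastole) plus an affine transverse contraction consistent
#' with the shrinking ellipsoid masks. Linear fields are represented
#' exactly by trilinear interpolation, and the triangular waveforms have
#' knots on the frame grid so fixed-step RK4 integrates them exactly;
#' the axial displacement is solved so that exactly
#' `round(target_sv / voxel_volume)` end-diastolic seed voxels cross the
#' basal valve plane, i.e. ground truth is enforced by construction.
#'
#' Mitral and aortic valve planes share the basal plane (normals along
#' the long axis, basal-pointing) and are laterally offset as in
#' long-axis delineations. The returned aortic ROI has area
#' `target_sv / displacement`, so its systolic flux integral equals the
#' target stroke volume.
#'
#' @param target_sv stroke volume to eject, ml.
#' @param v_ed end-diastolic volume, ml.
#' @param long_axis_mm long semi-axis, mm.
#' @param tilt length-2 (polar, azimuth) orientation of the long axis in
#'   radians: `u = (sin t1 cos t2, sin t1 sin t2, cos t1)`. A doubly
#'   oblique axis keeps the seeds' axial coordinates distinct, so the
#'   crossing count is controlled to single-voxel granularity.
#' @param systole_frames number of frames from ED to ES.
#' @param nt,cycle_length,spacing,venc grid/timing parameters.
#' @param density blood density, kg/m^3 (analytic KE ground truth).
#' @return list with `field`, `seg`, `planes` (mitral/aortic
#'   [valve_plane()]s), `roi_aortic`, and `truth` (true_sv_ml as
#'   constructed, the analytic cap-volume stroke volume, displacement,
#'   waveforms, analytic KE curve).
#' @export
make_contracting_ellipsoid <- function(target_sv = 80, v_ed = 140,
                                       long_axis_mm = 50,
                                       tilt = c(0.35, 0.6),
                                       systole_frames = 14, nt = 40,
                                       cycle_length = 1000, spacing = 3,
                                       venc = 100, density = 1060) {
  if (target_sv >= v_ed)
    stop("target_sv must be smaller than the end-diastolic volume")
  td <- cycle_length / nt
  ts <- systole_frames * td
  sv_mm3 <- target_sv * 1000
  ved_mm3 <- v_ed * 1000
  chalf <- long_axis_mm
  if (length(tilt) == 1L) tilt <- c(tilt, 0)
  u_hat <- c(sin(tilt[1]) * cos(tilt[2]), sin(tilt[1]) * sin(tilt[2]),
             cos(tilt[1]))
  a_ed <- sqrt(3 * ved_mm3 / (4 * pi * chalf))

  # continuous estimate of the axial displacement: basal cap of height h
  # of the ED ellipsoid holds the stroke volume
  cap_vol <- function(h) pi * a_ed^2 * h^2 * (3 * chalf - h) / (3 * chalf^2)
  d_cont <- if (sv_mm3 > 0)
    uniroot(function(h) cap_vol(h) - sv_mm3, c(1e-6, 2 * chalf - 1e-6))$root
  else 0
  # grid sized to hold the ellipsoid plus the ejected column
  d_guess <- d_cont + 4 * spacing
  ext_hi <- (chalf + d_guess + 4 * spacing) * abs(u_hat) +
    a_ed * sqrt(pmax(0, 1 - u_hat^2)) + 4 * spacing
  ext_lo <- chalf * abs(u_hat) + a_ed * sqrt(pmax(0, 1 - u_hat^2)) +
    4 * spacing
  nvox <- ceiling((ext_hi + ext_lo) / spacing) + 1
  origin <- -ext_lo
  nx <- nvox[1]; ny <- nvox[2]; nz <- nvox[3]
  field_dim <- c(nt, nz, ny, nx, 3)

  cen <- voxel_centers(
    velocity_field(array(0, dim = c(2, nz, ny, nx, 3)), rep(spacing, 3),
                   td, venc, origin))
  uu <- as.vector(cen %*% u_hat)
  rperp2 <- rowSums(cen^2) - uu^2

  inside_ellipsoid <- function(a) rperp2 / a^2 + uu^2 / chalf^2 <= 1
  ed_sel <- inside_ellipsoid(a_ed)

  voxvol <- spacing^3
  k <- round(sv_mm3 / voxvol)
  if (k >= sum(ed_sel)) stop("target_sv exceeds the discretized ED volume")
  us <- sort(uu[ed_sel], decreasing = TRUE)
  if (k == 0L) {
    # null-flow phantom: static ellipsoid, zero velocity everywhere
    dstar <- 0
    u_thr <- chalf
  } else {
  # place the threshold in the widest sense between *distinct* axial
  # values bracketing rank k, so seeds never sit on the plane to
  # within rounding
  uq <- sort(unique(us), decreasing = TRUE)
  ccount <- cumsum(as.integer(table(factor(us, levels = uq))))
  m <- which.min(abs(ccount[-length(ccount)] - k))
  u_thr <- (uq[m] + uq[m + 1]) / 2
  k <- ccount[m]  # achieved crossing count (voxel granularity)
  dstar <- chalf - u_thr  # axial displacement, mm
  if (dstar <= 0) stop("degenerate geometry: basal plane below crossing set")
  }

  # triangular waveforms with knots on the frame grid (exact under
  # linear time interpolation and 5 ms RK4 steps)
  tdia <- cycle_length - ts
  ws <- if (dstar > 0) 2 * dstar / ts else 0
  wd <- if (dstar > 0) 2 * dstar / tdia else 0
  w_of_t <- function(t) {  # axial speed, mm/ms, along +u_hat in systole
    t <- t %% cycle_length
    ifelse(t < ts,
           ws * (1 - abs(2 * t / ts - 1)),
           -wd * (1 - abs(2 * (t - ts) / tdia - 1)))
  }
  W_of_t <- function(t) {  # exact cumulative displacement of the triangles
    t <- t %% cycle_length
    ifelse(t <= ts / 2, ws * t^2 / ts,
    ifelse(t <= ts, dstar - ws * (ts - t)^2 / ts,
    {
      tau <- t - ts
      ifelse(tau <= tdia / 2, dstar - wd * tau^2 / tdia,
             wd * (tdia - tau)^2 / tdia)
    }))
  }
  tt <- (seq_len(nt) - 1) * td
  wt <- w_of_t(tt)
  Wt <- W_of_t(tt)
  eject_rate <- if (dstar > 0) sv_mm3 / dstar else 0  # mm^2 effective
  Vt <- ved_mm3 - eject_rate * Wt
  at <- sqrt(3 * Vt / (4 * pi * chalf))
  Vdot <- -eject_rate * wt                 # mm^3 / ms
  alpha <- Vdot / (2 * Vt)                 # 1/ms, transverse strain rate

  vel <- array(0, dim = field_dim)
  masks <- array(FALSE, dim = field_dim[1:4])
  rperp_vec <- cen - outer(uu, u_hat)
  for (t in seq_len(nt)) {
    vmat <- outer(rep(wt[t], length(uu)), u_hat) + alpha[t] * rperp_vec
    vmat <- vmat * 100                      # mm/ms -> cm/s
    for (c in 1:3) vel[t, , , , c] <- array(vmat[, c], dim = c(nz, ny, nx))
    masks[t, , , ] <- array(inside_ellipsoid(at[t]), dim = c(nz, ny, nx))
  }
  field <- velocity_field(vel, rep(spacing, 3), td, venc, origin)
  seg <- segmentation_set(masks, ed_index = 1L,
                          es_index = systole_frames + 1L)

  basis <- plane_basis(u_hat)
  base_pt <- chalf * u_hat
  planes <- list(
    mitral = valve_plane(base_pt - 12 * basis$e1, u_hat, "mitral"),
    aortic = valve_plane(base_pt + 12 * basis$e1, u_hat, "aortic"))
  r_roi <- if (dstar > 0) sqrt(sv_mm3 / (pi * dstar)) else a_ed / 2
  theta <- seq(0, 2 * pi, length.out = 97)[-97]
  roi_aortic <- planar_roi(base_pt, u_hat,
                           cbind(r_roi * cos(theta), r_roi * sin(theta)))

  # analytic KE of the ellipsoid interior:
  # int |v|^2 dV = V (w^2 + (2/5) alpha^2 a^2)
  # kg/m^3 * mm^3 * (mm/ms)^2 = 1e-9 kg m^2/s^2 = 1e-6 mJ
  ke_mJ <- 0.5 * density * Vt * (wt^2 + 0.4 * alpha^2 * at^2) * 1e-6

  cap_h <- chalf - u_thr
  cap_sv <- pi * a_ed^2 * cap_h^2 * (3 * chalf - cap_h) / (3 * chalf^2) / 1000

  list(field = field, seg = seg, planes = planes, roi_aortic = roi_aortic,
       truth = list(true_sv_ml = k * voxvol / 1000,
                    analytic_cap_sv_ml = cap_sv,
                    displacement_mm = dstar, long_axis = u_hat,
                    center = c(0, 0, 0), chalf = chalf,
                    waveform_mm_ms = wt, volumes_mm3 = Vt,
                    ke_curve_mJ = ke_mJ, density = density,
                    systole_frames = systole_frames))
}

#' Velocity of a (possibly translating) Hill spherical vortex
#'
#' Closed-form lab-frame velocity of the classical Hill vortex of radius
#' `a`, with quiescent far field. `strength` sets the internal
#' circulation: for the self-consistent classical solution the vortex
#' translates at `strength`.
#'
#' @param pos n x 3 world positions, mm.
#' @param center vortex center, mm.
#' @param a vortex radius, mm.
#' @param strength circulation scale U, cm/s.
#' @return n x 3 velocities, cm/s.
#' @export
hill_vortex_velocity <- function(pos, center, a, strength) {
  p <- sweep(as.matrix(pos), 2, center)
  s2 <- p[, 1]^2 + p[, 2]^2
  zeta <- p[, 3]
  r2 <- s2 + zeta^2
  out <- matrix(0, nrow(p), 3)
  inside <- r2 <= a^2
  if (any(inside)) {
    us <- (3 * strength / (2 * a^2)) * zeta[inside]      # per unit s
    out[inside, 1] <- us * p[inside, 1]
    out[inside, 2] <- us * p[inside, 2]
    out[inside, 3] <- (3 * strength / (2 * a^2)) *
      (a^2 - 2 * s2[inside] - zeta[inside]^2) + strength
  }
  if (any(!inside)) {
    r5 <- r2[!inside]^2.5
    usf <- (3 * strength * a^3 / 2) * zeta[!inside] / r5
    out[!inside, 1] <- usf * p[!inside, 1]
    out[!inside, 2] <- usf * p[!inside, 2]
    out[!inside, 3] <- (strength * a^3 / 2) *
      (2 * zeta[!inside]^2 - s2[!inside]) / r5
  }
  out
}

#' Hill spherical vortex phantom
#'
#' A Hill vortex of radius `a` embedded in a quiescent surround,
#' translating along +z at `translation` (default: the self-consistent
#' speed, equal to `strength`). With `translation = 0` the snapshot is
#' frozen in time (a kinematic phantom used for volume-invariance
#' checks). The true vortex volume is `(4/3) pi a^3`.
#'
#' @param a vortex radius, mm.
#' @param strength internal circulation scale, cm/s.
#' @param translation translation speed along +z, cm/s.
#' @param center0 vortex center at t = 0, mm.
#' @param shape grid (nx, ny, nz); must contain the sphere over the
#'   whole cycle.
#' @param spacing,nt,cycle_length,venc grid/timing parameters.
#' @return list with `field` and `truth` (true_vortex_volume_ml,
#'   center trajectory, a, strength).
#' @export
make_hill_vortex <- function(a = 20, strength = 10, translation = strength,
                             center0 = c(0, 0, -26), shape = c(32, 32, 56),
                             spacing = 2, nt = 52, cycle_length = 520,
                             venc = 100) {
  td <- cycle_length / nt
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  origin <- c(-(nx - 1) / 2 * spacing, -(ny - 1) / 2 * spacing,
              -(nz - 1) / 2 * spacing + center0[3] + translation / 100 *
                cycle_length / 2)
  tt <- (seq_len(nt) - 1) * td
  centers <- cbind(center0[1], center0[2],
                   center0[3] + translation * 10 / 1000 * tt)  # cm/s -> mm/ms
  lim_lo <- origin
  lim_hi <- origin + (c(nx, ny, nz) - 1) * spacing
  if (any(centers[, 3] - a < lim_lo[3]) || any(centers[, 3] + a > lim_hi[3]) ||
      center0[1] - a < lim_lo[1] || center0[1] + a > lim_hi[1] ||
      center0[2] - a < lim_lo[2] || center0[2] + a > lim_hi[2])
    stop("vortex sphere not fully inside the grid over the cycle")
  tmp <- velocity_field(array(0, dim = c(2, nz, ny, nx, 3)),
                        rep(spacing, 3), td, venc, origin)
  cen <- voxel_centers(tmp)
  vel <- array(0, dim = c(nt, nz, ny, nx, 3))
  for (t in seq_len(nt)) {
    v <- hill_vortex_velocity(cen, centers[t, ], a, strength)
    for (c in 1:3) vel[t, , , , c] <- array(v[, c], dim = c(nz, ny, nx))
  }
  field <- velocity_field(vel, rep(spacing, 3), td, venc, origin)
  list(field = field,
       truth = list(true_vortex_volume_ml = 4 / 3 * pi * a^3 / 1000,
                    a = a, strength = strength, translation = translation,
                    centers = centers, t_ref = cycle_length / 2))
}

#' Spatially linear reference fields
#'
#' Steady fields with closed-form Lagrangian behaviour, used to validate
#' the tracer and FTLE computation: a pure planar strain
#' `v = rate * (x, -y, 0)`, a rigid rotation `v = omega * (y, -x, 0)`,
#' or a uniform translation.
#'
#' @param kind `"strain"`, `"rotation"` or `"uniform"`.
#' @param rate strain rate or angular velocity, 1/s (rad/s).
#' @param velocity uniform velocity (cm/s), `kind = "uniform"` only.
#' @param shape,spacing grid dimensions and voxel size (mm); the field
#'   is centered on the grid center.
#' @param nt,cycle_length,venc timing parameters (the field is steady).
#' @return a [velocity_field()].
#' @export
make_linear_field <- function(kind = c("strain", "rotation", "uniform"),
                              rate = 1, velocity = c(10, 0, 0),
                              shape = c(64, 64, 64), spacing = 2, nt = 4,
                              cycle_length = 1000, venc = 100) {
  kind <- match.arg(kind)
  td <- cycle_length / nt
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  origin <- -(c(nx, ny, nz) - 1) / 2 * spacing
  tmp <- velocity_field(array(0, dim = c(2, nz, ny, nx, 3)),
                        rep(spacing, 3), td, venc, origin)
  cen <- voxel_centers(tmp)
  v <- switch(kind,
    strain = cbind(rate * cen[, 1], -rate * cen[, 2], 0) / 10,
    rotation = cbind(rate * cen[, 2], -rate * cen[, 1], 0) / 10,
    uniform = matrix(velocity, nrow(cen), 3, byrow = TRUE))
  # rate [1/s] * mm = mm/s; /10 -> cm/s
  vel <- array(0, dim = c(nt, nz, ny, nx, 3))
  for (t in seq_len(nt)) for (c in 1:3)
    vel[t, , , , c] <- array(v[, c], dim = c(nz, ny, nx))
  velocity_field(vel, rep(spacing, 3), td, venc, origin)
}

#' Corrupt a velocity field with background offsets, noise and wrapping
#'
#' Emulates the measurement imperfections the preprocessing stage must
#' undo: a static per-component affine phase background
#' `b(x) = c0 + c1 x + c2 y + c3 z` (eddy-current-like, constant over
#' the cycle), zero-mean Gaussian velocity noise, and phase wrapping of
#' values beyond the VENC (`v -> ((v + venc) mod 2 venc) - venc`).
#' Corruptions are applied in that order; the wrap mask records which
#' stored values exceeded the VENC before wrapping.
#'
#' @param field a [velocity_field()].
#' @param wrap apply VENC wrapping?
#' @param noise_sigma Gaussian velocity noise SD, cm/s.
#' @param background `NULL` or a 3 x 4 matrix (row = component,
#'   columns = c0 [cm/s], c1..c3 [cm/s per mm]).
#' @param seed RNG seed for the noise (local; does not disturb the
#'   global RNG state).
#' @return list with `field` (corrupted) and `truth`
#'   (background_coeffs, wrap_mask, noise_sigma, seed).
#' @export
corrupt_field <- function(field, wrap = FALSE, noise_sigma = 0,
                          background = NULL, seed = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  v <- field$velocities
  d <- dim(v)
  if (!is.null(background)) {
    background <- matrix(as.numeric(background), 3, 4)
    cen <- voxel_centers(field)
    for (c in 1:3) {
      b <- background[c, 1] + cen %*% background[c, 2:4]
      barr <- array(b, dim = d[2:4])
      for (t in seq_len(d[1])) v[t, , , , c] <- v[t, , , , c] + barr
    }
  }
  if (noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
    v <- v + array(rnorm(length(v), sd = noise_sigma), dim = d)
  }
  wrap_mask <- NULL
  if (wrap) {
    wrap_mask <- abs(v) > field$venc
    v <- ((v + field$venc) %% (2 * field$venc)) - field$venc
  }
  out <- field
  out$velocities <- v
  list(field = out,
       truth = list(background_coeffs = background, wrap_mask = wrap_mask,
                    noise_sigma = noise_sigma, seed = seed))
}

#' Emulate bulk respiratory displacement
#'
#' Shifts the whole field periodically along one axis before sampling,
#' the artifact a respiratory navigator is meant to avoid. Off by
#' default in all generators.
#'
#' @param field a [velocity_field()].
#' @param amplitude peak displacement, mm.
#' @param period respiratory period, ms.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return a displaced [velocity_field()].
#' @export
apply_respiratory_shift <- function(field, amplitude, period, axis = "z") {
  ax <- match(axis, c("x", "y", "z"))
  d <- dim(field$velocities)
  n_ax <- d[c(4, 3, 2)][ax]
  sp <- field$spacing[ax]
  tt <- frame_times(field)
  out <- field$velocities
  for (t in seq_len(d[1])) {
    shift <- amplitude * sin(2 * pi * tt[t] / period) / sp  # voxels
    i0 <- floor(shift); w <- shift - i0
    idx <- seq_len(n_ax)
    iA <- pmin(pmax(idx - i0, 1), n_ax)
    iB <- pmin(pmax(idx - i0 - 1, 1), n_ax)
    for (c in 1:3) {
      sl <- out[t, , , , c]
      out[t, , , , c] <- switch(ax,
        (1 - w) * sl[, , iA] + w * sl[, , iB],
        (1 - w) * sl[, iA, ] + w * sl[, iB, ],
        (1 - w) * sl[iA, , ] + w * sl[iB, , ])
    }
  }
  field$velocities <- out
  field
}

#' Generate a phantom from a declarative spec
#'
#' Dispatcher used by the pipeline/CLI layer: `kind` selects the
#' generator, remaining entries are passed through. `composite` is a
#' contracting ellipsoid with measurement corruption applied.
#'
#' @param spec named list with `kind` (`plug_tube`,
#'   `contracting_ellipsoid`, `hill_vortex`, `composite`), generator
#'   arguments, and optionally `corrupt` (arguments to
#'   [corrupt_field()]) and `seed`.
#' @return the generator's result, with `field` corrupted when
#'   requested (the clean field is kept as `field_clean`).
#' @export
make_phantom <- function(spec) {
  kind <- spec$kind
  if (is.null(kind)) stop("phantom spec needs a `kind`")
  args <- spec[setdiff(names(spec), c("kind", "corrupt", "seed"))]
  gen <- switch(kind,
    plug_tube = make_plug_tube,
    contracting_ellipsoid = make_contracting_ellipsoid,
    composite = make_contracting_ellipsoid,
    hill_vortex = make_hill_vortex,
    stop("unknown phantom kind: ", kind))
  ph <- do.call(gen, args)
  corr <- spec$corrupt
  if (identical(kind, "composite") && is.null(corr))
    corr <- list(noise_sigma = 2)
  if (!is.null(corr)) {
    if (!is.null(spec$seed) && is.null(corr$seed)) corr$seed <- spec$seed
    cr <- do.call(corrupt_field, c(list(field = ph$field), corr))
    ph$field_clean <- ph$field
    ph$field <- cr$field
    ph$truth$corruption <- cr$truth
  }
  ph
}
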