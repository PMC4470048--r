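#' Temporal phase unwrapping of velocity data
#'
#' Velocities beyond the VENC alias by multiples of 2*VENC. This
#' corrects them by walking each voxel's component time series around
#' the (periodic) cycle: whenever the jump from the corrected temporal
#' predecessor exceeds the VENC, the multiple of 2*VENC minimizing the
#' jump is added. Sweeps repeat until stable or `max_passes`. A series
#' with net winding around the cycle cannot be made consistent; such
#' voxels are counted and reported with a warning. Values are only ever
#' changed by integer multiples of 2*VENC. The first frame is taken as
#' the unwrapped reference.
#'
#' @param field a [velocity_field()].
#' @param manual optional data.frame of manual corrections with columns
#'   `t, z, y, x, component, k` (1-based indices; adds `k * 2 * venc`),
#'   applied after the automatic sweep.
#' @param max_passes maximum sweeps over the cycle.
#' @return list with `field` (corrected), `n_corrected` (voxel series
#'   touched) and `n_unresolved`.
#' @export
unwrap_velocity <- function(field, manual = NULL, max_passes = 3L) {
  stopifnot(inherits(field, "velocity_field"))
  venc <- field$venc
  d <- dim(field$velocities)
  nt <- d[1]
  m <- field$velocities
  dim(m) <- c(nt, prod(d[-1]))
  changed <- rep(FALSE, ncol(m))
  for (pass in seq_len(max_passes)) {
    any_change <- FALSE
    for (t in 2:nt) {
      k <- round((m[t - 1, ] - m[t, ]) / (2 * venc))
      nz <- k != 0
      if (any(nz)) {
        m[t, nz] <- m[t, nz] + 2 * venc * k[nz]
        changed <- changed | nz
        any_change <- TRUE
      }
    }
    if (!any_change) break
  }
  unresolved <- abs(m[1, ] - m[nt, ]) > venc
  n_unresolved <- sum(unresolved)
  if (n_unresolved > 0)
    warning(n_unresolved,
            " voxel series with net phase winding remain inconsistent ",
            "across the cycle seam")
  dim(m) <- d
  if (!is.null(manual)) {
    need <- c("t", "z", "y", "x", "component", "k")
    if (!all(need %in% names(manual)))
      stop("manual corrections need columns: ", paste(need, collapse = ", "))
    idx <- cbind(manual$t, manual$z, manual$y, manual$x, manual$component)
    m[idx] <- m[idx] + 2 * venc * manual$k
  }
  field$velocities <- m
  list(field = field, n_corrected = sum(changed),
       n_unresolved = n_unresolved)
}

#' Identify stationary tissue
#'
#' Voxels suitable for the eddy-current background fit: low temporal
#' variation of speed over the cycle, outside the (dilated) LV masks.
#' The selection is the automatic analog of delineating static chest
#' wall tissue by hand.
#'
#' @param field a [velocity_field()].
#' @param lv_masks optional [segmentation_set()] (the union of its
#'   masks is excluded) or a plain logical nz x ny x nx exclusion mask,
#'   either dilated by `dilate` voxels before exclusion.
#' @param sd_threshold temporal standard deviation of speed below which
#'   a voxel counts as stationary, cm/s (default 2).
#' @param dilate dilation radius (voxels, 6-connected) applied to the
#'   LV union before exclusion.
#' @param speed_max optional ceiling on the time-averaged speed (cm/s);
#'   `NULL` disables the magnitude floor.
#' @return list with `mask` (logical nz x ny x nx), `n`, and the
#'   selection parameters.
#' @export
find_stationary_tissue <- function(field, lv_masks = NULL, sd_threshold = 2,
                                   dilate = 1L, speed_max = NULL) {
  if (sd_threshold <= 0)
    stop("sd_threshold must be > 0 (cm/s); increase it to obtain a ",
         "non-empty stationary mask")
  d <- dim(field$velocities)
  nt <- d[1]; nvox <- prod(d[2:4])
  v <- field$velocities
  dim(v) <- c(nt, nvox, 3)
  speed <- sqrt(v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)  # (nt, nvox)
  mu <- colMeans(speed)
  sdv <- sqrt(colSums(sweep(speed, 2, mu)^2) / (nt - 1))
  sel <- sdv < sd_threshold
  if (!is.null(speed_max)) sel <- sel & (mu < speed_max)
  excl <- rep(FALSE, nvox)
  if (!is.null(lv_masks)) {
    u <- if (inherits(lv_masks, "segmentation_set"))
      apply(lv_masks$masks, c(2, 3, 4), any)
    else lv_masks  # a plain 3D exclusion mask
    for (i in seq_len(dilate)) u <- dilate6(u)
    excl <- as.vector(u)
  }
  sel <- sel & !excl
  if (!any(sel))
    stop("no stationary voxels found; increase sd_threshold")
  mask <- array(sel, dim = d[2:4])
  list(mask = mask, n = sum(sel), sd_threshold = sd_threshold,
       dilate = dilate, speed_max = speed_max)
}

# 6-connected binary dilation of a 3D array (nz, ny, nx)
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Stationary-tissue linear background correction
#'
#' Eddy currents leave a static, spatially smooth phase offset on the
#' velocity images. Per component, the time-averaged velocity over the
#' stationary mask is fit by least squares to a first-order spatial
#' polynomial `c0 + c1 x + c2 y + c3 z` (world mm) and the fitted plane
#' is subtracted from every voxel at every timeframe. The operation is
#' idempotent up to numerical precision.
#'
#' @param field a [velocity_field()].
#' @param stationary result of [find_stationary_tissue()] (or a logical
#'   nz x ny x nx mask).
#' @return list with `field` (corrected) and `coefficients` (3 x 4
#'   matrix, row = component).
#' @export
correct_background <- function(field, stationary) {
  mask <- if (is.list(stationary)) stationary$mask else stationary
  d <- dim(field$velocities)
  if (!identical(dim(mask), d[2:4]))
    stop("stationary mask grid ", paste(dim(mask), collapse = "x"),
         " does not match field grid ", paste(d[2:4], collapse = "x"))
  n <- sum(mask)
  if (n < 40L)
    stop("stationary mask has ", n,
         " voxels; need at least 10x the 4 fit parameters")
  cen_all <- voxel_centers(field)
  vbar <- apply(field$velocities, c(2, 3, 4, 5), mean)
  sel <- as.vector(mask)
  X <- cbind(1, cen_all[sel, , drop = FALSE])
  if (qr(X)$rank < 4L)
    stop("degenerate stationary mask geometry: background fit is rank-deficient")
  coefs <- matrix(NA_real_, 3, 4,
                  dimnames = list(c("vx", "vy", "vz"),
                                  c("c0", "cx", "cy", "cz")))
  Xall <- cbind(1, cen_all)
  v <- field$velocities
  for (c in 1:3) {
    yv <- as.vector(vbar[, , , c])[sel]
    beta <- lm.fit(X, yv)$coefficients
    coefs[c, ] <- beta
    plane <- array(Xall %*% beta, dim = d[2:4])
    for (t in seq_len(d[1])) v[t, , , , c] <- v[t, , , , c] - plane
  }
  field$velocities <- v
  list(field = field, coefficients = coefs)
}
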