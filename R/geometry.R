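#' Per-timeframe left-ventricular segmentation
#'
#' Binary LV blood-pool masks on the velocity grid, one per timeframe,
#' with the end-diastolic and end-systolic frame indices. When the
#' indices are not supplied they default to the frames of maximal and
#' minimal segmented volume.
#'
#' @param masks logical 4-d array, dim `(nt, nz, ny, nx)`.
#' @param ed_index,es_index 1-based timeframe indices of end-diastole
#'   and end-systole; `NULL` to derive from the mask volumes.
#' @return An object of class `segmentation_set` with elements `masks`,
#'   `ed_index`, `es_index` and `volumes` (voxel counts per frame).
#' @export
segmentation_set <- function(masks, ed_index = NULL, es_index = NULL) {
  d <- dim(masks)
  if (is.null(d) || length(d) != 4L)
    stop("`masks` must be a 4-d logical array (nt, nz, ny, nx)")
  storage.mode(masks) <- "logical"
  nt <- d[1]
  counts <- vapply(seq_len(nt), function(t) sum(masks[t, , , ]), numeric(1))
  if (is.null(ed_index)) ed_index <- which.max(counts)
  if (is.null(es_index)) es_index <- which.min(counts)
  ed_index <- as.integer(ed_index); es_index <- as.integer(es_index)
  if (ed_index < 1L || ed_index > nt || es_index < 1L || es_index > nt)
    stop("ed/es indices must lie in [1, ", nt, "]")
  if (counts[ed_index] < counts[es_index])
    stop("end-diastolic volume (", counts[ed_index],
         " voxels) is smaller than end-systolic (", counts[es_index], ")")
  structure(list(masks = masks, ed_index = ed_index, es_index = es_index,
                 volumes = counts),
            class = "segmentation_set")
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf("<segmentation_set> %d frames, ED frame %d (%d vox), ES frame %d (%d vox)\n",
              dim(x$masks)[1], x$ed_index, x$volumes[x$ed_index],
              x$es_index, x$volumes[x$es_index]))
  invisible(x)
}

#' Oriented valve plane
#'
#' A plane through `point` with unit normal `normal` pointing toward the
#' basal (atrial/aortic) side of the valve. A position `y` is on the
#' basal side iff `(y - point) . normal >= 0`; exact ties count as
#' basal.
#'
#' @param point world position on the plane, mm.
#' @param normal basal-pointing normal; normalized internally.
#' @param label `"mitral"` or `"aortic"`.
#' @export
valve_plane <- function(point, normal, label = c("mitral", "aortic")) {
  label <- match.arg(label)
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("`point` and `normal` must be length-3 world vectors (mm)")
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be nonzero")
  structure(list(point = point, normal = normal / nn, label = label),
            class = "valve_plane")
}

# signed basal distance of positions (n x 3) to a valve plane
basal_distance <- function(plane, pos) {
  sweep(pos, 2, plane$point) %*% plane$normal
}

#' Planar vessel region of interest
#'
#' An oriented plane together with a closed polygonal contour per
#' timeframe, expressed in in-plane coordinates (mm). The in-plane basis
#' is derived deterministically from the normal (see
#' [plane_basis()]), so contours delineated on a resampled plane and
#' contours supplied in config agree.
#'
#' @param point,normal plane origin (mm) and unit normal (normalized
#'   internally); flux is positive along `normal`.
#' @param contours either a single n x 2 matrix (recycled over frames)
#'   or a list with one closed, simple polygon per timeframe.
#' @export
planar_roi <- function(point, normal, contours) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("ROI plane normal must be nonzero")
  normal <- normal / nn
  if (is.matrix(contours)) contours <- list(contours)
  contours <- lapply(contours, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L)
      stop("each contour must be an n x 2 matrix of in-plane mm, n >= 3")
    if (!polygon_is_simple(p)) stop("ROI contour is self-intersecting")
    p
  })
  structure(list(point = point, normal = normal, contours = contours),
            class = "planar_roi")
}

roi_contour <- function(roi, t) {
  k <- length(roi$contours)
  if (k == 1L) return(roi$contours[[1L]])
  if (t > k) stop("ROI has no contour for timeframe ", t)
  roi$contours[[t]]
}

# Deterministic orthonormal in-plane basis (e1, e2) with e1 x e2 = n:
# e1 is the projection of the world axis least aligned with n.
#' Orthonormal in-plane basis of a plane normal
#' @param normal unit normal vector.
#' @return list with `e1`, `e2` (unit, orthogonal, `cross(e1,e2) = normal`).
#' @export
plane_basis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- diag(3)[, which.min(abs(normal))]
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# O(n^2) simplicity check: no two non-adjacent edges intersect.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Signed polygon area (shoelace), mm^2.
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Per-timeframe scalar series over the cardiac cycle
#'
#' @param values one scalar per timeframe (e.g. flux in ml/s or kinetic
#'   energy in mJ).
#' @param timeframe_duration ms.
#' @param units free-text unit label.
#' @export
flow_curve <- function(values, timeframe_duration, units = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a flow curve needs at least 2 timeframes")
  if (!is.numeric(timeframe_duration) || timeframe_duration <= 0)
    stop("`timeframe_duration` must be positive (ms)")
  structure(list(values = values,
                 timeframe_duration = as.numeric(timeframe_duration),
                 units = units),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %d frames x %.3g ms [%s]; mean %.4g, peak %.4g\n",
              length(x$values), x$timeframe_duration, x$units,
              mean(x$values), max(x$values)))
  invisible(x)
}
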