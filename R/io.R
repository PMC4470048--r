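#' Write a dataset to the canonical container
#'
#' The canonical on-disk form is a self-describing directory with the
#' logical groups `velocity` (one NIfTI volume per component, dim
#' x,y,z,t, cm/s, float64), `masks` (optional NIfTI, uint8), `meta.json`
#' (spacing, timeframe duration, VENC, origin, ED/ES indices) and an
#' optional `geometry.yaml` with valve planes and ROIs.
#'
#' @param field a [velocity_field()].
#' @param path directory to create.
#' @param seg optional [segmentation_set()] on the same grid.
#' @param overwrite overwrite an existing container?
#' @return `path`, invisibly.
#' @export
write_dataset <- function(field, path, seg = NULL, overwrite = FALSE) {
  stopifnot(inherits(field, "velocity_field"))
  if (dir.exists(path) && !overwrite)
    stop("container ", path, " already exists (use overwrite = TRUE)")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(field$velocities)
  for (c in 1:3) {
    # (t,z,y,x) -> (x,y,z,t)
    vol <- aperm(field$velocities[, , , , c, drop = FALSE][, , , , 1],
                 c(4, 3, 2, 1))
    hdr <- RNifti::niftiHeader(RNifti::asNifti(vol))
    hdr$pixdim[2:5] <- c(field$spacing, field$timeframe_duration)
    img <- RNifti::asNifti(vol, reference = hdr, datatype = "double")
    RNifti::writeNifti(img, file.path(path, sprintf("velocity_v%s.nii.gz",
                                                    c("x", "y", "z")[c])))
  }
  meta <- list(format = "cardioflow4d-container", version = 1L,
               dims = d, spacing = field$spacing,
               timeframe_duration = field$timeframe_duration,
               venc = field$venc, origin = field$origin,
               velocity_units = "cm/s")
  if (!is.null(seg)) {
    stopifnot(inherits(seg, "segmentation_set"))
    m <- aperm(seg$masks, c(4, 3, 2, 1)) * 1L
    RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"),
                       file.path(path, "masks_lv.nii.gz"))
    meta$ed_index <- seg$ed_index
    meta$es_index <- seg$es_index
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset from the canonical container
#'
#' @param path a container directory written by [write_dataset()].
#' @return list with `field` ([velocity_field()]), `seg`
#'   ([segmentation_set()] or `NULL`) and `geometry` (parsed
#'   `geometry.yaml` or `NULL`).
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("no meta.json in ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (fld in c("spacing", "timeframe_duration", "venc", "origin", "dims"))
    if (is.null(meta[[fld]]))
      stop("metadata field `", fld, "` missing from ", mf)
  d <- as.integer(meta$dims)
  vel <- array(NA_real_, dim = d)
  for (c in 1:3) {
    f <- file.path(path, sprintf("velocity_v%s.nii.gz", c("x", "y", "z")[c]))
    if (!file.exists(f)) stop("missing component volume ", f)
    vol <- as.array(RNifti::readNifti(f))
    if (!identical(dim(vol), d[c(4, 3, 2, 1)]))
      stop("velocity grid ", paste(dim(vol), collapse = "x"),
           " does not match metadata dims ",
           paste(d[c(4, 3, 2, 1)], collapse = "x"))
    vel[, , , , c] <- aperm(vol, c(4, 3, 2, 1))
  }
  field <- velocity_field(vel, meta$spacing, meta$timeframe_duration,
                          meta$venc, meta$origin)
  seg <- NULL
  mk <- file.path(path, "masks_lv.nii.gz")
  if (file.exists(mk)) {
    m <- as.array(RNifti::readNifti(mk))
    if (!identical(dim(m), d[c(4, 3, 2, 1)]))
      stop("mask grid ", paste(dim(m), collapse = "x"),
           " does not match velocity grid ",
           paste(d[c(4, 3, 2, 1)], collapse = "x"))
    seg <- segmentation_set(aperm(m, c(4, 3, 2, 1)) > 0,
                            ed_index = meta$ed_index,
                            es_index = meta$es_index)
  }
  geom <- NULL
  gf <- file.path(path, "geometry.yaml")
  if (file.exists(gf)) geom <- read_geometry(gf)
  list(field = field, seg = seg, geometry = geom)
}

#' Import a per-timeframe NIfTI volume series
#'
#' Interoperability importer for exports that store one 3D volume per
#' timeframe and velocity component. NIfTI carries no VENC or cycle
#' timing, so those must be given explicitly; a missing value is a hard
#' error. The world-coordinate handedness of scanner exports varies, so
#' axes can be flipped explicitly.
#'
#' @param files character matrix `nt x 3` (rows = timeframes, columns =
#'   vx, vy, vz) of NIfTI paths; entries of missing files are reported
#'   with their timeframe index.
#' @param timeframe_duration,venc acquisition metadata (ms, cm/s).
#' @param origin world position of voxel (1,1,1), mm.
#' @param flip logical length-3: negate the (x, y, z) velocity component
#'   and reverse that grid axis.
#' @param scale multiplicative factor bringing stored values to cm/s.
#' @return a [velocity_field()].
#' @export
read_nifti_series <- function(files, timeframe_duration, venc,
                              origin = c(0, 0, 0),
                              flip = c(FALSE, FALSE, FALSE), scale = 1) {
  if (missing(timeframe_duration) || is.null(timeframe_duration))
    stop("metadata field `timeframe_duration` is required")
  if (missing(venc) || is.null(venc))
    stop("metadata field `venc` is required")
  files <- as.matrix(files)
  if (ncol(files) != 3L) stop("`files` must be nt x 3 (vx, vy, vz)")
  nt <- nrow(files)
  missing_idx <- which(!apply(files, 1, function(r) all(file.exists(r))))
  if (length(missing_idx))
    stop("missing timeframe volume(s) at index: ",
         paste(missing_idx, collapse = ", "))
  first <- RNifti::readNifti(files[1, 1])
  sp <- RNifti::pixdim(first)[1:3]
  dd <- dim(as.array(first))
  vel <- array(NA_real_, dim = c(nt, dd[3], dd[2], dd[1], 3))
  for (t in seq_len(nt)) for (c in 1:3) {
    vol <- as.array(RNifti::readNifti(files[t, c])) * scale
    if (!identical(dim(vol), dd))
      stop("grid mismatch at timeframe ", t, ": ",
           paste(dim(vol), collapse = "x"), " vs ",
           paste(dd, collapse = "x"))
    if (flip[c]) vol <- -vol
    vel[t, , , , c] <- aperm(vol, c(3, 2, 1))
  }
  for (ax in 1:3) if (flip[ax]) {
    # reverse the grid axis so the handedness flip is geometric, not
    # just a sign change of the component
    axdim <- c(4, 3, 2)[ax]
    idx <- rev(seq_len(dim(vel)[axdim]))
    vel <- switch(ax,
                  vel[, , , idx, , drop = FALSE],
                  vel[, , idx, , , drop = FALSE],
                  vel[, idx, , , , drop = FALSE])
  }
  velocity_field(vel, sp, timeframe_duration, venc, origin)
}

#' Read valve-plane / ROI geometry from YAML
#'
#' Expected layout: top-level keys `valve_planes` (list of
#' point/normal/label), `rois` (list of point/normal/contours, contours
#' as lists of `[u, v]` mm pairs) and free-form `options`.
#'
#' @param path YAML file.
#' @return list with `valve_planes`, `rois`, `options`.
#' @export
read_geometry <- function(path) {
  g <- yaml::read_yaml(path)
  planes <- lapply(g$valve_planes, function(p)
    valve_plane(unlist(p$point), unlist(p$normal), p$label))
  if (length(planes)) names(planes) <- vapply(planes, `[[`, "", "label")
  rois <- lapply(g$rois, function(r) {
    contours <- r$contours
    if (!is.null(contours) && !is.list(contours[[1]])) contours <- list(contours)
    contours <- lapply(contours, function(cc)
      do.call(rbind, lapply(cc, unlist)))
    planar_roi(unlist(r$point), unlist(r$normal), contours)
  })
  if (length(rois) && !is.null(g$rois[[1]]$label))
    names(rois) <- vapply(g$rois, `[[`, "", "label")
  list(valve_planes = planes, rois = rois, options = g$options)
}

#' Write metric tables and run metadata
#'
#' Writes a deterministic CSV of metric records (fixed column order:
#' subject, condition, metric, value, units) plus a JSON sidecar with
#' the configuration hash, seed and package version. Two runs on the
#' same inputs produce byte-identical files apart from the timestamp
#' field in the JSON.
#'
#' @param records data.frame with columns subject, condition, metric,
#'   value, units (extra columns are dropped; zero rows give a
#'   header-only CSV).
#' @param dir output directory.
#' @param config arbitrary R object describing the run; hashed into the
#'   metadata.
#' @param seed integer seed recorded in the metadata.
#' @param overwrite overwrite existing files?
#' @param name basename for the pair of files.
#' @return named character vector of the two paths, invisibly.
#' @export
write_results <- function(records, dir, config = list(), seed = NA_integer_,
                          overwrite = FALSE, name = "metrics") {
  cols <- c("subject", "condition", "metric", "value", "units")
  if (nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(character(0)), 5), cols))
  } else {
    miss <- setdiff(cols, names(records))
    if (length(miss)) stop("records lack column(s): ",
                           paste(miss, collapse = ", "))
    records <- records[, cols]
    records <- records[order(records$subject, records$condition,
                             records$metric), , drop = FALSE]
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, "_run.json"))
  if (!overwrite && (file.exists(csv) || file.exists(js)))
    stop("output ", csv, " already exists (use overwrite = TRUE)")
  write.csv(records, csv, row.names = FALSE)
  meta <- list(config_hash = hash_object(config), seed = seed,
               package_version = as.character(packageVersion("cardioflow4d")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

# md5 of a canonical serialization (version 2 for stability)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
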