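#' Run the full quantification workflow from a config
#'
#' Orchestrates the study workflow end-to-end: per condition, load a
#' dataset (canonical container) or generate a phantom, optionally
#' preprocess (unwrap, background-correct), compute the selected
#' metrics (particle-trace volumes, kinetic energy, stroke volume,
#' vortex volume), then compare every pair of conditions with the
#' agreement layer. Identical config and seeds give identical numeric
#' outputs.
#'
#' @param config a named list or a YAML file path. Keys: `seed`,
#'   `output_dir`, `metrics` (subset of pt, ke, sv, vortex),
#'   `conditions` (list; each has `label` and either `dataset` (a
#'   container path) or `phantom` (a [make_phantom()] spec), optional
#'   `subject`, `preprocess` (logical or list with `sd_threshold`),
#'   optional `corrupt`), optional `vortex_window` (ms).
#' @return list with `metrics` (data.frame), `agreement` (data.frame or
#'   NULL), `log` (list), and output file paths; results are also
#'   written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(packageVersion("cardioflow4d")),
              stages = list())
  cfg_err <- function(...) stop("config validation: ", ...)
  if (is.null(config$conditions) || length(config$conditions) == 0)
    cfg_err("no conditions given")
  labels <- vapply(config$conditions, function(cc) cc$label %||% "",
                   character(1))
  if (any(labels == "")) cfg_err("every condition needs a label")
  if (anyDuplicated(labels)) cfg_err("condition labels must be unique")
  metrics <- config$metrics
  if (is.null(metrics) || length(metrics) == 0)
    cfg_err("empty metric selection")
  bad <- setdiff(unlist(metrics), c("pt", "ke", "sv", "vortex"))
  if (length(bad)) cfg_err("unknown metric(s): ", paste(bad, collapse = ", "))
  for (cc in config$conditions)
    if (!is.null(cc$dataset) && !dir.exists(cc$dataset))
      cfg_err("dataset path does not exist: ", cc$dataset)
  seed <- config$seed %||% 1L
  outdir <- config$output_dir %||% tempfile("cardioflow4d_run_")

  rows <- list()
  for (cc in config$conditions) {
    stage <- paste0("condition:", cc$label)
    res <- tryCatch(
      run_condition(cc, metrics, config, seed),
      error = function(e) stop("stage `", stage, "` failed: ",
                               conditionMessage(e), call. = FALSE))
    rows[[cc$label]] <- res$rows
    log$stages[[stage]] <- res$log
  }
  metric_df <- do.call(rbind, rows)
  rownames(metric_df) <- NULL

  agree <- NULL
  if (length(labels) >= 2L) {
    pairs <- utils::combn(labels, 2, simplify = FALSE)
    tabs <- lapply(pairs, function(pr) {
      tb <- agreement_table(metric_df, pr[1], pr[2])
      if (!is.null(tb) && nrow(tb)) {
        tb$condition_a <- pr[1]; tb$condition_b <- pr[2]
      }
      tb
    })
    tabs <- tabs[!vapply(tabs, is.null, logical(1))]
    if (length(tabs)) agree <- do.call(rbind, tabs)
  }

  paths <- write_results(metric_df, outdir, config = config, seed = seed,
                         overwrite = TRUE)
  if (!is.null(agree)) {
    af <- file.path(outdir, "agreement.csv")
    write.csv(agree, af, row.names = FALSE)
    paths <- c(paths, agreement = af)
  }
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  writeLines(c(paste("cardioflow4d run", log$started),
               paste("conditions:", paste(labels, collapse = ", ")),
               paste("metrics:", paste(unlist(metrics), collapse = ", ")),
               paste("seed:", seed)),
             file.path(outdir, "run_log.txt"))
  list(metrics = metric_df, agreement = agree, log = log, paths = paths,
       output_dir = outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_condition <- function(cc, metrics, config, seed) {
  lg <- list()
  subject <- cc$subject %||% "phantom"
  if (!is.null(cc$dataset)) {
    ds <- read_dataset(cc$dataset)
    field <- ds$field; seg <- ds$seg
    planes <- ds$geometry$valve_planes
    roi <- if (length(ds$geometry$rois)) ds$geometry$rois[[1]] else NULL
    truth <- NULL
    lg$source <- cc$dataset
  } else if (!is.null(cc$phantom)) {
    spec <- cc$phantom
    if (!is.null(cc$corrupt)) spec$corrupt <- cc$corrupt
    if (is.null(spec$seed)) spec$seed <- seed
    ph <- make_phantom(spec)
    field <- ph$field; seg <- ph$seg
    planes <- ph$planes
    roi <- ph$roi_aortic %||% ph$roi
    truth <- ph$truth
    lg$source <- paste0("phantom:", spec$kind)
  } else stop("condition needs either `dataset` or `phantom`")

  if (isTRUE(cc$preprocess) || is.list(cc$preprocess)) {
    pp <- if (is.list(cc$preprocess)) cc$preprocess else list()
    uw <- unwrap_velocity(field)
    field <- uw$field
    lg$unwrapped_voxels <- uw$n_corrected
    st <- find_stationary_tissue(field, seg,
                                 sd_threshold = pp$sd_threshold %||% 2)
    bc <- correct_background(field, st)
    field <- bc$field
    lg$background_coefficients <- bc$coefficients
  }

  rows <- list()
  add <- function(metric, value, units)
    rows[[length(rows) + 1]] <<- data.frame(
      subject = subject, condition = cc$label, metric = metric,
      value = value, units = units)

  if ("pt" %in% metrics) {
    if (is.null(seg) || is.null(planes))
      stop("pt metric needs segmentation and valve planes")
    pt <- pt_volumes(field, seg, planes$mitral, planes$aortic)
    add("pt_inflow", pt$inflow_volume, "ml")
    add("pt_outflow", pt$outflow_volume, "ml")
    lg$pt_left_grid <- pt$left_grid_inflow + pt$left_grid_outflow
  }
  if ("ke" %in% metrics) {
    if (is.null(seg)) stop("ke metric needs segmentation")
    ke <- kinetic_energy_curve(field, seg)
    add("mean_ke", ke$mean_ke, "mJ")
    add("peak_ke", ke$peak_ke, "mJ")
  }
  if ("sv" %in% metrics) {
    if (is.null(roi)) stop("sv metric needs a planar ROI")
    fs <- flux_2d(resample_plane_from_4d(field, roi), roi)
    sysf <- truth$systole_frames
    sv <- if (!is.null(sysf)) flux_stroke_volume(fs, seq_len(sysf + 1))
          else fs$sv
    add("sv", sv, "ml")
  }
  if ("vortex" %in% metrics) {
    win <- config$vortex_window %||%
      c(0, min(250, cycle_length(field) / 4))
    ff <- ftle(field, win[1], win[2], direction = "backward")
    vv <- vortex_volume(ff)
    add("vortex_volume", vv$total_volume, "ml")
    lg$vortex_window <- win
  }
  list(rows = do.call(rbind, rows), log = lg)
}
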