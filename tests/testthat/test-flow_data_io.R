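test_that("velocity_field validates and reports geometry", {
  f <- random_field()
  expect_equal(voxel_volume(f), prod(c(2, 3, 4)), tolerance = 1e-12)
  expect_equal(n_timeframes(f), 5L)
  expect_equal(cycle_length(f), 200)
  # typical acquisition: 3 mm isotropic voxels -> 27 mm^3
  f3 <- velocity_field(array(0, dim = c(2, 4, 4, 4, 3)), c(3, 3, 3),
                       25, 100)
  expect_equal(voxel_volume(f3), 27)
  expect_error(velocity_field(array(0, dim = c(1, 4, 4, 4, 3)),
                              c(3, 3, 3), 25, 100), "2 timeframes")
  expect_error(velocity_field(array(0, dim = c(2, 4, 4, 4, 2)),
                              c(3, 3, 3), 25, 100), "dim")
  expect_error(velocity_field(array(0, dim = c(2, 4, 4, 4, 3)),
                              c(3, -3, 3), 25, 100), "spacing")
})

test_that("container write/read round trip is exact", {
  ph <- fixture("tube_small", small_tube())
  d <- withr::local_tempdir()
  p <- file.path(d, "ds")
  write_dataset(ph$field, p, seg = ph$seg)
  rt <- read_dataset(p)
  expect_identical(rt$field$velocities, ph$field$velocities)
  expect_equal(rt$field$spacing, ph$field$spacing)
  expect_equal(rt$field$venc, ph$field$venc)
  expect_equal(rt$field$timeframe_duration, ph$field$timeframe_duration)
  expect_identical(rt$seg$masks, ph$seg$masks)
  expect_equal(rt$seg$ed_index, ph$seg$ed_index)
  expect_error(write_dataset(ph$field, p), "overwrite")
})

test_that("container read fails hard on missing metadata", {
  ph <- fixture("tube_small", small_tube())
  d <- withr::local_tempdir()
  p <- file.path(d, "ds")
  write_dataset(ph$field, p)
  meta <- jsonlite::read_json(file.path(p, "meta.json"),
                              simplifyVector = TRUE)
  meta$venc <- NULL
  jsonlite::write_json(meta, file.path(p, "meta.json"), auto_unbox = TRUE)
  expect_error(read_dataset(p), "venc")
  expect_error(read_dataset(file.path(d, "nothere")), "meta.json")
})

test_that("NIfTI series importer reports missing timeframes by index", {
  ph <- fixture("tube_small", small_tube())
  d <- withr::local_tempdir()
  nt <- n_timeframes(ph$field)
  files <- matrix("", nt, 3)
  for (t in seq_len(nt)) for (c in 1:3) {
    vol <- aperm(ph$field$velocities[t, , , , c], c(3, 2, 1))
    files[t, c] <- file.path(d, sprintf("v%d_t%02d.nii.gz", c, t))
    hdr <- RNifti::niftiHeader(RNifti::asNifti(vol))
    hdr$pixdim[2:4] <- ph$field$spacing
    RNifti::writeNifti(RNifti::asNifti(vol, reference = hdr,
                                       datatype = "double"), files[t, c])
  }
  f <- read_nifti_series(files, timeframe_duration = 100, venc = 100)
  expect_equal(f$velocities, ph$field$velocities, tolerance = 1e-12)
  expect_equal(f$spacing, ph$field$spacing)
  unlink(files[7, 2])
  expect_error(read_nifti_series(files, 100, 100), "7")
  expect_error(read_nifti_series(files[-7, ], venc = 100),
               "timeframe_duration")
})

test_that("metric tables are deterministic and complete", {
  d <- withr::local_tempdir()
  rec <- data.frame(subject = rep(c("s1", "s2"), each = 3),
                    condition = "gated",
                    metric = rep(c("sv", "mean_ke", "pt_inflow"), 2),
                    value = c(88, 1.5, 91, 97, 1.4, 85),
                    units = c("ml", "mJ", "ml", "ml", "mJ", "ml"))
  p1 <- write_results(rec, file.path(d, "a"), config = list(x = 1), seed = 7)
  out <- read.csv(p1[["csv"]])
  expect_equal(nrow(out), 6L)
  expect_equal(names(out), c("subject", "condition", "metric", "value",
                             "units"))
  # empty record list -> header-only CSV
  p0 <- write_results(rec[0, ], file.path(d, "b"))
  expect_equal(nrow(read.csv(p0[["csv"]])), 0L)
  # rerun: byte-identical CSV; JSON differs only in the timestamp
  p2 <- write_results(rec, file.path(d, "c"), config = list(x = 1), seed = 7)
  expect_identical(readLines(p1[["csv"]]), readLines(p2[["csv"]]))
  j1 <- jsonlite::read_json(p1[["json"]])
  j2 <- jsonlite::read_json(p2[["json"]])
  j1$timestamp <- j2$timestamp <- NULL
  expect_identical(j1, j2)
  expect_error(write_results(rec, file.path(d, "a")), "exists")
  expect_error(write_results(rec[, -4], file.path(d, "z")), "value")
})

test_that("geometry YAML round trips planes and ROIs", {
  d <- withr::local_tempdir()
  gf <- file.path(d, "geometry.yaml")
  yaml::write_yaml(list(
    valve_planes = list(
      list(point = c(10, 0, 40), normal = c(0, 0, 2), label = "mitral"),
      list(point = c(-10, 0, 40), normal = c(0, 0, 1), label = "aortic")),
    rois = list(list(label = "aorta", point = c(0, 0, 40),
                     normal = c(0, 0, 1),
                     contours = list(list(c(-5, -5), c(5, -5), c(5, 5),
                                          c(-5, 5))))),
    options = list(sd_threshold = 2)), gf)
  g <- read_geometry(gf)
  expect_named(g$valve_planes, c("mitral", "aortic"))
  expect_equal(g$valve_planes$mitral$normal, c(0, 0, 1))  # normalized
  expect_s3_class(g$rois$aorta, "planar_roi")
  expect_equal(g$options$sd_threshold, 2)
})

test_that("valve planes classify and polygons are checked", {
  vp <- valve_plane(c(0, 0, 10), c(0, 0, 3), "mitral")
  expect_equal(sqrt(sum(vp$normal^2)), 1, tolerance = 1e-12)
  expect_error(valve_plane(c(0, 0, 0), c(0, 0, 0)), "nonzero")
  # a bow-tie is rejected as self-intersecting
  expect_error(planar_roi(c(0, 0, 0), c(0, 0, 1),
                          rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))),
               "self-intersecting")
})
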