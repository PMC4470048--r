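test_that("sampling reproduces stored values at nodes and wraps time", {
  f <- random_field()
  d <- dim(f$velocities)
  set.seed(3)
  for (i in 1:20) {
    t <- sample(d[1], 1); z <- sample(d[2], 1)
    y <- sample(d[3], 1); x <- sample(d[4], 1)
    pos <- f$origin + (c(x, y, z) - 1) * f$spacing
    v <- sample_velocity(f, pos, (t - 1) * f$timeframe_duration,
                         units = "cm_s")
    expect_equal(unname(v[1, ]), f$velocities[t, z, y, x, ],
                 tolerance = 1e-12)
  }
  # periodic time wrap: t and t + cycle are identical
  pos <- matrix(f$origin + 1.7 * f$spacing, ncol = 3)
  expect_equal(sample_velocity(f, pos, 13),
               sample_velocity(f, pos, 13 + cycle_length(f)),
               tolerance = 1e-12)
  # outside the voxel-center box: sentinel
  expect_true(all(is.na(sample_velocity(f, f$origin - 10, 0))))
})

test_that("interpolation is linear between nodes", {
  # field linear in x: value midway equals the mean of its neighbors
  f <- make_linear_field("strain", rate = 1, shape = c(10, 10, 10),
                         spacing = 3)
  p1 <- c(0, 0, 0); p2 <- c(3, 0, 0)
  vmid <- sample_velocity(f, (p1 + p2) / 2, 0, units = "cm_s")
  v1 <- sample_velocity(f, p1, 0, units = "cm_s")
  v2 <- sample_velocity(f, p2, 0, units = "cm_s")
  expect_equal(vmid, (v1 + v2) / 2, tolerance = 1e-12)
  # spatially uniform 100 cm/s == 1 mm/ms
  fu <- make_linear_field("uniform", velocity = c(100, 0, 0),
                          shape = c(8, 8, 8), spacing = 3)
  expect_equal(unname(sample_velocity(fu, c(1, 2, 3), 57)[1, ]),
               c(1, 0, 0), tolerance = 1e-15)
})

test_that("RK4 is exact for a constant field", {
  fu <- make_linear_field("uniform", velocity = c(100, 0, 0),
                          shape = c(40, 8, 8), spacing = 3)
  seed <- c(-55, 0, 0)
  ps <- trace(fu, seed, integration_config(0, 50, 5, "forward"))
  expect_equal(unname(ps$positions[1, ]), seed + c(50, 0, 0),
               tolerance = 1e-12)
  expect_equal(as.character(ps$status), "active")
  expect_equal(ps$carried_volume, 27)
})

test_that("RK4 convergence order on the rotation field is 4", {
  f <- fixture("rotation64",
               make_linear_field("rotation", rate = 2 * pi,
                                 shape = c(48, 48, 6), spacing = 3))
  seed <- c(30, 0, 0)  # closed circle of radius 30 mm, period 1 s
  errs <- vapply(c(10, 5, 2.5), function(dt) {
    ps <- trace(f, seed, integration_config(0, 1000, dt, "forward"))
    sqrt(sum((ps$positions - seed)^2))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(abs(orders - 4) < 0.2))
})

test_that("forward then backward tracing returns to the start", {
  f <- fixture("rotation64",
               make_linear_field("rotation", rate = 2 * pi,
                                 shape = c(48, 48, 6), spacing = 3))
  seeds <- rbind(c(20, 5, 0), c(-10, 25, 0), c(0, -31, 0))
  fw <- trace(f, seeds, integration_config(0, 400, 5, "forward"))
  bw <- trace(f, fw$positions, integration_config(400, 0, 5, "backward"))
  expect_lt(max(abs(bw$positions - seeds)), 1e-6)
})

test_that("trajectories are continuous and bounded by the local speed", {
  ph <- fixture("tube_default", make_plug_tube())
  seeds <- voxel_centers(ph$field, ph$seg$masks[1, , , ])[1:50, ]
  ps <- trace(ph$field, seeds,
              integration_config(0, 400, 5, "forward",
                                 record_trajectories = TRUE))
  steps <- apply(ps$trajectories, c(2, 3), diff)
  disp <- sqrt(apply(steps^2, c(1, 2), sum))
  vmax_mm_ms <- max(abs(ph$field$velocities)) / 100
  expect_lte(max(disp), vmax_mm_ms * 5 + 1e-9)
})

test_that("particles leaving the grid are frozen and flagged", {
  fu <- make_linear_field("uniform", velocity = c(100, 0, 0),
                          shape = c(8, 8, 8), spacing = 3)
  # box spans +/-10.5 mm; this particle exits through +x
  ps <- trace(fu, c(8, 0, 0), integration_config(0, 100, 5, "forward"))
  expect_equal(as.character(ps$status), "left_grid")
  expect_lte(ps$positions[1, 1], 10.5)
  expect_gte(ps$positions[1, 1], 8)
  # zero seeds: empty set, not an error
  ps0 <- trace(fu, matrix(numeric(0), 0, 3),
               integration_config(0, 100, 5))
  expect_equal(nrow(ps0$positions), 0L)
})

test_that("the final partial step lands exactly on t_end", {
  fu <- make_linear_field("uniform", velocity = c(100, 0, 0),
                          shape = c(40, 8, 8), spacing = 3)
  ps <- trace(fu, c(-55, 0, 0), integration_config(0, 52, 5, "forward"))
  expect_equal(unname(ps$positions[1, 1]), -55 + 52, tolerance = 1e-12)
  expect_equal(ps$times[length(ps$times)], 52)
  expect_error(integration_config(0, 10, timestep = 0), "positive")
  f2 <- make_linear_field("uniform", velocity = c(10, 0, 0))
  expect_error(trace(f2, c(0, 0, 0), integration_config(0, 0, 5)),
               "differ")
})

test_that("emission seeds particles per voxel per emission time", {
  ph <- fixture("tube_small", small_tube())
  region <- ph$seg$masks[1, , , ]
  nvox <- sum(region)
  em <- emit_particles(ph$field, region, window = c(500, 600),
                       interval = 25)
  expect_length(em, 4L)
  expect_equal(nrow(em[[1]]$positions), nvox)
  # interval larger than the window: a single emission
  em1 <- emit_particles(ph$field, region, window = c(500, 600),
                        interval = 250)
  expect_length(em1, 1L)
  # empty region: empty set
  expect_length(emit_particles(ph$field, region & FALSE,
                               window = c(500, 600)), 0L)
})

test_that("trajectory export round trips", {
  ph <- fixture("tube_small", small_tube())
  em <- emit_particles(ph$field, ph$seg$masks[1, , , ],
                       window = c(500, 600), interval = 250)
  ps <- em[[1]]
  csv <- withr::local_tempfile(fileext = ".csv")
  export_trajectories(ps, csv)
  tj <- read_trajectories(csv)
  n <- nrow(ps$positions); ns <- dim(ps$trajectories)[1]
  expect_equal(nrow(tj), n * ns)
  expect_equal(tj$x[tj$particle == 2], ps$trajectories[, 2, 1])
  vtk <- withr::local_tempfile(fileext = ".vtk")
  export_trajectories(ps, vtk, format = "vtk")
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET POLYDATA")
  expect_match(lines[5], sprintf("POINTS %d float", n * ns))
})
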