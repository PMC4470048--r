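test_that("plug tube stroke volume has the stated closed form", {
  # sharp wall: SV = pi R^2 * (2/pi) * v_peak * T_sys
  ph <- make_plug_tube(radius = 15, v_peak = 50, systole_duration = 300,
                       wall_width = 0)
  expect_equal(ph$truth$true_sv_ml,
               pi * 15^2 * (2 / pi) * 500 * 0.3 / 1000, tolerance = 1e-12)
  # ramped wall: effective area pi (R^2 + w^2/12)
  ph2 <- make_plug_tube(radius = 15, wall_width = 6)
  expect_equal(ph2$truth$effective_area_mm2, pi * (15^2 + 3),
               tolerance = 1e-12)
  expect_error(make_plug_tube(radius = 30), "radius larger")
})

test_that("null-flow tube gives zero SV and zero KE", {
  ph <- make_plug_tube(v_peak = 0)
  expect_equal(ph$truth$true_sv_ml, 0)
  expect_true(all(ph$truth$ke_curve_mJ == 0))
  expect_true(all(ph$field$velocities == 0))
})

test_that("tube flux is independent of the cross-section position", {
  ph <- fixture("tube_default", make_plug_tube())
  roi2 <- planar_roi(ph$roi$point + c(9, 0, 0), ph$roi$normal,
                     ph$roi$contours[[1]])
  f1 <- flux_2d(resample_plane_from_4d(ph$field, ph$roi), ph$roi)
  f2 <- flux_2d(resample_plane_from_4d(ph$field, roi2), roi2)
  expect_lt(abs(f2$sv - f1$sv) / f1$sv, 0.001)
})

test_that("contracting ellipsoid has the prescribed volumes and flux", {
  ph <- fixture("ellipsoid80", make_contracting_ellipsoid())
  vv <- voxel_volume(ph$field) / 1000
  ed_ml <- ph$seg$volumes[ph$seg$ed_index] * vv
  es_ml <- ph$seg$volumes[ph$seg$es_index] * vv
  expect_lt(abs(ed_ml - 140), 140 * 0.015)
  expect_lt(abs(es_ml - 60), 60 * 0.015)
  expect_lt(abs((ed_ml - es_ml) - 80), 80 * 0.015)
  expect_equal(ph$seg$ed_index, 1L)
  expect_equal(ph$seg$es_index, 15L)
  # constructed truth sits within one voxel of the requested 80 ml
  expect_lt(abs(ph$truth$true_sv_ml - 80), vv)
  # and agrees with the continuous ellipsoid-cap calculation
  expect_lt(abs(ph$truth$analytic_cap_sv_ml - 80) / 80, 0.01)
  # numerically integrated aortic-plane flux over systole = 80 ml +/- 2%
  fs <- flux_2d(resample_plane_from_4d(ph$field, ph$roi_aortic),
                ph$roi_aortic)
  sv <- flux_stroke_volume(fs, seq_len(ph$truth$systole_frames + 1))
  expect_lt(abs(sv - 80) / 80, 0.02)
})

test_that("zero-stroke-volume ellipsoid is static", {
  ph <- make_contracting_ellipsoid(target_sv = 0, v_ed = 140)
  expect_equal(ph$truth$true_sv_ml, 0)
  expect_true(all(ph$field$velocities == 0))
  for (t in c(5, 20, 35))
    expect_identical(ph$seg$masks[t, , , ], ph$seg$masks[1, , , ])
})

test_that("Hill vortex has exact volume and a continuous boundary", {
  hv <- fixture("hill", make_hill_vortex())
  expect_equal(hv$truth$true_vortex_volume_ml, 4 / 3 * pi * 20^3 / 1000,
               tolerance = 1e-12)
  expect_equal(hv$truth$true_vortex_volume_ml, 33.51, tolerance = 1e-4)
  # volume ground truth does not depend on the translation speed
  hv0 <- make_hill_vortex(translation = 0, nt = 4, cycle_length = 40,
                          shape = c(24, 24, 24), center0 = c(0, 0, 0))
  expect_equal(hv0$truth$true_vortex_volume_ml,
               hv$truth$true_vortex_volume_ml)
  # closed-form velocity is continuous across the sphere
  set.seed(1)
  theta <- runif(200, 0, pi); phi <- runif(200, 0, 2 * pi)
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  vin <- hill_vortex_velocity(dirs * 20 * (1 - 1e-9), c(0, 0, 0), 20, 10)
  vout <- hill_vortex_velocity(dirs * 20 * (1 + 1e-9), c(0, 0, 0), 20, 10)
  expect_lt(max(abs(vin - vout)), 1e-6)
  expect_error(make_hill_vortex(a = 40), "not fully inside")
})

test_that("corruption wraps, adds noise and backgrounds as specified", {
  f <- velocity_field(array(120, dim = c(2, 2, 2, 2, 3)), c(3, 3, 3),
                      25, venc = 100)
  wr <- corrupt_field(f, wrap = TRUE)
  expect_equal(unname(wr$field$velocities[1, 1, 1, 1, 1]), -80)
  expect_true(all(wr$truth$wrap_mask))
  # identity: no wrap, no noise, zero coefficients
  ph <- fixture("tube_small", small_tube())
  idc <- corrupt_field(ph$field, wrap = FALSE, noise_sigma = 0,
                       background = matrix(0, 3, 4))
  expect_equal(idc$field$velocities, ph$field$velocities)
  # determinism under a fixed seed
  c1 <- corrupt_field(ph$field, noise_sigma = 3, seed = 11)
  c2 <- corrupt_field(ph$field, noise_sigma = 3, seed = 11)
  expect_identical(c1$field$velocities, c2$field$velocities)
  c3 <- corrupt_field(ph$field, noise_sigma = 3, seed = 12)
  expect_false(identical(c1$field$velocities, c3$field$velocities))
  expect_error(corrupt_field(ph$field, noise_sigma = -1), "non-negative")
})

test_that("respiratory displacement shifts the field periodically", {
  ph <- fixture("tube_small", small_tube())
  sh <- apply_respiratory_shift(ph$field, amplitude = 3, period = 400,
                                axis = "y")
  expect_equal(dim(sh$velocities), dim(ph$field$velocities))
  expect_false(identical(sh$velocities, ph$field$velocities))
  # zero amplitude is the identity
  sh0 <- apply_respiratory_shift(ph$field, amplitude = 0, period = 400)
  expect_equal(sh0$velocities, ph$field$velocities)
})
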