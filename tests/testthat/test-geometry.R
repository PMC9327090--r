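test_that("canonical solids give exact volumes, areas and sections", {
  cube <- make_cube(100)                        # 1 dm side
  expect_equal(mesh_volume(cube), 1)
  expect_equal(mesh_surface_area(cube), 6)
  sec <- plane_section(cube, 50)
  expect_equal(sec$area, 1, tolerance = 1e-12)
  expect_equal(sec$perimeter, 40, tolerance = 1e-12)
  tetra <- make_tetra(100)                      # unit simplex in dm
  expect_equal(mesh_volume(tetra), 1 / 6, tolerance = 1e-12)
})

test_that("icosphere measurements approach the analytic sphere from below", {
  sph <- make_icosphere(100, 3)
  vol <- mesh_volume(sph)
  expect_lt(vol, 4 * pi / 3)
  expect_gt(vol, 4 * pi / 3 * 0.99)
  area <- mesh_surface_area(sph)
  expect_lt(area, 4 * pi)
  expect_gt(area, 4 * pi * 0.99)
  eq <- plane_section(sph, 0)
  expect_lt(eq$perimeter, 2 * pi * 10)
  expect_gt(eq$perimeter, 2 * pi * 10 * 0.99)
  expect_lt(eq$area, pi)
  expect_gt(eq$area, pi * 0.99)
})

test_that("measures are rigid-invariant and scale-covariant", {
  sph <- make_icosphere(80, 2)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- transform_mesh(sph, R, c(40, -3, 17))
  expect_equal(mesh_volume(rot), mesh_volume(sph), tolerance = 1e-9)
  expect_equal(mesh_surface_area(rot), mesh_surface_area(sph),
               tolerance = 1e-9)
  big <- sph
  big$vertices <- big$vertices * 2
  expect_equal(mesh_volume(big), 8 * mesh_volume(sph), tolerance = 1e-9)
  expect_equal(mesh_surface_area(big), 4 * mesh_surface_area(sph),
               tolerance = 1e-9)
  s1 <- plane_section(sph, 10)
  s2 <- plane_section(big, 20)
  expect_equal(s2$perimeter, 2 * s1$perimeter, tolerance = 1e-9)
})

test_that("a section plane through a vertex is nudged and stays stable", {
  sph <- make_icosphere(100, 2)
  zv <- sph$vertices[5, 3]
  sec <- plane_section(sph, zv)
  ref <- plane_section(sph, zv + 0.5)
  expect_equal(sec$perimeter, ref$perimeter, tolerance = 0.02)
})

test_that("phantom diameters recover the configured half-axes", {
  lay <- default_layout()
  cfg <- small_phantom_config(quiet_duration = 6)
  ph <- generate_phantom(cfg)
  fr <- phantom_frame(ph, 1L)
  d <- level_diameters(fr, lay, "xiphoid")
  expect_equal(d$AP, 2 * cfg$b0[4] / 10, tolerance = 1e-9)
  expect_equal(d$ML, 2 * cfg$a0[4] / 10, tolerance = 1e-9)
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d2 <- level_diameters(fr %*% t(R), lay, "xiphoid")
  expect_equal(d2$AP, d$AP, tolerance = 1e-9)
  expect_equal(d2$ML, d$ML, tolerance = 1e-9)
})

test_that("trunk height is the virtual top-bottom distance in cm", {
  lay <- default_layout()
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  closed <- add_closure_markers(phantom_frame(ph, 1L), lay, "trunk")
  expect_equal(trunk_height(closed), 40, tolerance = 1e-9)
  shifted <- add_closure_markers(
    phantom_frame(ph, 1L) + matrix(c(0, 0, 123), 89, 3, byrow = TRUE),
    lay, "trunk")
  expect_equal(trunk_height(shifted), 40, tolerance = 1e-9)
})

test_that("shape factors reproduce worked ratios", {
  summary <- list(
    AP = list(louis_angle = 19.8, xiphoid = 23.2, umbilicus = 22.7),
    ML = list(louis_angle = 27.7, xiphoid = 27.5, umbilicus = 27.4),
    perimeter = c(louis_angle = 92.2, xiphoid = 90.1, umbilicus = 82.5),
    surface_area = 45.6, CW_obj = 23.2, trunk_height = 42.5)
  sf <- shape_factors(summary)
  expect_equal(unname(sf$ap_ml_ratio[["louis_angle"]]), 0.7148,
               tolerance = 1e-4)
  expect_equal(sf$height_to_perimeter_xiphoid, 0.4717, tolerance = 1e-4)
  expect_equal(sf$surface_to_volume, 4560 / 23200, tolerance = 1e-6)
})

test_that("validation errors follow the signed gold-minus-model convention", {
  e <- volume_error(21.70, 20.73)
  expect_equal(e$absolute, 0.97, tolerance = 1e-9)
  expect_equal(e$percent, 0.97 / 21.70 * 100, tolerance = 1e-9)
  expect_equal(volume_error(5, 5)$percent, 0)
  expect_lt(volume_error(1, 1.011)$absolute, 0)   # model above gold: negative
  expect_error(volume_error(0, 1), "positive")
})

test_that("the phase geometry summary is internally consistent", {
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6,
                                              jitter_sd = 1, seed = 11))
  g <- geometry_summary(ph$traj, 1L, phase = "FRC")
  expect_equal(g$CW_sum, g$RCp + g$RCa + g$AB, tolerance = 1e-12)
  expect_true(all(unlist(g[c("RCp", "RCa", "AB", "CW_sum", "CW_obj",
                             "trunk_height", "surface_area")]) > 0))
  expect_true(all(g$perimeter > 0) && all(g$section_area > 0))
  # smoothed object volume is below the level-0 marker volume
  g0 <- geometry_summary(ph$traj, 1L, phase = "FRC", level = 0L)
  expect_lt(g$CW_obj, g0$CW_obj)
})
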