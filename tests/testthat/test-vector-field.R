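test_that("displacement fields follow the basic contracts", {
  sph <- make_icosphere(100, 2)
  vf0 <- build_vector_field(sph, sph, "FRC:FRCVT")
  expect_true(all(vf0$modulus == 0))
  moved <- transform_mesh(sph, diag(3), c(0, 0, 10))
  vf1 <- build_vector_field(sph, moved, "FRC:FRCVT")
  expect_equal(vf1$modulus, rep(1, nrow(sph$vertices)), tolerance = 1e-12)
  other <- make_icosphere(100, 1)
  expect_error(build_vector_field(sph, other), "topolog")
})

test_that("inward motion gets a negative sign, outward positive", {
  sph <- make_icosphere(100, 2)
  grow <- sph; grow$vertices <- sph$vertices * 1.1
  shrink <- sph; shrink$vertices <- sph$vertices * 0.9
  vf_out <- assign_signs(build_vector_field(sph, grow), sph)
  expect_true(all(vf_out$modulus > 0))
  expect_equal(vf_out$modulus, rep(1, nrow(sph$vertices)), tolerance = 1e-9)
  vf_in <- assign_signs(build_vector_field(sph, shrink), sph)
  expect_true(all(vf_in$modulus < 0))
  expect_equal(vf_in$modulus, rep(-1, nrow(sph$vertices)), tolerance = 1e-9)
  # zero-motion vertices keep modulus zero, not a flipped sign
  mixed <- grow
  mixed$vertices[1:5, ] <- sph$vertices[1:5, ]
  vf_m <- assign_signs(build_vector_field(sph, mixed), sph)
  expect_true(all(vf_m$modulus[1:5] == 0))
  expect_true(all(vf_m$modulus[-(1:5)] > 0))
})

test_that("winding-number signs agree with the ray-casting oracle", {
  sph <- make_icosphere(100, 2)
  set.seed(42)
  pts <- matrix(rnorm(300, sd = 80), ncol = 3)
  wn_in <- winding_number(pts, sph) > 0.5
  rc_in <- point_in_mesh_raycast(pts, sph)
  expect_identical(wn_in, rc_in)
  # also on the (non-spherical) trunk mesh
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  trunk <- phantom_trunk_mesh(ph, 1L)
  ctr <- colMeans(trunk$vertices)
  set.seed(43)
  pts2 <- sweep(matrix(rnorm(300, sd = 150), ncol = 3), 2, ctr, "+")
  expect_identical(winding_number(pts2, trunk) > 0.5,
                   point_in_mesh_raycast(pts2, trunk))
})

test_that("swapping the meshes negates vectors; signs follow the new start", {
  sph <- make_icosphere(100, 2)
  grow <- sph; grow$vertices <- sph$vertices * 1.08
  fwd <- assign_signs(build_vector_field(sph, grow), sph)
  bwd <- assign_signs(build_vector_field(grow, sph), grow)
  expect_equal(bwd$end - bwd$start, -(fwd$end - fwd$start), tolerance = 1e-12)
  expect_true(all(fwd$modulus > 0))
  expect_true(all(bwd$modulus < 0))
  expect_equal(abs(bwd$modulus), abs(fwd$modulus), tolerance = 1e-12)
})

test_that("rigid motion of both meshes leaves moduli and signs unchanged", {
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  frames <- truth_phase_frames(small_phantom_config())
  mA <- phantom_trunk_mesh(ph, frames$FRC, level = 1L)
  mB <- phantom_trunk_mesh(ph, frames$FRCVT, level = 1L)
  vf <- assign_signs(build_vector_field(mA, mB), mA)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d <- c(100, -50, 20)
  vf2 <- assign_signs(
    build_vector_field(transform_mesh(mA, R, d), transform_mesh(mB, R, d)),
    transform_mesh(mA, R, d))
  expect_equal(abs(vf2$modulus), abs(vf$modulus), tolerance = 1e-9)
  # signs are stable wherever the motion is not vanishingly small
  # (endpoints within ~a hundredth of a millimetre of the surface may
  # classify either way under coordinate changes)
  clear <- abs(vf$modulus) > 1e-2
  expect_gt(mean(clear), 0.9)
  expect_equal(sign(vf2$modulus[clear]), sign(vf$modulus[clear]))
})

test_that("joint normalization preserves zero and relative scale", {
  sph <- make_icosphere(50, 1)
  mk_vf <- function(moduli) {
    vf <- build_vector_field(sph, sph)
    vf$modulus <- rep_len(moduli, length(vf$modulus))
    vf$signed <- TRUE
    vf
  }
  n1 <- normalize_fields(list(mk_vf(c(-2, 1, 4))))
  expect_equal(sort(unique(n1$fields[[1]]$modulus)), c(-0.5, 0.25, 1))
  expect_equal(n1$scale, 4)
  # two subjects: the weaker subject stays at half scale
  n2 <- normalize_fields(list(mk_vf(3), mk_vf(1.5)))
  expect_equal(unique(n2$fields[[1]]$modulus), 1)
  expect_equal(unique(n2$fields[[2]]$modulus), 0.5)
  expect_warning(nz <- normalize_fields(list(mk_vf(0))), "zero")
  expect_equal(nz$scale, 0)
})

test_that("mesh interpolation is the linear vertex blend", {
  sph <- make_icosphere(60, 1)
  grow <- sph; grow$vertices <- sph$vertices * 1.2
  expect_equal(interpolate_meshes(sph, grow, 0)$vertices, sph$vertices)
  expect_equal(interpolate_meshes(sph, grow, 1)$vertices, grow$vertices)
  expect_equal(interpolate_meshes(sph, grow, 0.5)$vertices,
               (sph$vertices + grow$vertices) / 2, tolerance = 1e-12)
  expect_error(interpolate_meshes(sph, grow, 1.2), "alpha")
})

test_that("vector fields round-trip through the text format", {
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6,
                                              jitter_sd = 1, seed = 12))
  cfg <- small_phantom_config()
  frames <- truth_phase_frames(cfg)
  mA <- phantom_trunk_mesh(ph, frames$FRC, level = 1L)
  mB <- phantom_trunk_mesh(ph, frames$FRCVT, level = 1L)
  vf <- assign_signs(build_vector_field(mA, mB, "FRC:FRCVT", "s1"), mA)
  expect_equal(length(vf$modulus), 548L)
  tf <- tempfile(fileext = ".txt")
  export_vector_field(vf, tf)
  lines <- readLines(tf)
  fsep <- grep("^# faces", lines)
  hdr <- grep("^id ", lines)
  expect_equal(fsep - hdr - 1L, 548L)           # one data row per vertex
  expect_true(any(grepl("phase_pair=FRC:FRCVT", lines)))
  expect_true(any(grepl("units=", lines)))
  back <- import_vector_field(tf)
  expect_lt(max(abs(back$start - unname(vf$start))), 1e-5)
  expect_lt(max(abs(back$end - unname(vf$end))), 1e-5)
  expect_lt(max(abs(back$modulus - unname(vf$modulus))), 1e-5)
  expect_identical(back$faces, unname(vf$faces))
  expect_equal(back$phase_pair, "FRC:FRCVT")
  expect_true(back$signed)
})
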