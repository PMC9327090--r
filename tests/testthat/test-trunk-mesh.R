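test_that("virtual closure markers are recomputable means of their subsets", {
  lay <- default_layout()
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6,
                                              jitter_sd = 1, seed = 5))
  fr <- phantom_frame(ph, 1L)
  closed <- add_closure_markers(fr, lay, "trunk")
  expect_equal(nrow(closed$original) + nrow(closed$virtual), 93L)
  mk <- lay$markers
  sheet <- mk$region %in% c("front", "back")
  expect_equal(unname(closed$virtual["top", ]),
               unname(colMeans(fr[sheet & mk$row == 1, ])))
  expect_equal(unname(closed$virtual["bottom", ]),
               unname(colMeans(fr[sheet & mk$row == 7, ])))
  right_cols <- (mk$region == "front" & mk$col == 1) |
    (mk$region == "back" & mk$col == lay$back_cols)
  expect_equal(unname(closed$virtual["right", ]),
               unname(colMeans(fr[right_cols, ])))
  # symmetric top row example: mean of symmetric points is the centroid
  sq <- rbind(c(10, 5, 400), c(-10, 5, 400), c(10, -5, 400), c(-10, -5, 400))
  expect_equal(colMeans(sq), c(0, 0, 400))
})

test_that("compartment closures are local to the compartment rows", {
  lay <- default_layout()
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  fr <- phantom_frame(ph, 1L)
  v1 <- add_closure_markers(fr, lay, "RCp")$virtual
  fr2 <- fr
  ab_rows <- setdiff(lay$compartment_rows$AB, lay$compartment_rows$RCa)
  sel <- lay$markers$row %in% ab_rows
  fr2[sel, ] <- fr2[sel, ] + 50
  v2 <- add_closure_markers(fr2, lay, "RCp")$virtual
  expect_identical(v1, v2)
})

test_that("reference levels are row means at the configured rows", {
  lay <- default_layout()
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  fr <- phantom_frame(ph, 1L)
  lv <- compute_reference_levels(fr, lay)
  cfg <- small_phantom_config()
  expect_equal(lv$z_louis, cfg$z_rows[2], tolerance = 1e-9)
  expect_equal(lv$z_xiphoid, cfg$z_rows[4], tolerance = 1e-9)
  expect_equal(lv$z_umbilicus, cfg$z_rows[6], tolerance = 1e-9)
  expect_true(lv$z_louis > lv$z_xiphoid && lv$z_xiphoid > lv$z_umbilicus)
  # arithmetic mean over the row: perturb the xiphoid row symmetrically
  xr <- which(lay$markers$row == 4)
  fr2 <- fr
  fr2[xr[1], 3] <- fr2[xr[1], 3] + 2
  fr2[xr[2], 3] <- fr2[xr[2], 3] - 2
  expect_equal(compute_reference_levels(fr2, lay)$z_xiphoid, lv$z_xiphoid)
})

test_that("the trunk mesh hits the canonical counts and invariants", {
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  m <- phantom_trunk_mesh(ph, 1L)
  chk <- mesh_check(m)
  expect_equal(nrow(m$vertices), 93L)
  expect_equal(nrow(m$faces), 182L)   # forced by Euler: F = 2V - 4
  expect_equal(chk$n_edges, 273L)     # E = 3V - 6
  expect_true(chk$watertight)
  expect_equal(chk$euler, 2L)
  expect_gt(chk$signed_volume_mm3, 0)
})

test_that("compartment meshes are watertight and cover the trunk", {
  lay <- default_layout()
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  fr <- phantom_frame(ph, 1L)
  vols <- c()
  for (cp in c("RCp", "RCa", "AB")) {
    m <- build_compartment_mesh(fr, lay, cp)
    chk <- mesh_check(m)
    expect_true(chk$watertight)
    expect_equal(chk$euler, 2L)
    vols[cp] <- mesh_volume(m)
  }
  trunk <- mesh_volume(phantom_trunk_mesh(ph, 1L))
  # sum of compartments approximates (but need not equal) the trunk object
  expect_lt(abs(sum(vols) / trunk - 1), 0.05)
  # RCp original vertices all come from rows 1..xiphoid
  rcp <- build_compartment_mesh(fr, lay, "RCp")
  n_orig <- sum(lay$markers$row %in% lay$compartment_rows$RCp)
  lab <- names(rcp$origin_ids)[seq_len(n_orig)]
  expect_true(all(lay$markers$row[match(lab, lay$markers$label)] <=
                    lay$level_rows[["xiphoid"]]))
})

test_that("mesh construction is rigid-equivariant and topology is static", {
  lay <- default_layout()
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6,
                                              jitter_sd = 1, seed = 6))
  fr <- phantom_frame(ph, 1L)
  m1 <- build_trunk_mesh(add_closure_markers(fr, lay, "trunk"), lay)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d <- c(12, -7, 30)
  fr_t <- fr %*% t(R) + matrix(d, nrow(fr), 3, byrow = TRUE)
  m2 <- build_trunk_mesh(add_closure_markers(fr_t, lay, "trunk"), lay)
  expect_identical(m1$faces, m2$faces)
  expect_equal(m2$vertices,
               m1$vertices %*% t(R) + matrix(d, 93, 3, byrow = TRUE),
               tolerance = 1e-9)
  # different frames share the face matrix
  m3 <- phantom_trunk_mesh(ph, 5L)
  expect_identical(m1$faces, m3$faces)
})

test_that("the frame-wise volume trace matches per-frame mesh volumes", {
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6,
                                              jitter_sd = 1, seed = 8))
  tr <- chest_volume_trace(ph$traj)
  for (fr in c(1L, 10L, 50L))
    expect_equal(tr$V[fr], mesh_volume(phantom_trunk_mesh(ph, fr)),
                 tolerance = 1e-12)
})
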