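test_that("the breathing waveform follows the declared phase convention", {
  cfg <- small_phantom_config()
  f <- cfg$f
  expect_equal(breathing_waveform(0, cfg), 0)
  expect_equal(breathing_waveform(1 / (4 * f), cfg), 1)
  # continuity across the quiet-to-maneuver junction
  t0 <- cfg$maneuver_start
  expect_equal(breathing_waveform(t0 - 1e-8, cfg),
               breathing_waveform(t0 + 1e-8, cfg), tolerance = 1e-5)
  # the forced expiration dips below anything seen during quiet breathing
  tq <- seq(0, t0 - 0.01, by = 0.01)
  tm <- seq(t0, cfg$duration, by = 0.01)
  expect_lt(min(breathing_waveform(tm, cfg)), min(breathing_waveform(tq, cfg)))
  # TLC excursion exceeds the tidal excursion
  expect_gt(max(breathing_waveform(tm, cfg)), max(breathing_waveform(tq, cfg)))
})

test_that("analytic volume matches closed forms", {
  lay <- default_layout()
  # static elliptic cylinder: pi * a * b * H
  cfg <- phantom_config(lay, H = 400, a0 = 100, b0 = 150,
                        eps = c(RCp = 0, RCa = 0, AB = 0),
                        quiet_duration = 8, sample_rate = 20, jitter_sd = 0)
  expect_equal(analytic_chest_volume(cfg, 0), pi * 100 * 150 * 400 / 1e6,
               tolerance = 1e-12)
  expect_equal(analytic_chest_volume(cfg, 0), 18.85, tolerance = 1e-3)
  # uniform radial amplitude: peak-to-trough Delta V = 4 eps V0 exactly
  eps <- 0.0125
  cfg2 <- phantom_config(lay, H = 400, a0 = 100, b0 = 150,
                         eps = c(RCp = eps, RCa = eps, AB = eps),
                         quiet_duration = 8, sample_rate = 20, jitter_sd = 0)
  V0 <- pi * 100 * 150 * 400 / 1e6
  f <- cfg2$f
  dV <- analytic_chest_volume(cfg2, 1 / (4 * f)) -
    analytic_chest_volume(cfg2, 3 / (4 * f))
  expect_equal(dV, 4 * eps * V0, tolerance = 1e-12)
  # doubling all linear dimensions scales the volume by 8
  cfg3 <- phantom_config(lay, H = 800, a0 = 200, b0 = 300,
                         eps = c(RCp = 0, RCa = 0, AB = 0),
                         quiet_duration = 8, sample_rate = 20, jitter_sd = 0)
  expect_equal(analytic_chest_volume(cfg3, 0),
               8 * analytic_chest_volume(cfg, 0), tolerance = 1e-12)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_phantom(small_phantom_config(seed = 9, jitter_sd = 1,
                                             quiet_duration = 6))
  b <- generate_phantom(small_phantom_config(seed = 9, jitter_sd = 1,
                                             quiet_duration = 6))
  expect_identical(a$traj$positions, b$traj$positions)
  c <- generate_phantom(small_phantom_config(seed = 10, jitter_sd = 1,
                                             quiet_duration = 6))
  expect_false(identical(a$traj$positions, c$traj$positions))
})

test_that("compartment traces sum to the total volume at every instant", {
  ph <- generate_phantom(small_phantom_config(quiet_duration = 6))
  tot <- with(ph$truth$compartments, RCp + RCa + AB)
  expect_equal(tot, ph$truth$V, tolerance = 1e-12)
})

test_that("a paradox-flagged compartment moves inward during inspiration", {
  cfg <- small_phantom_config(paradox_flags = "RCa", quiet_duration = 6)
  ph <- generate_phantom(cfg)
  lay <- ph$traj$layout
  frames <- truth_phase_frames(cfg)
  rca_rows <- lay$compartment_rows$RCa
  sel <- which(lay$markers$row %in% rca_rows)
  r_frc <- sqrt(rowSums(phantom_frame(ph, frames$FRC)[sel, 1:2]^2))
  r_vt <- sqrt(rowSums(phantom_frame(ph, frames$FRCVT)[sel, 1:2]^2))
  # radial coordinate decreases as the waveform increases
  expect_true(all(r_vt < r_frc))
  # non-flagged abdominal interior rows still move outward
  ab_only <- setdiff(lay$compartment_rows$AB, lay$compartment_rows$RCa)
  sel_ab <- which(lay$markers$row %in% ab_only)
  expect_true(all(
    sqrt(rowSums(phantom_frame(ph, frames$FRCVT)[sel_ab, 1:2]^2)) >
    sqrt(rowSums(phantom_frame(ph, frames$FRC)[sel_ab, 1:2]^2))))
})

test_that("full left-right asymmetry leaves the left sheet static", {
  cfg <- small_phantom_config(asymmetry = 0, quiet_duration = 6)
  ph <- generate_phantom(cfg)
  lay <- ph$traj$layout
  frames <- truth_phase_frames(cfg)
  ang <- lay$markers$angle
  left <- which(ang > 90 & ang < 270)
  right <- which(ang < 90 | ang > 270)
  d_left <- phantom_frame(ph, frames$FRCVT)[left, ] -
    phantom_frame(ph, frames$FRC)[left, ]
  d_right <- phantom_frame(ph, frames$FRCVT)[right, ] -
    phantom_frame(ph, frames$FRC)[right, ]
  expect_lt(max(abs(d_left)), 1e-9)
  expect_gt(max(abs(d_right)), 0.5)
})

test_that("marker-sampled mesh volume tracks analytic truth within 5%", {
  cfg <- small_phantom_config(seed = 2, jitter_sd = 1, quiet_duration = 6)
  ph <- generate_phantom(cfg)
  for (fr in c(1L, truth_phase_frames(cfg)$FRCVT)) {
    m <- phantom_trunk_mesh(ph, fr)
    truth <- analytic_chest_volume(cfg, ph$truth$t[fr])
    expect_lt(abs(mesh_volume(m) / truth - 1), 0.05)
  }
})
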