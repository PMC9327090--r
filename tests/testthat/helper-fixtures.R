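# Fixtures are generated in code: canonical solids with known geometry and
# small, fast phantom configurations.

make_cube <- function(side = 100) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  m <- orient_mesh(list(vertices = v, faces = f))
  trimesh(m$vertices, m$faces)
}

make_tetra <- function(scale = 100) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  m <- orient_mesh(list(vertices = v, faces = f))
  trimesh(m$vertices, m$faces)
}

# Icosphere by midpoint refinement of an icosahedron.
make_icosphere <- function(radius = 100, refinements = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (i in seq_len(refinements)) {
    nv <- nrow(v)
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    k <- (pmin(e[, 1], e[, 2]) - 1) * nv + pmax(e[, 1], e[, 2])
    uk <- unique(k)
    mid <- (v[e[!duplicated(k), 1], ] + v[e[!duplicated(k), 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    mi <- nv + match(k, uk)
    nf <- nrow(f)
    m1 <- mi[seq_len(nf)]
    m2 <- mi[nf + seq_len(nf)]
    m3 <- mi[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
    v <- rbind(v, mid)
  }
  trimesh(v * radius, f)
}

# Small, fast phantom: a few quiet breaths plus the capacity maneuver.
small_phantom_config <- function(seed = 1, jitter_sd = 0, ...,
                                 quiet_duration = 20, sample_rate = 20) {
  phantom_config(default_layout(), quiet_duration = quiet_duration,
                 sample_rate = sample_rate, jitter_sd = jitter_sd,
                 seed = seed, ...)
}

phantom_frame <- function(ph, frame = 1L) {
  p <- ph$traj$positions[frame, , ]
  dim(p) <- c(dim(ph$traj$positions)[2], 3L)
  p
}

# Frame indices where the quiet waveform hits its extremes (ground truth).
truth_phase_frames <- function(cfg) {
  sr <- cfg$sample_rate
  list(FRC = 1L + round(3 / (4 * cfg$f) * sr),
       FRCVT = 1L + round(1 / (4 * cfg$f) * sr))
}

# Level-`level` trunk mesh at one frame.
phantom_trunk_mesh <- function(ph, frame, level = 0L) {
  lay <- ph$traj$layout
  m0 <- build_trunk_mesh(
    add_closure_markers(phantom_frame(ph, frame), lay, "trunk"), lay)
  if (level > 0L) subdivide(m0, level)$mesh else m0
}

# Write a trajectory CSV preserving NA cells (the package writer refuses
# incomplete positions by design).
write_trajectories_na <- function(traj, path) {
  d <- dim(traj$positions)
  cols <- list(time = (seq_len(d[1]) - 1) / traj$sample_rate)
  for (j in seq_len(d[2])) for (ax in 1:3)
    cols[[paste0(traj$labels[j], "_", c("X", "Y", "Z")[ax])]] <-
      traj$positions[, j, ax]
  con <- file(path, "w")
  writeLines(c("# unit=mm", paste0("# sample_rate=", traj$sample_rate)), con)
  utils::write.csv(as.data.frame(cols, check.names = FALSE), con,
                   row.names = FALSE, quote = FALSE)
  close(con)
}

# Exhaustive two-sided Mann-Whitney oracle by complete enumeration.
mwu_brute_force <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  w0 <- sum(r[seq_len(n)])
  W <- apply(utils::combn(length(r), n), 2, function(s) sum(r[s]))
  min(1, 2 * min(mean(W <= w0 + 1e-9), mean(W >= w0 - 1e-9)))
}
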