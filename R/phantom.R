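#' Synthetic breathing-torso phantom configuration
#'
#' The phantom is a stack of elliptic cross-sections (one band per marker
#' row) whose half-axes oscillate with a breathing waveform: a quiet
#' sinusoidal phase followed by a maximal capacity maneuver (ramp to total
#' lung capacity, forced expiration to residual volume, recovery). Markers
#' are sampled at the layout's angular stations on each row's ellipse, so
#' every downstream stage can be tested against exact analytic volumes.
#'
#' Radial motion of a marker at angle theta in row r is
#' \code{r(t) = r0 * (1 + eps_r * side(theta) * w(t))}, where \code{eps_r}
#' is the row amplitude (mean of the compartment amplitudes covering the
#' row, sign-flipped for paradox-flagged compartments), \code{side} is 1 on
#' the right half and \code{asymmetry} on the left half, and \code{w} is
#' the breathing waveform. During quiet breathing \code{w} spans [-1, 1]
#' (end-expiration at -1), so the tidal excursion is 2 waveform units;
#' \code{tlc_gain} and \code{rv_gain} (> 1) set the maneuver extremes in
#' the same units.
#'
#' Defaults emulate an adult male seated acquisition: 19.3 L chest-wall
#' volume, tidal volume ~0.52 L split ~41/25/34\% over RCp/RCa/AB,
#' inspiratory capacity ~3.5 L, vital capacity ~4.5 L, 15 breaths/min,
#' 3 min of quiet breathing at 60 Hz, and 1 mm isotropic marker jitter.
#'
#' @param layout an \code{oep_layout}.
#' @param H trunk height (mm).
#' @param a0 mediolateral half-axis per row (mm; recycled over rows).
#' @param b0 anteroposterior half-axis per row (mm; recycled).
#' @param eps named per-compartment fractional breathing amplitudes
#'   (RCp, RCa, AB), dimensionless.
#' @param f breathing frequency (Hz).
#' @param quiet_duration quiet-breathing duration (s); the maneuver starts
#'   at the first completed breath cycle after it.
#' @param sample_rate acquisition rate (Hz).
#' @param tlc_gain,rv_gain maneuver excursions in quiet-amplitude units
#'   (both must exceed 1: TLC above the tidal peak, RV below quiet
#'   end-expiration).
#' @param ramp_up,ramp_down,ramp_recover,tail maneuver segment durations (s).
#' @param paradox_flags compartments whose amplitude sign is flipped
#'   (inward inspiratory motion, e.g. the Hoover-sign pattern).
#' @param asymmetry left/right amplitude ratio (1 = symmetric, 0 = left
#'   side static).
#' @param jitter_sd isotropic Gaussian marker noise sd (mm).
#' @param seed RNG seed for the jitter.
#' @return an object of class \code{oep_phantom_config}.
#' @export
phantom_config <- function(layout = default_layout(), H = 400,
                           a0 = 140, b0 = 110,
                           eps = c(RCp = 0.0055, RCa = 0.010, AB = 0.007),
                           f = 0.25, quiet_duration = 180, sample_rate = 60,
                           tlc_gain = 12.4, rv_gain = 4.8,
                           ramp_up = 3, ramp_down = 6, ramp_recover = 3,
                           tail = 2,
                           paradox_flags = character(),
                           asymmetry = 1, jitter_sd = 1, seed = 1L) {
  rows <- layout$rows
  a0 <- rep_len(a0, rows)
  b0 <- rep_len(b0, rows)
  if (!all(c("RCp", "RCa", "AB") %in% names(eps)))
    stop("eps must name RCp, RCa and AB")
  if (any(eps < 0)) stop("eps amplitudes must be non-negative")
  bad <- setdiff(paradox_flags, c("RCp", "RCa", "AB"))
  if (length(bad)) stop("unknown paradox_flags: ", paste(bad, collapse = ", "))
  if (tlc_gain <= 1) stop("tlc_gain must exceed 1 (TLC above tidal peak)")
  if (rv_gain <= 1) stop("rv_gain must exceed 1 (RV below end-expiration)")
  eps_signed <- eps
  eps_signed[paradox_flags] <- -eps_signed[paradox_flags]
  # row amplitude = mean over compartments containing the row
  eps_row <- vapply(seq_len(rows), function(r) {
    inc <- vapply(layout$compartment_rows,
                  function(rr) r %in% rr, logical(1))
    mean(eps_signed[names(layout$compartment_rows)[inc]])
  }, numeric(1))
  worst <- 1 - max(abs(eps_row)) * max(tlc_gain, rv_gain)
  if (worst <= 0)
    stop("amplitudes produce non-positive half-axes during the maneuver")
  maneuver_start <- ceiling(f * quiet_duration - 1e-9) / f
  duration <- maneuver_start + ramp_up + ramp_down + ramp_recover + tail
  z_rows <- H * (rows - seq_len(rows)) / (rows - 1)
  mids <- (z_rows[-rows] + z_rows[-1L]) / 2
  band_hi <- c(H, mids)
  band_lo <- c(mids, 0)
  structure(
    list(layout = layout, H = H, a0 = a0, b0 = b0,
         eps = eps, eps_row = eps_row, f = f,
         quiet_duration = quiet_duration, sample_rate = sample_rate,
         tlc_gain = tlc_gain, rv_gain = rv_gain, ramp_up = ramp_up,
         ramp_down = ramp_down, ramp_recover = ramp_recover, tail = tail,
         maneuver_start = maneuver_start, duration = duration,
         paradox_flags = paradox_flags, asymmetry = asymmetry,
         jitter_sd = jitter_sd, seed = as.integer(seed),
         z_rows = z_rows, band_lo = band_lo, band_hi = band_hi),
    class = "oep_phantom_config")
}

#' Breathing waveform of the phantom
#'
#' Unit sinusoid \code{sin(2 pi f t)} during quiet breathing (peak
#' inspiration at t = 1/(4f)), then a continuous piecewise-linear maneuver:
#' ramp to \code{+tlc_gain}, forced expiration to \code{-rv_gain},
#' recovery to 0. Total function of t (0 after the session ends).
#'
#' @param t time in seconds (vectorised).
#' @param config an \code{oep_phantom_config}.
#' @return waveform value(s).
#' @export
breathing_waveform <- function(t, config) {
  m0 <- config$maneuver_start
  k1 <- m0 + config$ramp_up
  k2 <- k1 + config$ramp_down
  k3 <- k2 + config$ramp_recover
  w <- numeric(length(t))
  quiet <- t < m0
  w[quiet] <- sin(2 * pi * config$f * t[quiet])
  up <- !quiet & t < k1
  w[up] <- config$tlc_gain * (t[up] - m0) / config$ramp_up
  dn <- t >= k1 & t < k2
  w[dn] <- config$tlc_gain -
    (config$tlc_gain + config$rv_gain) * (t[dn] - k1) / config$ramp_down
  rc <- t >= k2 & t < k3
  w[rc] <- -config$rv_gain * (1 - (t[rc] - k2) / config$ramp_recover)
  w
}

# Cross-section area (mm^2) of row r at waveform value w: two half-ellipses,
# right half scaled by (1 + eps_r w), left half by (1 + asymmetry eps_r w).
phantom_row_area <- function(config, r, w) {
  fr <- 1 + config$eps_row[r] * w
  fl <- 1 + config$asymmetry * config$eps_row[r] * w
  pi * config$a0[r] * config$b0[r] * (fr^2 + fl^2) / 2
}

# Volume (L) over a z interval, integrating piecewise-constant row bands.
phantom_volume_between <- function(config, w, z_lo, z_hi) {
  v <- numeric(length(w))
  for (r in seq_along(config$z_rows)) {
    ov <- max(0, min(config$band_hi[r], z_hi) - max(config$band_lo[r], z_lo))
    if (ov > 0) v <- v + phantom_row_area(config, r, w) * ov
  }
  v / 1e6
}

#' Analytic chest-wall volume of the phantom
#'
#' Closed-form volume of the stacked elliptic cross-sections
#' (piecewise-constant half-axes per row band), in litres.
#'
#' @param config an \code{oep_phantom_config}.
#' @param t time(s) in seconds.
#' @return volume(s) in L.
#' @export
analytic_chest_volume <- function(config, t) {
  if (any(config$a0 <= 0) || any(config$b0 <= 0))
    stop("non-positive half-axis in phantom config")
  phantom_volume_between(config, breathing_waveform(t, config), 0, config$H)
}

# z ranges of the three compartments (boundary at the shared row's height).
phantom_compartment_z <- function(config) {
  cr <- config$layout$compartment_rows
  z <- config$z_rows
  b1 <- z[cr$RCp[length(cr$RCp)]]
  b2 <- z[cr$RCa[length(cr$RCa)]]
  list(RCp = c(b1, config$H), RCa = c(b2, b1), AB = c(0, b2))
}

#' Generate a synthetic acquisition and its ground truth
#'
#' Samples markers at the layout's angular stations on each row's ellipse
#' for every frame, applies per-compartment amplitudes (with paradox and
#' asymmetry), adds isotropic Gaussian jitter, and returns the noise-free
#' analytic ground truth alongside.
#'
#' @param config an \code{oep_phantom_config}.
#' @return list with \code{traj} (an \code{oep_traj}) and \code{truth}, a
#'   list holding the analytic volume traces (total and per compartment,
#'   L), the waveform, the static volumes (RV, FRC, FRCVT, TLC) and the
#'   true ventilatory pattern (VT, IC, VC in L; RR in breaths/min).
#' @export
generate_phantom <- function(config) {
  layout <- config$layout
  n <- floor(config$duration * config$sample_rate) + 1L
  t <- (seq_len(n) - 1) / config$sample_rate
  w <- breathing_waveform(t, config)
  mk <- layout$markers
  theta <- mk$angle * pi / 180
  # right half expands with factor 1, left half with `asymmetry`;
  # markers exactly on the midline (theta = 90 or 270) take the mean
  side <- rep((1 + config$asymmetry) / 2, length(theta))
  side[cos(theta) > 1e-12] <- 1
  side[cos(theta) < -1e-12] <- config$asymmetry
  eps_m <- config$eps_row[mk$row] * side
  x0 <- config$a0[mk$row] * cos(theta)
  y0 <- config$b0[mk$row] * sin(theta)
  z0 <- config$z_rows[mk$row]
  m <- nrow(mk)
  pos <- array(0, c(n, m, 3L))
  fac <- 1 + outer(w, eps_m)            # n x m radial factors
  pos[, , 1] <- fac * matrix(x0, n, m, byrow = TRUE)
  pos[, , 2] <- fac * matrix(y0, n, m, byrow = TRUE)
  pos[, , 3] <- matrix(z0, n, m, byrow = TRUE)
  if (config$jitter_sd > 0) {
    runif(1)  # ensure RNG is initialised before saving its state
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(config$seed)
    pos <- pos + array(stats::rnorm(length(pos), 0, config$jitter_sd),
                       dim(pos))
  }
  traj <- marker_trajectories(pos, config$sample_rate, mk$label, layout)

  zc <- phantom_compartment_z(config)
  vc <- lapply(zc, function(zr)
    phantom_volume_between(config, w, zr[1], zr[2]))
  V <- vc$RCp + vc$RCa + vc$AB
  vol_at <- function(wv) phantom_volume_between(config, wv, 0, config$H)
  frc <- vol_at(-1); frcvt <- vol_at(1)
  tlc <- vol_at(config$tlc_gain); rv <- vol_at(-config$rv_gain)
  comp_delta <- function(w1, w2) vapply(zc, function(zr)
    phantom_volume_between(config, w2, zr[1], zr[2]) -
      phantom_volume_between(config, w1, zr[1], zr[2]), numeric(1))
  truth <- list(
    t = t, waveform = w, V = V,
    compartments = list(RCp = vc$RCp, RCa = vc$RCa, AB = vc$AB),
    RV = rv, FRC = frc, FRCVT = frcvt, TLC = tlc,
    VT = frcvt - frc, IC = tlc - frc, VC = tlc - rv,
    VT_comp = comp_delta(-1, 1), IC_comp = comp_delta(-1, config$tlc_gain),
    VC_comp = comp_delta(-config$rv_gain, config$tlc_gain),
    RR = 60 * config$f)
  list(traj = traj, truth = truth)
}
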