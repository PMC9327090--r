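#' Detect the four static respiratory volumes on a chest-wall volume trace
#'
#' Locates end-inspiration peaks and end-expiration troughs in the quiet
#' breathing window by prominence-based extremum detection on a low-pass
#' smoothed copy of the trace (moving mean over \code{smooth_window}
#' seconds; required prominence is 25\% of the median quiet-breath
#' excursion). The static volumes are then: FRC = median trough value,
#' FRCVT = median peak value (both robust to slow drift), TLC = global
#' maximum, RV = global minimum. Raw trace values at the detected indices
#' are reported.
#'
#' @param trace an \code{oep_volume_trace} (or data frame with \code{t}
#'   and \code{V} plus a \code{sample_rate} attribute).
#' @param quiet_window length of the quiet-breathing window (s) at the
#'   start of the trace; the capacity maneuver is expected after it.
#' @param smooth_window low-pass moving-mean length (s).
#' @return object of class \code{oep_phases}: list with \code{RV},
#'   \code{FRC}, \code{FRCVT}, \code{TLC} (L), their frame indices
#'   (\code{idx}), the quiet end-expiration indices
#'   (\code{breath_boundaries}) and peak indices (\code{breath_peaks}).
#' @export
detect_phases <- function(trace, quiet_window = NULL, smooth_window = 0.25) {
  sr <- attr(trace, "sample_rate")
  if (is.null(sr)) sr <- 1 / stats::median(diff(trace$t))
  V <- trace$V
  n <- length(V)
  if (any(!is.finite(V))) stop("volume trace contains non-finite values")
  k <- max(1L, round(smooth_window * sr))
  Vs <- stats::filter(V, rep(1 / k, k), sides = 2L)
  Vs[is.na(Vs)] <- V[is.na(Vs)]
  if (is.null(quiet_window)) {
    # unless told otherwise, end the quiet window shortly before the global
    # maximum (the capacity maneuver, when present, dominates the trace end)
    quiet_window <- trace$t[which.max(Vs)] - 0.1 * n / sr
    quiet_window <- max(quiet_window, 3)
  }
  qn <- min(n, max(2L, floor(quiet_window * sr)))
  Vq <- as.numeric(Vs[seq_len(qn)])
  exc <- stats::quantile(Vq, 0.95) - stats::quantile(Vq, 0.05)
  if (exc <= 0 || !is.finite(exc) || exc < 1e-9)
    stop("no breaths detected: quiet-window volume excursion is zero")
  prom <- 0.25 * exc
  peak_idx <- prominent_extrema(Vq, prom)
  trough_idx <- prominent_extrema(-Vq, prom)
  if (length(peak_idx) < 3L || length(trough_idx) < 3L)
    stop("fewer than 3 quiet breaths detected in the quiet window")
  frc <- stats::median(V[trough_idx])
  frcvt <- stats::median(V[peak_idx])
  tlc_idx <- which.max(V)   # global extrema are taken on the raw trace
  rv_idx <- which.min(V)
  tlc <- V[tlc_idx]
  rv <- V[rv_idx]
  if (tlc_idx <= qn)
    warning("global maximum (TLC) falls inside the quiet window; ",
            "was the capacity maneuver performed?")
  nearest <- function(val, cand) cand[which.min(abs(V[cand] - val))]
  out <- list(
    RV = rv, FRC = frc, FRCVT = frcvt, TLC = tlc,
    idx = c(RV = rv_idx, FRC = nearest(frc, trough_idx),
            FRCVT = nearest(frcvt, peak_idx), TLC = tlc_idx),
    breath_boundaries = trough_idx, breath_peaks = peak_idx,
    sample_rate = sr, quiet_window = qn / sr)
  class(out) <- "oep_phases"
  if (!(out$RV <= out$FRC && out$FRC < out$FRCVT && out$FRCVT <= out$TLC))
    stop("phase ordering violated (RV <= FRC < FRCVT <= TLC); ",
         "the global trace is paradoxical or the maneuver is missing")
  out
}

# Local maxima with topographic prominence >= min_prom: each peak's
# prominence is its height above the higher of the two valley minima
# separating it from the nearest higher terrain (or the trace ends).
prominent_extrema <- function(x, min_prom) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- min(x[(if (length(higher_l)) max(higher_l) else 1L):p])
    right <- x[p:n]
    higher_r <- which(right > h)
    rmin <- min(x[p:(p - 1L + (if (length(higher_r)) min(higher_r)
                               else n - p + 1L))])
    if (h - max(lmin, rmin) >= min_prom) keep[i] <- TRUE
  }
  cand[keep]
}

#' @export
print.oep_phases <- function(x, ...) {
  cat(sprintf(
    "Respiratory phases [L]: RV %.2f, FRC %.2f, FRCVT %.2f, TLC %.2f\n",
    x$RV, x$FRC, x$FRCVT, x$TLC))
  cat(sprintf("  %d quiet breaths detected\n",
              length(x$breath_boundaries) - 1L))
  invisible(x)
}

#' Ventilatory pattern from detected phases
#'
#' Tidal volume VT = FRCVT - FRC, inspiratory capacity IC = TLC - FRC,
#' vital capacity VC = TLC - RV; respiratory rate from the mean quiet
#' breath period (trough-to-trough); minute ventilation MV = VT x RR.
#'
#' @param phases an \code{oep_phases}.
#' @param trace the volume trace the phases were detected on (only its
#'   sample rate is needed; defaults to the rate stored in
#'   \code{phases}).
#' @return object of class \code{oep_pattern}: list with \code{VT},
#'   \code{IC}, \code{VC} (L), \code{RR} (breaths/min), \code{MV} (L/min).
#' @export
ventilatory_pattern <- function(phases, trace = NULL) {
  bb <- phases$breath_boundaries
  if (length(bb) < 2L) stop("fewer than 2 breath boundaries")
  sr <- phases$sample_rate
  period <- mean(diff(bb)) / sr
  rr <- 60 / period
  vt <- phases$FRCVT - phases$FRC
  out <- list(VT = vt, IC = phases$TLC - phases$FRC,
              VC = phases$TLC - phases$RV, RR = rr, MV = vt * rr)
  class(out) <- "oep_pattern"
  out
}

#' @export
print.oep_pattern <- function(x, ...) {
  cat(sprintf(
    "Ventilatory pattern: VT %.2f L, IC %.2f L, VC %.2f L, RR %.1f /min, MV %.2f L/min\n",
    x$VT, x$IC, x$VC, x$RR, x$MV))
  if (!is.null(x$compartments)) {
    cat("  compartment contributions [% CW]:\n")
    print(round(x$compartments, 1))
  }
  invisible(x)
}

#' Compartmental contributions to a volume variation
#'
#' Percentage of the chest-wall volume change carried by each compartment,
#' computed as each compartment's delta over the sum of the deltas.
#' Negative deltas (paradoxical motion) are allowed and reported signed.
#'
#' @param deltas named numeric vector of compartment volume changes (L),
#'   e.g. \code{c(RCp = 0.20, RCa = 0.13, AB = 0.16)}.
#' @return named percentages summing to 100.
#' @export
compartmental_contributions <- function(deltas) {
  if (!length(deltas) || all(deltas == 0))
    stop("all compartment deltas are zero")
  tot <- sum(deltas)
  if (tot == 0) stop("compartment deltas sum to zero")
  deltas / tot * 100
}
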