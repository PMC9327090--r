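#' Marker trajectory set
#'
#' Labelled 3D marker positions over time at a fixed sampling rate, the
#' pipeline's raw input. Positions are held internally in millimetres as a
#' \code{frames x markers x 3} array.
#'
#' @param positions numeric array \code{frames x markers x 3} (mm).
#' @param sample_rate sampling frequency in Hz.
#' @param labels marker labels, matching \code{layout$markers$label}.
#' @param layout the \code{oep_layout} the markers follow.
#' @return an object of class \code{oep_traj}.
#' @export
marker_trajectories <- function(positions, sample_rate, labels, layout) {
  positions <- as.array(positions)
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("positions must be a frames x markers x 3 array")
  if (dim(positions)[2] != length(labels))
    stop("marker count does not match labels")
  miss <- setdiff(layout$markers$label, labels)
  if (length(miss))
    stop("labels missing from trajectories: ", paste(miss, collapse = ", "))
  unknown <- setdiff(labels, layout$markers$label)
  if (length(unknown))
    stop("unknown labels not in layout: ", paste(unknown, collapse = ", "))
  # canonical marker order = layout order
  positions <- positions[, match(layout$markers$label, labels), , drop = FALSE]
  if (anyNA(positions)) stop("positions contain missing values")
  structure(list(positions = positions, sample_rate = sample_rate,
                 labels = layout$markers$label, layout = layout),
            class = "oep_traj")
}

#' @export
print.oep_traj <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf(
    "Marker trajectories: %d frames x %d markers at %g Hz (%.1f s)\n",
    d[1], d[2], x$sample_rate, d[1] / x$sample_rate))
  invisible(x)
}

# One frame as a markers x 3 matrix with labels as rownames.
traj_frame <- function(traj, frame) {
  p <- traj$positions[frame, , , drop = TRUE]
  dim(p) <- c(dim(traj$positions)[2], 3L)
  rownames(p) <- traj$labels
  p
}

#' Read marker trajectories from the documented CSV dialect
#'
#' The dialect replaces the proprietary motion-capture acquisition format
#' with plain text: optional metadata comment lines \code{# unit=mm} (or
#' \code{m}, \code{cm}) and \code{# sample_rate=<Hz>}, then a CSV table
#' with a \code{time} column and three columns \code{<label>_X},
#' \code{<label>_Y}, \code{<label>_Z} per marker. Coordinates are converted
#' to the canonical internal unit (mm) on load. Frames with missing
#' coordinates are filled by linear temporal interpolation provided the gap
#' does not exceed \code{max_gap} seconds; longer gaps (or gaps at the
#' trace ends) are an error, since they would invalidate volumes.
#'
#' @param path CSV file path.
#' @param layout an \code{oep_layout}; column labels must match its marker
#'   labels.
#' @param max_gap longest marker occlusion (s) bridged by interpolation.
#' @return an \code{oep_traj}.
#' @export
load_trajectories <- function(path, layout, max_gap = 0.5) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  meta_lines <- grep("^#", readLines(path, n = 20L, warn = FALSE),
                     value = TRUE)
  meta <- list(unit = "mm", sample_rate = NA_real_)
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (key %in% names(meta)) meta[[key]] <- val
    }
  }
  sample_rate <- suppressWarnings(as.numeric(meta$sample_rate))
  if (is.na(sample_rate))
    stop("trajectory header must declare '# sample_rate=<Hz>'")
  scale <- switch(meta$unit, mm = 1, cm = 10, m = 1000,
                  stop("unknown unit '", meta$unit, "' in trajectory header"))
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  cols <- setdiff(names(tab), "time")
  got <- unique(sub("_[XYZ]$", "", cols))
  unmatched <- setdiff(got, layout$markers$label)
  if (length(unmatched))
    stop("unknown marker labels in trajectory file: ",
         paste(unmatched, collapse = ", "))
  missing <- setdiff(layout$markers$label, got)
  if (length(missing))
    stop("trajectory file lacks markers: ", paste(missing, collapse = ", "))
  n <- nrow(tab)
  m <- length(got)
  pos <- array(NA_real_, c(n, m, 3L))
  axes <- c("X", "Y", "Z")
  for (j in seq_len(m)) for (k in 1:3) {
    cn <- paste0(got[j], "_", axes[k])
    if (!cn %in% names(tab)) stop("trajectory file lacks column ", cn)
    pos[, j, k] <- tab[[cn]] * scale
  }
  pos <- fill_marker_gaps(pos, sample_rate, max_gap, got)
  marker_trajectories(pos, sample_rate, got, layout)
}

# Linear temporal interpolation of NA runs, bounded by max_gap seconds.
fill_marker_gaps <- function(pos, sample_rate, max_gap, labels) {
  max_run <- floor(max_gap * sample_rate)
  n <- dim(pos)[1]
  for (j in seq_len(dim(pos)[2])) {
    na_frame <- is.na(pos[, j, 1]) | is.na(pos[, j, 2]) | is.na(pos[, j, 3])
    if (!any(na_frame)) next
    r <- rle(na_frame)
    runs <- r$lengths[r$values]
    if (any(runs > max_run))
      stop("marker ", labels[j], ": occlusion of ", max(runs),
           " frames exceeds the ", max_gap, " s interpolation limit")
    if (na_frame[1] || na_frame[n])
      stop("marker ", labels[j], ": missing coordinates at the trace ends ",
           "cannot be interpolated")
    ok <- which(!na_frame)
    for (k in 1:3)
      pos[, j, k] <- stats::approx(ok, pos[ok, j, k], xout = seq_len(n))$y
  }
  pos
}

#' Write marker trajectories in the documented CSV dialect
#'
#' Inverse of \code{\link{load_trajectories}}; load-write-load is
#' idempotent at the written precision.
#'
#' @param traj an \code{oep_traj}.
#' @param path output file.
#' @param digits decimal digits written (default preserves 1e-6 mm).
#' @export
write_trajectories <- function(traj, path, digits = 6L) {
  d <- dim(traj$positions)
  axes <- c("X", "Y", "Z")
  cols <- vector("list", 1L + 3L * d[2])
  names(cols)[1] <- "time"
  cols[[1]] <- round((seq_len(d[1]) - 1) / traj$sample_rate, digits)
  ci <- 2L
  for (j in seq_len(d[2])) for (k in 1:3) {
    names(cols)[ci] <- paste0(traj$labels[j], "_", axes[k])
    cols[[ci]] <- round(traj$positions[, j, k], digits)
    ci <- ci + 1L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# unit=mm", paste0("# sample_rate=", traj$sample_rate)), con)
  utils::write.csv(as.data.frame(cols, check.names = FALSE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
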