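#' Rendering specification for 3D surface plots
#'
#' Fixed-view orthographic rendering with the diverging blue-white-red
#' palette of the breathing maps: outward (positive) motion is red, inward
#' (negative) motion blue, zero motion white. The color range is symmetric
#' about zero so the sign semantics survive rescaling.
#'
#' @param view one of \code{"front"}, \code{"back"}, \code{"left"},
#'   \code{"right"}.
#' @param range symmetric color limit L (values clipped to [-L, L]); by
#'   default the maximum absolute value of the rendered data.
#' @param width,height raster size in pixels.
#' @param n_colors palette resolution.
#' @return list of class \code{oep_render_spec}.
#' @export
render_spec <- function(view = c("front", "back", "left", "right"),
                        range = NULL, width = 800L, height = 750L,
                        n_colors = 101L) {
  view <- match.arg(view)
  if (!is.null(range) && range <= 0) stop("range must be positive")
  structure(list(view = view, range = range, width = as.integer(width),
                 height = as.integer(height), n_colors = as.integer(n_colors)),
            class = "oep_render_spec")
}

# Orthographic projection: screen x/y plus depth towards the viewer.
project_view <- function(vertices, view) {
  x <- vertices[, 1L]; y <- vertices[, 2L]; z <- vertices[, 3L]
  switch(view,
    front = cbind(sx = x, sy = z, depth = y),
    back  = cbind(sx = -x, sy = z, depth = -y),
    right = cbind(sx = -y, sy = z, depth = x),
    left  = cbind(sx = y, sy = z, depth = -x))
}

diverging_palette <- function(n) {
  grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(n)
}

# Map signed values to palette indices over the symmetric range [-L, L].
value_colors <- function(values, limit, n_colors) {
  pal <- diverging_palette(n_colors)
  v <- pmax(-limit, pmin(limit, values))
  idx <- 1L + round((v + limit) / (2 * limit) * (n_colors - 1L))
  pal[idx]
}

draw_colorbar <- function(limit, n_colors, label) {
  pal <- diverging_palette(n_colors)
  usr <- graphics::par("usr")
  x0 <- usr[2L] - 0.06 * (usr[2L] - usr[1L])
  x1 <- usr[2L] - 0.02 * (usr[2L] - usr[1L])
  ys <- seq(usr[3L] + 0.1 * (usr[4L] - usr[3L]),
            usr[4L] - 0.1 * (usr[4L] - usr[3L]), length.out = n_colors + 1L)
  graphics::rect(x0, ys[-length(ys)], x1, ys[-1L], col = pal, border = NA)
  graphics::text(x1, range(ys), labels = sprintf("%+.2g", c(-limit, limit)),
                 pos = 4L, cex = 0.8, xpd = NA)
  graphics::text(x1, mean(range(ys)), labels = label, pos = 4L, cex = 0.8,
                 srt = 90, xpd = NA)
}

#' Render a 3D heatmap of per-vertex motion on a mesh
#'
#' Paints the trunk model at the starting volume with the per-vertex
#' signed displacement values through the diverging blue-white-red map
#' (painter's algorithm, orthographic view, color bar included). Output
#' is deterministic for fixed inputs.
#'
#' @param mesh an \code{oep_mesh}.
#' @param values per-vertex signed values (cm, or normalized units).
#' @param spec an \code{oep_render_spec}.
#' @param path output PNG file.
#' @param label color bar label.
#' @return invisibly, \code{path}.
#' @export
render_heatmap <- function(mesh, values, spec = render_spec(), path,
                           label = "displacement [cm]") {
  if (length(values) != nrow(mesh$vertices))
    stop("values length (", length(values), ") does not match vertex count (",
         nrow(mesh$vertices), ")")
  limit <- spec$range
  if (is.null(limit)) limit <- max(abs(values), 1e-12)
  prj <- project_view(mesh$vertices, spec$view)
  f <- mesh$faces
  face_val <- (values[f[, 1L]] + values[f[, 2L]] + values[f[, 3L]]) / 3
  face_depth <- (prj[f[, 1L], 3L] + prj[f[, 2L], 3L] + prj[f[, 3L], 3L]) / 3
  ord <- order(face_depth)
  cols <- value_colors(face_val, limit, spec$n_colors)
  grDevices::png(path, width = spec$width, height = spec$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 5))
  graphics::plot(NA, xlim = range(prj[, 1L]) + c(-1, 1) * 10,
                 ylim = range(prj[, 2L]) + c(-1, 1) * 10,
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = paste0("view: ", spec$view))
  for (i in ord)
    graphics::polygon(prj[f[i, ], 1L], prj[f[i, ], 2L], col = cols[i],
                      border = NA)
  draw_colorbar(limit, spec$n_colors, label)
  invisible(path)
}

#' Render a 3D arrow (vector field) plot
#'
#' Draws the displacement vectors as color-coded arrows from their start
#' points; length and direction reflect the field, color encodes the
#' signed modulus through the same diverging map as the heatmap (inward
#' negative = blue, outward positive = red).
#'
#' @param vf an \code{oep_vf} (signed).
#' @param spec an \code{oep_render_spec}.
#' @param path output PNG file.
#' @param stride arrow subsampling step (>= 1); every stride-th vertex is
#'   drawn.
#' @param amplify geometric arrow length multiplier for legibility.
#' @return invisibly, \code{path}.
#' @export
render_arrow_plot <- function(vf, spec = render_spec(), path, stride = 1L,
                              amplify = 1) {
  if (stride < 1L) stop("stride must be >= 1")
  keep <- seq(1L, length(vf$modulus), by = stride)
  limit <- spec$range
  if (is.null(limit)) limit <- max(abs(vf$modulus), 1e-12)
  p0 <- project_view(vf$start, spec$view)
  p1 <- project_view(vf$start + amplify * (vf$end - vf$start), spec$view)
  cols <- value_colors(vf$modulus, limit, spec$n_colors)
  nonzero <- abs(vf$modulus[keep]) > 1e-9
  grDevices::png(path, width = spec$width, height = spec$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 5))
  graphics::plot(NA, xlim = range(p0[, 1L]) + c(-1, 1) * 15,
                 ylim = range(p0[, 2L]) + c(-1, 1) * 15,
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = paste0("vector field, view: ", spec$view))
  if (!any(nonzero)) {
    warning("zero-length vector field: rendered without arrows")
  } else {
    sel <- keep[nonzero]
    # arrows pointing along the view axis can project to zero length
    suppressWarnings(
      graphics::arrows(p0[sel, 1L], p0[sel, 2L], p1[sel, 1L], p1[sel, 2L],
                       length = 0.05, col = cols[sel]))
  }
  draw_colorbar(limit, spec$n_colors, "signed modulus [cm]")
  invisible(path)
}

#' Render a per-triangle significance map
#'
#' Paints the averaged, uncolored model with the test outcome per
#' triangle: red where group 1 shows the greater average displacement
#' (p < alpha), blue where group 2 does, grey otherwise.
#'
#' @param map an \code{oep_sigmap}.
#' @param spec an \code{oep_render_spec}.
#' @param path output PNG file.
#' @return invisibly, \code{path}.
#' @export
render_significance_map <- function(map, spec = render_spec(), path) {
  mesh <- map$base_mesh
  prj <- project_view(mesh$vertices, spec$view)
  f <- mesh$faces
  cols <- c(group1_greater = "#B2182B", group2_greater = "#2166AC",
            none = "#D9D9D9")[map$direction]
  face_depth <- (prj[f[, 1L], 3L] + prj[f[, 2L], 3L] + prj[f[, 3L], 3L]) / 3
  ord <- order(face_depth)
  grDevices::png(path, width = spec$width, height = spec$height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 2))
  graphics::plot(NA, xlim = range(prj[, 1L]) + c(-1, 1) * 10,
                 ylim = range(prj[, 2L]) + c(-1, 1) * 10,
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("significance map (alpha = %g), view: %s",
                                map$alpha, spec$view))
  for (i in ord)
    graphics::polygon(prj[f[i, ], 1L], prj[f[i, ], 2L], col = cols[i],
                      border = NA)
  invisible(path)
}
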