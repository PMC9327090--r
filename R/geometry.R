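#' Mesh volume by the divergence theorem
#'
#' Exact polyhedral volume of a watertight, outward-oriented triangle
#' mesh: \code{V = |sum_faces det(v0, v1, v2)| / 6}, converted from mm^3
#' to litres. An inward-oriented mesh is repaired (global flip) with a
#' warning; a non-watertight mesh is an error.
#'
#' @param mesh an \code{oep_mesh}.
#' @return volume in L.
#' @export
mesh_volume <- function(mesh) {
  chk <- mesh_check(mesh)
  if (!chk$watertight)
    stop("volume requires a watertight mesh: ", chk$detail)
  sv <- chk$signed_volume_mm3
  if (sv < 0) {
    warning("mesh was inward oriented; orientation repaired")
    sv <- -sv
  }
  sv / 1e6
}

#' Mesh surface area
#'
#' Sum of triangle areas via cross products, in dm^2.
#'
#' @param mesh an \code{oep_mesh}.
#' @return surface area in dm^2.
#' @export
mesh_surface_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  ndeg <- sum(areas == 0)
  if (ndeg > 0)
    warning(ndeg, " degenerate (zero-area) face(s)")
  sum(areas) / 1e4
}

#' Transversal section of a mesh at a given height
#'
#' Cuts the mesh with the horizontal plane z = \code{z} (mm), chains the
#' triangle-plane intersection segments into closed polygons and reports
#' the largest one: area by the shoelace formula (dm^2) and perimeter as
#' the summed segment lengths (cm). A plane passing exactly through a
#' vertex is nudged by 1e-6 mm (declared tie-break).
#'
#' @param mesh an \code{oep_mesh}.
#' @param z section height in mm, strictly inside the mesh z range.
#' @return list with \code{area} (dm^2), \code{perimeter} (cm),
#'   \code{polygon} (n x 2 matrix, mm, ordered) and \code{n_components}.
#' @export
plane_section <- function(mesh, z) {
  vz <- mesh$vertices[, 3L]
  if (z <= min(vz) || z >= max(vz))
    stop("section plane z = ", z, " mm does not intersect the mesh")
  for (try in 1:5) {
    if (min(abs(vz - z)) > 1e-9) break
    z <- z + 1e-6
  }
  f <- mesh$faces
  s <- vz - z
  side <- s > 0
  cr <- side[f[, 1L]] + side[f[, 2L]] + side[f[, 3L]]
  hit <- which(cr == 1L | cr == 2L)
  if (!length(hit)) stop("no intersection at z = ", z)
  nV <- nrow(mesh$vertices)
  seg_edges <- matrix(0, length(hit), 2L)  # undirected edge keys per face
  pts <- new.env()
  edge_key <- function(a, b) (min(a, b) - 1) * nV + max(a, b)
  keys <- numeric(0)
  pt_list <- list()
  key_pt <- function(a, b) {
    k <- edge_key(a, b)
    pos <- match(k, keys)
    if (is.na(k)) stop("bad edge")
    if (is.na(pos)) {
      t <- s[a] / (s[a] - s[b])
      p <- mesh$vertices[a, ] + t * (mesh$vertices[b, ] - mesh$vertices[a, ])
      keys <<- c(keys, k)
      pt_list[[length(keys)]] <<- p
      pos <- length(keys)
    }
    pos
  }
  for (i in seq_along(hit)) {
    tri <- f[hit[i], ]
    crossed <- integer(0)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      a <- tri[e[1L]]; b <- tri[e[2L]]
      if (side[a] != side[b]) crossed <- c(crossed, key_pt(a, b))
    }
    if (length(crossed) != 2L)
      stop("non-manifold intersection while chaining the section")
    seg_edges[i, ] <- crossed
  }
  # walk the section graph: every crossing point joins exactly two faces
  npts <- length(keys)
  used <- logical(length(hit))
  polys <- list()
  seg_of_pt <- split(rep(seq_along(hit), 2L), as.vector(seg_edges))
  while (any(!used)) {
    start <- which(!used)[1L]
    used[start] <- TRUE
    ring <- seg_edges[start, ]
    cur_pt <- ring[2L]
    repeat {
      nxt <- setdiff(seg_of_pt[[as.character(cur_pt)]], which(used))
      if (!length(nxt)) break
      nxt <- nxt[1L]
      used[nxt] <- TRUE
      two <- seg_edges[nxt, ]
      cur_pt <- if (two[1L] == cur_pt) two[2L] else two[1L]
      if (cur_pt == ring[1L]) break
      ring <- c(ring, cur_pt)
    }
    polys[[length(polys) + 1L]] <- ring
  }
  measure <- function(ring) {
    P <- do.call(rbind, pt_list[ring])
    x <- P[, 1L]; y <- P[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    area <- abs(sum(x * yn - xn * y)) / 2
    per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
    list(area = area, per = per, P = P[, 1:2])
  }
  ms <- lapply(polys, measure)
  best <- which.max(vapply(ms, function(m) m$area, numeric(1)))
  list(area = ms[[best]]$area / 1e4, perimeter = ms[[best]]$per / 10,
       polygon = ms[[best]]$P, n_components = length(polys))
}

#' Anteroposterior and mediolateral diameters at a reference level
#'
#' Distances between designated marker pairs of the level's row: AP
#' between the front-central and back-central sheet markers, ML between
#' the right and left lateral markers.
#'
#' @param frame markers x 3 matrix (mm) in layout order.
#' @param layout an \code{oep_layout}.
#' @param level \code{"louis_angle"}, \code{"xiphoid"} or
#'   \code{"umbilicus"}.
#' @return list with \code{AP} and \code{ML} in cm.
#' @export
level_diameters <- function(frame, layout, level) {
  frame <- as.matrix(frame)
  idx <- layout_diameter_markers(layout, level)
  d <- function(i, j) sqrt(sum((frame[i, ] - frame[j, ])^2)) / 10
  list(AP = d(idx$front, idx$back), ML = d(idx$right, idx$left))
}

#' Trunk height
#'
#' Longitudinal distance between the top and bottom virtual (central)
#' markers of a closed frame, in cm.
#'
#' @param closed an \code{oep_closed_frame} (trunk scope).
#' @return height in cm.
#' @export
trunk_height <- function(closed) {
  unname(abs(closed$virtual["top", 3L] - closed$virtual["bottom", 3L])) / 10
}

#' Shape factors of a geometry summary
#'
#' AP/ML ratio at the three reference levels, surface-to-volume ratio
#' (cm^-1, using the whole chest-wall object volume) and the trunk
#' height to xiphoid perimeter ratio.
#'
#' @param summary an \code{oep_geometry} (or compatible list).
#' @return list with \code{ap_ml_ratio} (named, 3 levels),
#'   \code{surface_to_volume} (cm^-1), \code{height_to_perimeter_xiphoid}.
#' @export
shape_factors <- function(summary) {
  lv <- c("louis_angle", "xiphoid", "umbilicus")
  ap <- unlist(summary$AP[lv]); ml <- unlist(summary$ML[lv])
  if (any(!is.finite(ml)) || any(ml == 0)) stop("zero or missing ML diameter")
  if (!is.finite(summary$CW_obj) || summary$CW_obj <= 0)
    stop("zero chest-wall volume")
  per_x <- summary$perimeter[["xiphoid"]]
  if (!is.finite(per_x) || per_x == 0) stop("zero xiphoid perimeter")
  list(
    ap_ml_ratio = stats::setNames(ap / ml, lv),
    surface_to_volume = (summary$surface_area * 100) / (summary$CW_obj * 1000),
    height_to_perimeter_xiphoid = summary$trunk_height / per_x)
}

#' Volume validation error against a gold standard
#'
#' Signed error conventions of the 89-marker validation: absolute error is
#' gold minus model (L, sign preserved), percentage error is the absolute
#' error over the gold volume times 100.
#'
#' @param gold gold-standard volume (L), must be positive.
#' @param model model volume (L).
#' @return list with \code{absolute} (L) and \code{percent}.
#' @export
volume_error <- function(gold, model) {
  if (any(gold <= 0)) stop("gold-standard volume must be positive")
  list(absolute = gold - model, percent = (gold - model) / gold * 100)
}

#' Geometry summary of one frame at one respiratory phase
#'
#' Builds the closed trunk and compartment meshes of the frame, smooths
#' them (default one subdivision iteration), and measures the full set of
#' descriptors: trunk height, AP/ML diameters, perimeters and section
#' areas at the three reference levels (sections cut the smoothed trunk by
#' default), chest-wall surface area, compartment volumes, their sum
#' (CW_sum) and the whole-trunk object volume (CW_obj).
#'
#' @param traj an \code{oep_traj}.
#' @param frame frame index.
#' @param phase phase label (\code{"RV"}, \code{"FRC"}, \code{"FRCVT"},
#'   \code{"TLC"} or other).
#' @param level subdivision iterations applied before measuring.
#' @param sections_on_smoothed cut sections on the smoothed mesh (default)
#'   or on the level-0 marker mesh.
#' @return an object of class \code{oep_geometry}: list of measurements
#'   in the units of the field's tables (cm, dm^2, L).
#' @export
geometry_summary <- function(traj, frame, phase = NA_character_,
                             level = 1L, sections_on_smoothed = TRUE) {
  layout <- traj$layout
  fr <- traj_frame(traj, frame)
  closed <- add_closure_markers(fr, layout, "trunk", frame_index = frame)
  trunk0 <- build_trunk_mesh(closed, layout)
  trunk <- if (level > 0L) subdivide(trunk0, level)$mesh else trunk0
  comp_vol <- vapply(c("RCp", "RCa", "AB"), function(cp) {
    m0 <- build_compartment_mesh(fr, layout, cp)
    m <- if (level > 0L) subdivide(m0, level)$mesh else m0
    mesh_volume(m)
  }, numeric(1))
  levels <- compute_reference_levels(fr, layout)
  zs <- c(louis_angle = levels$z_louis, xiphoid = levels$z_xiphoid,
          umbilicus = levels$z_umbilicus)
  cut_mesh <- if (sections_on_smoothed) trunk else trunk0
  secs <- lapply(zs, function(z) plane_section(cut_mesh, z))
  dia <- lapply(names(zs), function(lv) level_diameters(fr, layout, lv))
  names(dia) <- names(zs)
  out <- list(
    phase = phase, frame = frame,
    trunk_height = trunk_height(closed),
    AP = lapply(dia, `[[`, "AP"),
    ML = lapply(dia, `[[`, "ML"),
    perimeter = vapply(secs, `[[`, numeric(1), "perimeter"),
    section_area = vapply(secs, `[[`, numeric(1), "area"),
    surface_area = mesh_surface_area(trunk),
    RCp = comp_vol[["RCp"]], RCa = comp_vol[["RCa"]], AB = comp_vol[["AB"]],
    CW_sum = sum(comp_vol),
    CW_obj = mesh_volume(trunk),
    reference_levels = levels)
  class(out) <- "oep_geometry"
  out
}

#' @export
print.oep_geometry <- function(x, ...) {
  cat(sprintf("Chest-wall geometry (%s, frame %d)\n",
              ifelse(is.na(x$phase), "unlabelled", x$phase), x$frame))
  cat(sprintf("  trunk height %.1f cm; surface %.1f dm^2\n",
              x$trunk_height, x$surface_area))
  cat(sprintf("  volumes [L]: RCp %.2f, RCa %.2f, AB %.2f; sum %.2f; object %.2f\n",
              x$RCp, x$RCa, x$AB, x$CW_sum, x$CW_obj))
  for (lv in c("louis_angle", "xiphoid", "umbilicus"))
    cat(sprintf("  %-12s AP %.1f cm, ML %.1f cm, perimeter %.1f cm, area %.2f dm^2\n",
                lv, x$AP[[lv]], x$ML[[lv]], x$perimeter[[lv]],
                x$section_area[[lv]]))
  invisible(x)
}
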