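#' Add virtual closure markers to a marker frame
#'
#' The acquired marker cloud is an open tube (head and limbs prevent
#' marker placement at the trunk boundaries), so four virtual markers are
#' added to close the shape: one at the top, one at the bottom and two on
#' the sides. Each is the arithmetic mean of a defining subset of real
#' markers: top/bottom = all front+back sheet markers of the highest/lowest
#' row in scope; right/left = all markers of the most-lateral right/left
#' front and back sheet columns across the rows in scope. For a compartment
#' scope the same rule is restricted to that compartment's rows, so each
#' compartment owns its own closure set.
#'
#' @param frame markers x 3 numeric matrix (mm), rows in layout order.
#' @param layout an \code{oep_layout}.
#' @param scope \code{"trunk"} or a compartment name (\code{"RCp"},
#'   \code{"RCa"}, \code{"AB"}).
#' @param frame_index optional frame number carried along.
#' @return an object of class \code{oep_closed_frame}: list with
#'   \code{original} (markers of the scope rows, layout order),
#'   \code{virtual} (4 x 3 matrix, rows top/bottom/right/left),
#'   \code{marker_index} (layout marker row indices used), \code{scope},
#'   \code{rows}, \code{frame_index}.
#' @export
add_closure_markers <- function(frame, layout, scope = "trunk",
                                frame_index = NA_integer_) {
  frame <- as.matrix(frame)
  if (nrow(frame) != layout$total_markers)
    stop("frame has ", nrow(frame), " markers; layout expects ",
         layout$total_markers)
  rows <- scope_rows(layout, scope)
  W <- closure_weights(layout, scope)
  sel <- which(layout$markers$row %in% rows)
  structure(
    list(original = frame[sel, , drop = FALSE],
         virtual = W %*% frame,
         marker_index = sel, scope = scope, rows = rows,
         frame_index = frame_index),
    class = "oep_closed_frame")
}

scope_rows <- function(layout, scope) {
  if (identical(scope, "trunk")) return(seq_len(layout$rows))
  if (!scope %in% names(layout$compartment_rows))
    stop("unknown scope '", scope, "'")
  rows <- layout$compartment_rows[[scope]]
  if (length(rows) < 2L)
    stop("compartment ", scope, " spans fewer than 2 rows")
  rows
}

# 4 x total_markers weight matrix: virtual markers are linear (mean)
# combinations of real markers, so they are recomputable fixed points.
closure_weights <- function(layout, scope = "trunk") {
  mk <- layout$markers
  rows <- scope_rows(layout, scope)
  sheet <- mk$region %in% c("front", "back")
  top_set <- which(sheet & mk$row == min(rows))
  bot_set <- which(sheet & mk$row == max(rows))
  right_set <- which(mk$row %in% rows &
    ((mk$region == "front" & mk$col == 1L) |
     (mk$region == "back" & mk$col == layout$back_cols)))
  left_set <- which(mk$row %in% rows &
    ((mk$region == "front" & mk$col == layout$front_cols) |
     (mk$region == "back" & mk$col == 1L)))
  sets <- list(top = top_set, bottom = bot_set, right = right_set,
               left = left_set)
  W <- matrix(0, 4L, nrow(mk),
              dimnames = list(names(sets), mk$label))
  for (i in seq_along(sets)) {
    if (!length(sets[[i]]))
      stop("empty defining subset for virtual marker '", names(sets)[i], "'")
    W[i, sets[[i]]] <- 1 / length(sets[[i]])
  }
  W
}

#' Anatomical reference levels of a frame
#'
#' Heights (mm, along the longitudinal z axis) of the angle of Louis,
#' xiphoid and umbilicus levels, each the mean z coordinate of the markers
#' of the corresponding layout row.
#'
#' @param frame markers x 3 matrix (mm) in layout order.
#' @param layout an \code{oep_layout}.
#' @return list with \code{z_louis}, \code{z_xiphoid}, \code{z_umbilicus}
#'   (class \code{oep_levels}); seated head-up convention requires
#'   \code{z_louis > z_xiphoid > z_umbilicus}.
#' @export
compute_reference_levels <- function(frame, layout) {
  frame <- as.matrix(frame)
  zs <- vapply(c("louis_angle", "xiphoid", "umbilicus"), function(lv) {
    r <- layout$level_rows[[lv]]
    sel <- layout$markers$row == r
    if (!any(sel)) stop("no markers in level row ", r)
    mean(frame[sel, 3L])
  }, numeric(1))
  out <- structure(list(z_louis = zs[[1]], z_xiphoid = zs[[2]],
                        z_umbilicus = zs[[3]]), class = "oep_levels")
  if (!(out$z_louis > out$z_xiphoid && out$z_xiphoid > out$z_umbilicus))
    warning("reference levels are not in head-up order")
  out
}

# ---- layout-derived triangulation ----------------------------------------

# Stitch two circumferential rings (angularly sorted stations) into an
# oriented triangle band. Equal aligned rings use the fixed diagonal rule
# (row r, station i) -> (row r+1, station i+1); unequal rings are merged
# by advancing whichever ring has the smaller next unwrapped angle.
stitch_rings <- function(idsA, angA, idsB, angB) {
  nA <- length(idsA); nB <- length(idsB)
  if (nA == nB && max(abs(angA - angB)) < 1e-9) {
    i <- seq_len(nA)
    ip <- c(i[-1L], 1L)
    return(rbind(cbind(idsA[i], idsB[i], idsB[ip]),
                 cbind(idsA[i], idsB[ip], idsA[ip])))
  }
  j0 <- which.min(pmin(abs(angB - angA[1L]), 360 - abs(angB - angA[1L])))
  ua <- c(angA, angA[1L] + 360)
  ub_raw <- angB[c(j0:nB, seq_len(j0 - 1L))]
  ub <- ub_raw + 360 * (ub_raw < ub_raw[1L])
  ub <- c(ub, ub[1L] + 360)
  ia <- c(seq_len(nA), 1L)
  ib <- c(c(j0:nB, seq_len(j0 - 1L)), j0)
  faces <- matrix(0L, nA + nB, 3L)
  i <- 1L; j <- 1L; k <- 1L
  while (i <= nA || j <= nB) {
    adv_a <- j > nB || (i <= nA && ua[i + 1L] <= ub[j + 1L])
    if (adv_a) {
      faces[k, ] <- c(idsA[ia[i]], idsB[ib[j]], idsA[ia[i + 1L]])
      i <- i + 1L
    } else {
      faces[k, ] <- c(idsA[ia[i]], idsB[ib[j]], idsB[ib[j + 1L]])
      j <- j + 1L
    }
    k <- k + 1L
  }
  faces
}

# Faces and vertex bookkeeping for a scope, derived from the layout only
# (frame-independent): real markers of the scope rows in layout order,
# then the 4 virtuals (top, bottom, right, left).
layout_topology <- function(layout, scope = "trunk") {
  rows <- scope_rows(layout, scope)
  mk <- layout$markers
  sel <- which(mk$row %in% rows)
  local_id <- integer(nrow(mk))
  local_id[sel] <- seq_along(sel)
  nv <- length(sel)
  id_top <- nv + 1L; id_bottom <- nv + 2L
  id_right <- nv + 3L; id_left <- nv + 4L
  rings <- lapply(rows, function(r) {
    idx <- layout_ring(layout, r)
    list(ids = local_id[idx], ang = mk$angle[idx])
  })
  nr <- length(rings)
  side_faces <- vector("list", nr - 1L)
  for (p in seq_len(nr - 1L))
    side_faces[[p]] <- stitch_rings(rings[[p]]$ids, rings[[p]]$ang,
                                    rings[[p + 1L]]$ids, rings[[p + 1L]]$ang)
  r1 <- rings[[1L]]; rn <- rings[[nr]]
  n1 <- length(r1$ids); nn <- length(rn$ids)
  top_faces <- cbind(id_top, r1$ids, r1$ids[c(2:n1, 1L)])
  bot_faces <- cbind(id_bottom, rn$ids[c(2:nn, 1L)], rn$ids)
  # insert each side virtual by splitting the stitch triangle of the middle
  # row pair whose (circular) centroid angle is nearest the target side
  mid_pair <- max(1L, floor((nr + 1L) / 2L))
  band <- side_faces[[mid_pair]]
  ang_of <- numeric(length(sel))
  ang_of[local_id[sel]] <- mk$angle[sel]
  centroid_angle <- function(tri) {
    a <- ang_of[tri] * pi / 180
    atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  }
  cang <- apply(band, 1L, centroid_angle)
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  split_tri <- function(band, target, vid) {
    pick <- which.min(circ_dist(cang, target))
    tri <- band[pick, ]
    band <- band[-pick, , drop = FALSE]
    cang <<- cang[-pick]
    rbind(band, c(tri[1L], tri[2L], vid), c(tri[2L], tri[3L], vid),
          c(tri[3L], tri[1L], vid))
  }
  band <- split_tri(band, 0, id_right)
  band <- split_tri(band, 180, id_left)
  side_faces[[mid_pair]] <- band
  faces <- do.call(rbind, c(side_faces, list(top_faces, bot_faces)))
  storage.mode(faces) <- "integer"
  list(faces = faces, marker_index = sel, rows = rows,
       ids = list(top = id_top, bottom = id_bottom, right = id_right,
                  left = id_left),
       n_vertices = nv + 4L)
}

closed_frame_vertices <- function(closed) {
  rbind(closed$original, closed$virtual)
}

#' Build the closed trunk mesh of one frame
#'
#' Combines the closed marker frame with the layout-derived triangulation:
#' inter-row bands (fixed diagonal rule), top/bottom virtual markers
#' fanning the first/last ring, side virtual markers splitting a seam
#' triangle of the middle row pair. The topology depends only on the
#' layout; vertex positions carry all the time dependence. The result is
#' watertight, genus 0 and outward oriented.
#'
#' @param closed an \code{oep_closed_frame} from
#'   \code{\link{add_closure_markers}} (trunk scope).
#' @param layout the \code{oep_layout} used to close the frame.
#' @return an \code{oep_mesh} with \code{origin_ids} naming every original
#'   marker and the four virtuals.
#' @export
build_trunk_mesh <- function(closed, layout) {
  build_scope_mesh(closed, layout, "trunk")
}

#' Build the closed mesh of one chest-wall compartment
#'
#' Same construction as \code{\link{build_trunk_mesh}} restricted to the
#' compartment's row range and closed with that compartment's own virtual
#' markers.
#'
#' @param frame markers x 3 matrix (mm) in layout order, or an
#'   \code{oep_closed_frame} already closed for this compartment.
#' @param layout an \code{oep_layout}.
#' @param compartment \code{"RCp"}, \code{"RCa"} or \code{"AB"}.
#' @return an \code{oep_mesh}.
#' @export
build_compartment_mesh <- function(frame, layout, compartment) {
  closed <- if (inherits(frame, "oep_closed_frame")) frame
            else add_closure_markers(frame, layout, compartment)
  if (!identical(closed$scope, compartment))
    stop("closed frame scope '", closed$scope, "' does not match ",
         compartment)
  build_scope_mesh(closed, layout, compartment)
}

build_scope_mesh <- function(closed, layout, scope) {
  topo <- layout_topology(layout, scope)
  if (!identical(topo$marker_index, closed$marker_index))
    stop("closed frame does not match layout scope '", scope, "'")
  verts <- closed_frame_vertices(closed)
  origin <- c(layout$markers$label[topo$marker_index],
              paste0("virtual_", c("top", "bottom", "right", "left")))
  mesh <- trimesh(verts, topo$faces, level = 0L,
                  origin_ids = stats::setNames(seq_len(nrow(verts)), origin),
                  validate = FALSE)
  chk <- mesh_check(mesh)
  if (!chk$watertight)
    stop("layout produced a non-manifold mesh: ", chk$detail)
  if (!chk$genus0)
    stop("layout mesh is not genus 0")
  if (chk$signed_volume_mm3 < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Chest-wall volume trace from marker trajectories
#'
#' Builds the closed level-0 (89-marker) mesh at every frame and evaluates
#' its volume by the divergence theorem. This is the gold-standard volume
#' signal phase detection operates on. Virtual markers and the mesh volume
#' are both linear/polynomial in marker positions, so the whole trace is
#' computed vectorised over frames.
#'
#' @param traj an \code{oep_traj}.
#' @param scope \code{"trunk"} or a compartment name.
#' @return object of class \code{oep_volume_trace}: data frame with
#'   \code{t} (s) and \code{V} (L), with the sample rate as attribute.
#' @export
chest_volume_trace <- function(traj, scope = "trunk") {
  layout <- traj$layout
  topo <- layout_topology(layout, scope)
  W <- closure_weights(layout, scope)
  n <- dim(traj$positions)[1]
  sel <- topo$marker_index
  # frame-wise vertex coordinates: real markers then the 4 virtuals
  coord <- function(k) cbind(traj$positions[, sel, k, drop = TRUE],
                             traj$positions[, , k, drop = TRUE] %*% t(W))
  X <- coord(1L); Y <- coord(2L); Z <- coord(3L)
  f <- topo$faces
  vol <- numeric(n)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1L]; b <- f[i, 2L]; c3 <- f[i, 3L]
    vol <- vol +
      X[, a] * (Y[, b] * Z[, c3] - Z[, b] * Y[, c3]) -
      Y[, a] * (X[, b] * Z[, c3] - Z[, b] * X[, c3]) +
      Z[, a] * (X[, b] * Y[, c3] - Y[, b] * X[, c3])
  }
  vol <- vol / 6 / 1e6
  if (stats::median(vol) < 0) vol <- -vol
  out <- data.frame(t = (seq_len(n) - 1) / traj$sample_rate, V = vol)
  attr(out, "sample_rate") <- traj$sample_rate
  attr(out, "scope") <- scope
  class(out) <- c("oep_volume_trace", "data.frame")
  out
}
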