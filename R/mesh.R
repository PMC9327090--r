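#' Triangle mesh container
#'
#' A closed, consistently oriented triangulated surface (trunk or
#' compartment, before or after subdivision). Vertices are in millimetres,
#' the package's canonical internal unit; faces are 1-based vertex-index
#' triples, oriented counter-clockwise when seen from outside.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param level subdivision iteration count this mesh has undergone.
#' @param origin_ids named integer vector mapping original marker/vertex
#'   labels to vertex indices in this mesh (preserved across subdivision).
#' @param validate check watertightness, orientation and Euler
#'   characteristic (genus 0) and fail if violated.
#' @return an object of class \code{oep_mesh}: a list with elements
#'   \code{vertices}, \code{faces}, \code{level}, \code{origin_ids}.
#' @export
trimesh <- function(vertices, faces, level = 0L, origin_ids = NULL,
                    validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(
    list(vertices = vertices, faces = faces, level = as.integer(level),
         origin_ids = origin_ids),
    class = "oep_mesh")
  if (validate) {
    chk <- mesh_check(m)
    if (!chk$watertight)
      stop("mesh is not watertight: ", chk$detail)
    if (!chk$genus0)
      stop("mesh is not genus 0 (V - E + F = ", chk$euler, ")")
    if (chk$signed_volume_mm3 < 0)
      stop("mesh is not outward oriented (signed volume < 0)")
  }
  m
}

#' @export
print.oep_mesh <- function(x, ...) {
  cat(sprintf("Closed triangle mesh: %d vertices, %d faces (level %d)\n",
              nrow(x$vertices), nrow(x$faces), x$level))
  cat(sprintf("  signed volume %.3f L, surface %.2f dm^2\n",
              mesh_signed_volume(x) / 1e6,
              mesh_surface_area(x)))
  invisible(x)
}

# Undirected edge table: one row per undirected edge, with counts of the
# two orientations. Directed edges of face (a,b,c) are a->b, b->c, c->a.
mesh_edge_table <- function(faces, n_vertices) {
  from <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  to   <- c(faces[, 2L], faces[, 3L], faces[, 1L])
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  key <- (as.numeric(lo) - 1) * n_vertices + as.numeric(hi)
  ukey <- unique(key)
  idx <- match(key, ukey)
  cnt <- tabulate(idx, nbins = length(ukey))
  fwd <- tabulate(idx[from < to], nbins = length(ukey))
  list(lo = lo[match(ukey, key)], hi = hi[match(ukey, key)],
       count = cnt, forward = fwd, index = idx)
}

#' Structural checks for a triangle mesh
#'
#' @param mesh an \code{oep_mesh} (or a list with vertices/faces).
#' @return list with \code{watertight} (every undirected edge shared by
#'   exactly two faces, once per orientation), \code{euler} (V - E + F),
#'   \code{genus0}, \code{signed_volume_mm3} and a human-readable
#'   \code{detail} when watertightness fails.
#' @export
mesh_check <- function(mesh) {
  V <- nrow(mesh$vertices)
  Fn <- nrow(mesh$faces)
  et <- mesh_edge_table(mesh$faces, V)
  E <- length(et$count)
  bad <- which(et$count != 2L | et$forward != 1L)
  watertight <- length(bad) == 0L
  detail <- if (watertight) "" else
    paste0(length(bad), " offending edge(s), e.g. ",
           paste(utils::head(paste0(et$lo[bad], "-", et$hi[bad]), 5L),
                 collapse = ", "))
  euler <- V - E + Fn
  list(watertight = watertight, euler = euler, genus0 = euler == 2L,
       signed_volume_mm3 = mesh_signed_volume(mesh), detail = detail,
       n_edges = E)
}

# Signed volume in mm^3 via the divergence theorem:
# V = sum over faces of det(v0, v1, v2) / 6.
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  det3 <- a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
          a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
          a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])
  sum(det3) / 6
}

#' Repair face orientation
#'
#' Propagates a consistent winding across shared edges (breadth-first over
#' face adjacency), then flips the whole mesh if its signed volume is
#' negative, so that the result is outward oriented.
#'
#' @param mesh an \code{oep_mesh} or vertices/faces list; may be
#'   inconsistently oriented.
#' @return the mesh with consistently outward-oriented faces.
#' @export
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  nv <- nrow(mesh$vertices)
  # map undirected edge -> incident faces
  from <- c(f[, 1L], f[, 2L], f[, 3L])
  to   <- c(f[, 2L], f[, 3L], f[, 1L])
  face_of <- rep.int(seq_len(nf), 3L)
  key <- (pmin(from, to) - 1) * as.numeric(nv) + pmax(from, to)
  ord <- order(key)
  key_s <- key[ord]; face_s <- face_of[ord]
  runs <- rle(key_s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pair_sel <- runs$lengths == 2L
  fa <- face_s[starts[pair_sel]]
  fb <- face_s[ends[pair_sel]]
  adj <- split(c(fb, fa), c(fa, fb))
  visited <- logical(nf)
  flipped <- logical(nf)
  queue <- integer(0)
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    queue <- seed
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      fc <- f[cur, ]
      if (flipped[cur]) fc <- fc[c(1L, 3L, 2L)]
      dir_cur <- paste(fc, fc[c(2L, 3L, 1L)])
      for (nb in adj[[as.character(cur)]]) {
        if (is.null(nb) || visited[nb]) next
        fn <- f[nb, ]
        dir_nb <- paste(fn, fn[c(2L, 3L, 1L)])
        # consistent winding puts the shared edge in opposite directions;
        # if the raw neighbour repeats a directed edge of cur, flip it
        visited[nb] <- TRUE
        flipped[nb] <- any(dir_cur %in% dir_nb)
        queue <- c(queue, nb)
      }
    }
  }
  if (any(flipped))
    f[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
  out <- mesh
  out$faces <- f
  if (mesh_signed_volume(out) < 0)
    out$faces <- f[, c(1L, 3L, 2L), drop = FALSE]
  out
}

# Scale/transform helpers used across the package --------------------------

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh an \code{oep_mesh}.
#' @param rotation 3 x 3 matrix applied on the right of the vertex rows.
#' @param translation length-3 numeric offset in mm.
#' @return the transformed mesh (topology unchanged).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(rotation) +
    matrix(translation, nrow(mesh$vertices), 3L, byrow = TRUE)
  mesh
}
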