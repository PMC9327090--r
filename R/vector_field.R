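#' Displacement vector field between two phase meshes
#'
#' Connects corresponding vertices of two topologically identical meshes
#' (same faces, same vertex ids, same subdivision level): vector
#' \code{v_i = B_i - A_i}, with unsigned modulus in cm. Signs are assigned
#' separately by \code{\link{assign_signs}}.
#'
#' @param meshA start mesh (model at the starting volume).
#' @param meshB end mesh.
#' @param phase_pair label such as \code{"FRC:FRCVT"}, \code{"FRC:TLC"}
#'   or \code{"TLC:RV"}.
#' @param subject_id optional subject identifier.
#' @return object of class \code{oep_vf}: list with \code{start},
#'   \code{end} (n x 3 mm), \code{modulus} (cm, unsigned until signs are
#'   assigned), \code{faces}, \code{phase_pair}, \code{subject_id},
#'   \code{signed} flag.
#' @export
build_vector_field <- function(meshA, meshB, phase_pair = NA_character_,
                               subject_id = NA_character_) {
  if (!identical(dim(meshA$vertices), dim(meshB$vertices)) ||
      !identical(meshA$faces, meshB$faces))
    stop("meshes are not topologically identical")
  disp <- meshB$vertices - meshA$vertices
  structure(
    list(start = meshA$vertices, end = meshB$vertices,
         modulus = sqrt(rowSums(disp^2)) / 10,
         faces = meshA$faces, phase_pair = phase_pair,
         subject_id = subject_id, signed = FALSE),
    class = "oep_vf")
}

#' @export
print.oep_vf <- function(x, ...) {
  cat(sprintf("Vector field %s: %d vertices, %s moduli, mean |v| %.2f cm\n",
              ifelse(is.na(x$phase_pair), "", x$phase_pair),
              length(x$modulus),
              ifelse(x$signed, "signed", "unsigned"),
              mean(abs(x$modulus))))
  invisible(x)
}

#' Generalized winding number of points with respect to a closed mesh
#'
#' Sum of signed solid angles subtended by the mesh triangles (van
#' Oosterom-Strackee), divided by 4 pi: ~1 inside, ~0 outside.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a watertight \code{oep_mesh}.
#' @return numeric vector of winding numbers.
#' @export
winding_number <- function(points, mesh) {
  points <- matrix(points, ncol = 3L)
  v <- mesh$vertices
  f <- mesh$faces
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    A <- v[f[, 1L], , drop = FALSE]
    A[, 1L] <- A[, 1L] - p[1L]; A[, 2L] <- A[, 2L] - p[2L]
    A[, 3L] <- A[, 3L] - p[3L]
    B <- v[f[, 2L], , drop = FALSE]
    B[, 1L] <- B[, 1L] - p[1L]; B[, 2L] <- B[, 2L] - p[2L]
    B[, 3L] <- B[, 3L] - p[3L]
    C <- v[f[, 3L], , drop = FALSE]
    C[, 1L] <- C[, 1L] - p[1L]; C[, 2L] <- C[, 2L] - p[2L]
    C[, 3L] <- C[, 3L] - p[3L]
    la <- sqrt(rowSums(A^2)); lb <- sqrt(rowSums(B^2)); lc <- sqrt(rowSums(C^2))
    num <- A[, 1L] * (B[, 2L] * C[, 3L] - B[, 3L] * C[, 2L]) -
           A[, 2L] * (B[, 1L] * C[, 3L] - B[, 3L] * C[, 1L]) +
           A[, 3L] * (B[, 1L] * C[, 2L] - B[, 2L] * C[, 1L])
    den <- la * lb * lc + rowSums(A * B) * lc + rowSums(B * C) * la +
           rowSums(C * A) * lb
    out[i] <- sum(2 * atan2(num, den)) / (4 * pi)
  }
  out
}

#' Ray-casting point-in-mesh test
#'
#' Parity of ray-triangle intersections along a fixed direction
#' (Moller-Trumbore). Used as an independent cross-check of the winding
#' number classification.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a watertight \code{oep_mesh}.
#' @param dir ray direction (default an irrational-ish direction avoiding
#'   edge-grazing ties).
#' @return logical vector, TRUE when inside.
#' @export
point_in_mesh_raycast <- function(points, mesh,
                                  dir = c(0.57735, 0.648886, 0.495774)) {
  points <- matrix(points, ncol = 3L)
  dir <- dir / sqrt(sum(dir^2))
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - v0
  e2 <- v[f[, 3L], , drop = FALSE] - v0
  pvec <- cbind(dir[2L] * e2[, 3L] - dir[3L] * e2[, 2L],
                dir[3L] * e2[, 1L] - dir[1L] * e2[, 3L],
                dir[1L] * e2[, 2L] - dir[2L] * e2[, 1L])
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  out <- logical(nrow(points))
  for (i in seq_len(nrow(points))) {
    tvec <- sweep(v0, 2L, points[i, ])
    tvec <- -tvec
    u <- rowSums(tvec * pvec) / det
    qvec <- cbind(tvec[, 2L] * e1[, 3L] - tvec[, 3L] * e1[, 2L],
                  tvec[, 3L] * e1[, 1L] - tvec[, 1L] * e1[, 3L],
                  tvec[, 1L] * e1[, 2L] - tvec[, 2L] * e1[, 1L])
    vv <- (qvec[, 1L] * dir[1L] + qvec[, 2L] * dir[2L] +
             qvec[, 3L] * dir[3L]) / det
    tt <- rowSums(e2 * qvec) / det
    hits <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 0
    out[i] <- sum(hits) %% 2L == 1L
  }
  out
}

#' Assign inward-negative signs to a vector field
#'
#' Checks whether the endpoint of each vector lies inside the starting
#' volume (generalized winding number > 0.5) and negates the modulus of
#' inward-pointing vectors. Endpoints within \code{surface_tol} mm of
#' their start (zero-motion vertices) keep modulus 0 / positive sign, so
#' numerical noise cannot flip them.
#'
#' @param vf an \code{oep_vf}.
#' @param meshA the starting mesh (watertight).
#' @param surface_tol displacement below which a vector is treated as
#'   zero motion (mm).
#' @return the vector field with signed moduli (\code{signed = TRUE}).
#' @export
assign_signs <- function(vf, meshA, surface_tol = 1e-6) {
  chk <- mesh_check(meshA)
  if (!chk$watertight)
    stop("sign assignment requires a watertight starting mesh")
  disp_mm <- abs(vf$modulus) * 10
  moving <- disp_mm > surface_tol
  signs <- rep(1, length(vf$modulus))
  if (any(moving)) {
    wn <- winding_number(vf$end[moving, , drop = FALSE], meshA)
    signs[moving] <- ifelse(wn > 0.5, -1, 1)
  }
  vf$modulus <- abs(vf$modulus) * signs
  vf$signed <- TRUE
  vf
}

#' Jointly normalize vector fields to [-1, 1]
#'
#' Divides all signed moduli by the single largest absolute modulus across
#' all fields, so values lie in [-1, 1], zero stays zero (the inward /
#' outward color semantics survive), and relative magnitudes between
#' subjects are preserved.
#'
#' @param fields list of \code{oep_vf} with identical topology.
#' @return list with \code{fields} (normalized copies) and \code{scale}
#'   (cm; the shared maximum absolute modulus).
#' @export
normalize_fields <- function(fields) {
  if (!length(fields)) stop("no vector fields supplied")
  if (inherits(fields, "oep_vf")) fields <- list(fields)
  nv <- vapply(fields, function(f) length(f$modulus), integer(1))
  if (length(unique(nv)) != 1L)
    stop("vector fields differ in vertex count")
  s <- max(vapply(fields, function(f) max(abs(f$modulus)), numeric(1)))
  if (s == 0) {
    warning("all vector fields are zero; scale reported as 0")
    return(list(fields = fields, scale = 0))
  }
  list(fields = lapply(fields, function(f) {
    f$modulus <- f$modulus / s
    f$normalized <- TRUE
    f
  }), scale = s)
}

#' Linear blend between two topologically identical meshes
#'
#' Morphing between two respiratory phases: vertices are
#' \code{(1 - alpha) A + alpha B}.
#'
#' @param meshA,meshB \code{oep_mesh} objects with identical topology.
#' @param alpha blend coefficient in [0, 1].
#' @return the interpolated \code{oep_mesh}.
#' @export
interpolate_meshes <- function(meshA, meshB, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (!identical(meshA$faces, meshB$faces))
    stop("meshes are not topologically identical")
  out <- meshA
  out$vertices <- (1 - alpha) * meshA$vertices + alpha * meshB$vertices
  out
}

#' Export / import a vector field as a plain-text file
#'
#' The text file carries a commented header (phase pair, subject, units),
#' one row per vertex (id, start xyz in mm, end xyz in mm, signed modulus
#' in cm) and the face list of the start mesh, so the model can be rebuilt
#' downstream. Round-trips losslessly at the written precision.
#'
#' @param vf an \code{oep_vf}.
#' @param path output file.
#' @param digits decimal digits.
#' @export
export_vector_field <- function(vf, path, digits = 6L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# phase_pair=", vf$phase_pair),
    paste0("# subject_id=", vf$subject_id),
    paste0("# signed=", vf$signed),
    "# units=points:mm modulus:cm",
    paste0("# vertices=", length(vf$modulus)),
    "id start_x start_y start_z end_x end_y end_z modulus"), con)
  tab <- cbind(seq_along(vf$modulus),
               round(vf$start, digits), round(vf$end, digits),
               round(vf$modulus, digits))
  utils::write.table(tab, con, row.names = FALSE, col.names = FALSE)
  writeLines("# faces v1 v2 v3", con)
  utils::write.table(vf$faces, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname export_vector_field
#' @export
import_vector_field <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  getm <- function(key, default = NA_character_) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^#\\s*", key, "="), "", hit[1L])
  }
  fsep <- grep("^# faces", lines)
  hdr <- grep("^id ", lines)
  if (!length(fsep) || !length(hdr)) stop("malformed vector field file")
  vt <- utils::read.table(text = lines[(hdr + 1L):(fsep - 1L)])
  ft <- utils::read.table(text = lines[(fsep + 1L):length(lines)])
  faces <- as.matrix(ft)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  start <- unname(as.matrix(vt[, 2:4]))
  end <- unname(as.matrix(vt[, 5:7]))
  structure(
    list(start = start, end = end,
         modulus = vt[[8L]], faces = faces,
         phase_pair = getm("phase_pair"), subject_id = getm("subject_id"),
         signed = identical(getm("signed"), "TRUE")),
    class = "oep_vf")
}
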