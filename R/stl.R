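#' Read an STL surface file
#'
#' Accepts binary and ASCII STL. Facet vertices are welded into shared
#' vertices (coordinates matching within \code{weld_tol} mm collapse to one
#' vertex), then face orientation is repaired so the mesh is consistently
#' outward oriented (signed volume positive).
#'
#' @param path STL file.
#' @param weld_tol welding tolerance in mm.
#' @param validate require a watertight genus-0 result.
#' @return an \code{oep_mesh}.
#' @export
read_stl <- function(path, weld_tol = 1e-6, validate = TRUE) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  tri <- tryCatch(read_stl_ascii(path), error = function(e) NULL)
  if (is.null(tri)) tri <- read_stl_binary(path)
  if (is.null(tri) || nrow(tri) == 0L || nrow(tri) %% 3L != 0L)
    stop("unreadable STL file: ", path)
  key <- apply(round(tri / weld_tol) * weld_tol, 1L,
               function(p) paste(sprintf("%.9g", p), collapse = "/"))
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
            faces[, 1L] == faces[, 3L]))
    stop("degenerate facet after welding in ", path)
  m <- orient_mesh(list(vertices = verts, faces = faces))
  trimesh(m$vertices, m$faces, validate = validate)
}

read_stl_ascii <- function(path) {
  head <- readBin(path, "raw", n = 80L)
  if (!grepl("^\\s*solid", rawToChar(head[head != as.raw(0)])))
    stop("not ASCII")
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices")
  parts <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
  if (anyNA(coords)) stop("bad vertex line")
  t(coords)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(nf) || nf <= 0L) return(NULL)
  rec <- readBin(con, "raw", n = nf * 50L)
  if (length(rec) < nf * 50L) return(NULL)
  idx <- rep(seq(0L, (nf - 1L) * 50L, by = 50L), each = 36L) +
    rep(13:48, times = nf)
  vals <- readBin(rec[idx], "numeric", n = nf * 9L, size = 4L,
                  endian = "little")
  matrix(vals, ncol = 3L, byrow = TRUE)
}

#' Write an STL surface file
#'
#' @param mesh an \code{oep_mesh}.
#' @param path output file.
#' @param ascii write ASCII STL (default) or binary.
#' @return invisibly, a list with \code{path} and \code{watertight}; a
#'   non-watertight mesh is written anyway but flagged with a warning.
#' @export
write_stl <- function(mesh, path, ascii = TRUE) {
  chk <- mesh_check(mesh)
  if (!chk$watertight)
    warning("writing non-watertight mesh to ", path, ": ", chk$detail)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c3 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid thoraco", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2],
                nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", c3[i, 1], c3[i, 2], c3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid thoraco", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("thoraco binary stl"),
               raw(80L - nchar("thoraco binary stl"))), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], c3[i, ])), con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(list(path = path, watertight = chk$watertight))
}
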