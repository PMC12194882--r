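# Binary STL I/O. STL is unitless; this package writes micrometre
# coordinates and records the unit convention in an optional JSON sidecar,
# since the binary format has no units field.

#' Export a mesh as binary STL
#'
#' Binary little-endian STL: 80-byte header, uint32 triangle count, then
#' 50 bytes per triangle (normal, three vertices as float32, zero
#' attribute count). Output is deterministic: identical meshes produce
#' byte-identical files.
#'
#' @param mesh a triangulated \code{surface_mesh}.
#' @param file output path.
#' @param sidecar write \code{<file>.json} recording units and counts.
#' @return Invisibly, the file path.
#' @export
export_stl <- function(mesh, file, sidecar = FALSE) {
  con <- tryCatch(suppressWarnings(file(file, "wb")),
                  error = function(e) stop("cannot write '", file, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "capforge binary STL (units um)"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  n <- face_normals(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  # one triangle record: 12 float32 + uint16
  block <- matrix(0, nrow = 12, ncol = nf)
  block[1:3, ] <- t(n)
  block[4:6, ] <- t(V[F[, 1], , drop = FALSE])
  block[7:9, ] <- t(V[F[, 2], , drop = FALSE])
  block[10:12, ] <- t(V[F[, 3], , drop = FALSE])
  zero2 <- as.raw(c(0, 0))
  for (i in seq_len(nf)) {
    writeBin(block[, i], con, size = 4, endian = "little")
    writeBin(zero2, con)
  }
  if (sidecar) {
    jsonlite::write_json(
      list(units = "micrometre", triangles = nf,
           provenance = unique(mesh$provenance)),
      paste0(file, ".json"), auto_unbox = TRUE)
  }
  invisible(file)
}

#' Import a binary STL file
#'
#' Vertices within 1e-6 um are welded into an indexed mesh; facet normals
#' stored in the file are discarded and recomputed from triangle winding.
#'
#' @param file path to a binary STL file.
#' @param provenance tag applied to all faces.
#' @return A \code{surface_mesh}.
#' @export
import_stl <- function(file, provenance = "chip") {
  con <- file(file, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", nf * 50)
  if (length(raw) < nf * 50) stop("truncated STL file")
  m <- matrix(raw, nrow = 50)
  fl <- readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12 * nf,
                endian = "little")
  tri <- matrix(fl, nrow = 12)
  # interleave so triangle i occupies rows 3i-2 .. 3i
  vi <- as.vector(rbind(seq_len(nf), nf + seq_len(nf), 2 * nf + seq_len(nf)))
  verts <- rbind(t(tri[4:6, , drop = FALSE]), t(tri[7:9, , drop = FALSE]),
                 t(tri[10:12, , drop = FALSE]))[vi, , drop = FALSE]
  key <- paste(round(verts[, 1], 6), round(verts[, 2], 6),
               round(verts[, 3], 6))
  idx <- as.integer(factor(key, levels = unique(key)))
  first <- !duplicated(idx)
  V <- verts[first, , drop = FALSE][order(idx[first]), , drop = FALSE]
  Fm <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(V, Fm, provenance)
}
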