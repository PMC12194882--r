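#' Indexed triangle mesh
#'
#' The universal geometry carrier of the package: an indexed triangle mesh
#' with vertices in micrometres and a per-face provenance tag
#' (\code{"membrane"}, \code{"support"} or \code{"chip"}) that downstream
#' steps use, e.g. to exclude support structures from design-mask renders.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (um).
#' @param faces integer matrix, m x 3, 1-based vertex indices with
#'   counter-clockwise winding for outward normals.
#' @param provenance character scalar or per-face vector tagging the
#'   component each face belongs to.
#' @return An object of class \code{surface_mesh}: a list with elements
#'   \code{vertices}, \code{faces} and \code{provenance}.
#' @export
surface_mesh <- function(vertices, faces, provenance = "membrane") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(faces) == 0) {
    faces <- matrix(integer(0), 0, 3)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (ncol(vertices) != 3 && nrow(vertices) > 0) {
    stop("vertices must have 3 columns")
  }
  if (ncol(faces) != 3) stop("faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (length(provenance) == 1) provenance <- rep(provenance, nrow(faces))
  if (length(provenance) != nrow(faces)) {
    stop("provenance must be scalar or one tag per face")
  }
  structure(
    list(vertices = vertices, faces = faces,
         provenance = as.character(provenance)),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces (", paste(unique(x$provenance), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

is_surface_mesh <- function(x) inherits(x, "surface_mesh")

empty_mesh <- function(provenance = character(0)) {
  surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
               provenance = character(0))
}

#' Merge meshes by concatenation
#'
#' Concatenates vertex and face lists, preserving per-face provenance.
#' Overlapping solids remain as separate closed components; volume and void
#' queries treat the result as the CSG union of its components.
#'
#' @param meshes list of \code{surface_mesh} objects.
#' @return A single \code{surface_mesh}.
#' @export
mesh_merge <- function(meshes) {
  meshes <- Filter(function(m) nrow(m$faces) > 0 || nrow(m$vertices) > 0,
                   meshes)
  if (length(meshes) == 0) return(empty_mesh())
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  V <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  F <- do.call(rbind, Map(function(m, o) m$faces + o, meshes, off))
  p <- unlist(lapply(meshes, `[[`, "provenance"))
  surface_mesh(V, F, p)
}

#' Drop unreferenced vertices and degenerate faces
#'
#' @param mesh a \code{surface_mesh}.
#' @param area_tol faces with area below this are removed (um^2).
#' @return Compacted \code{surface_mesh}.
#' @export
mesh_compact <- function(mesh, area_tol = 1e-12) {
  if (nrow(mesh$faces) == 0) return(mesh)
  a <- face_areas(mesh)
  distinct <- mesh$faces[, 1] != mesh$faces[, 2] &
    mesh$faces[, 2] != mesh$faces[, 3] & mesh$faces[, 1] != mesh$faces[, 3]
  keep <- a > area_tol & distinct
  F <- mesh$faces[keep, , drop = FALSE]
  p <- mesh$provenance[keep]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[F], ncol = 3), p)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a \code{surface_mesh}.
#' @return Integer matrix, e x 2, each undirected edge once, with an
#'   attribute \code{count} giving the number of incident faces per edge.
#' @export
mesh_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2), drop = FALSE], F[, c(2, 3), drop = FALSE],
             F[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  first <- !duplicated(key)
  out <- cbind(pmin(e[first, 1], e[first, 2]), pmax(e[first, 1], e[first, 2]))
  attr(out, "count") <- as.integer(tab[key[first]])
  out
}

#' Euler characteristic V - E + F
#'
#' For a closed orientable surface chi = 2 - 2 genus; each through-pore of a
#' capped membrane tube adds a handle, so a tube with P pores has chi = -2P.
#'
#' @param mesh a \code{surface_mesh}.
#' @return Integer.
#' @export
euler_characteristic <- function(mesh) {
  v <- length(unique(as.vector(mesh$faces)))
  e <- nrow(mesh_edges(mesh))
  f <- nrow(mesh$faces)
  as.integer(v - e + f)
}

#' Watertightness predicate
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces and the two incident faces traverse it in opposite directions
#' (consistent orientation).
#'
#' @param mesh a \code{surface_mesh}.
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  ed <- mesh_edges(mesh)
  if (any(attr(ed, "count") != 2L)) return(FALSE)
  # orientation: each directed edge must appear exactly once
  F <- mesh$faces
  de <- rbind(F[, c(1, 2), drop = FALSE], F[, c(2, 3), drop = FALSE],
              F[, c(3, 1), drop = FALSE])
  !any(duplicated(paste(de[, 1], de[, 2])))
}

#' Boundary loops of an open mesh
#'
#' @param mesh a \code{surface_mesh}.
#' @return List of integer vectors, each an ordered cycle of vertex indices
#'   along one boundary loop.
#' @export
boundary_loops <- function(mesh) {
  F <- mesh$faces
  de <- rbind(F[, c(1, 2), drop = FALSE], F[, c(2, 3), drop = FALSE],
              F[, c(3, 1), drop = FALSE])
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  bnd <- de[cnt[key] == 1L, , drop = FALSE]
  if (nrow(bnd) == 0) return(list())
  # boundary directed edges run opposite to face winding; follow them
  nxt <- new.env(hash = TRUE, size = nrow(bnd))
  for (i in seq_len(nrow(bnd))) assign(as.character(bnd[i, 1]), bnd[i, 2], nxt)
  visited <- new.env(hash = TRUE, size = nrow(bnd))
  loops <- list()
  for (i in seq_len(nrow(bnd))) {
    s <- bnd[i, 1]
    if (!is.null(visited[[as.character(s)]])) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      assign(as.character(v), TRUE, visited)
      v <- nxt[[as.character(v)]]
      if (is.null(v) || v == s) break
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Face normals, areas, volume
#'
#' @param mesh a \code{surface_mesh}.
#' @return \code{face_normals}: m x 3 matrix of unit outward normals.
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname face_normals
#' @return \code{face_areas}: numeric vector of face areas (um^2).
#' @export
face_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  if (nrow(F) == 0) return(numeric(0))
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sqrt(rowSums(n^2)) / 2
}

#' @rdname face_normals
#' @return \code{mesh_volume}: signed enclosed volume (um^3) by the
#'   divergence theorem; positive for outward-oriented watertight meshes.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Distance from points to a mesh surface, and containment
#'
#' @param points n x 3 matrix of query points (um).
#' @param mesh a \code{surface_mesh}.
#' @return \code{point_mesh_distance}: numeric vector of unsigned distances;
#'   \code{points_in_mesh}: logical vector (ray-parity test, mesh must be
#'   watertight for meaningful results).
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3)
  cpp_point_mesh_distance(points, mesh$vertices, mesh$faces)
}

#' @rdname point_mesh_distance
#' @export
points_in_mesh <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3)
  cpp_points_in_mesh(points, mesh$vertices, mesh$faces)
}

#' Translate a mesh
#' @param mesh a \code{surface_mesh}.
#' @param offset length-3 numeric translation (um).
#' @return Translated mesh.
#' @export
mesh_translate <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.double(offset), "+")
  mesh
}
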