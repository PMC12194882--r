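# Built-in centerline generators: Hilbert space-filling curves (2D/3D,
# optionally stacked in layers) and single/double helices.

# Hilbert index -> axes for n dims, b bits per dim (Skilling's transform).
# Returns integer coordinates on the 2^b grid for one index.
hilbert_index_to_xyz <- function(h, b, n) {
  # build transposed representation: X[i] holds b bits of dimension i
  X <- integer(n)
  bitpos <- n * b - 1
  for (j in seq_len(b)) {        # MSB group first
    for (i in seq_len(n)) {
      bit <- bitwAnd(bitwShiftR(h, bitpos), 1L)
      X[i] <- bitwOr(bitwShiftL(X[i], 1), bit)
      bitpos <- bitpos - 1
    }
  }
  N <- bitwShiftL(2L, b - 1L)
  # Gray decode
  t <- bitwShiftR(X[n], 1)
  if (n > 1) for (i in n:2) X[i] <- bitwXor(X[i], X[i - 1])
  X[1] <- bitwXor(X[1], t)
  # undo excess work
  Q <- 2L
  while (Q != N) {
    P <- Q - 1L
    for (i in n:1) {
      if (bitwAnd(X[i], Q) != 0L) {
        X[1] <- bitwXor(X[1], P)
      } else {
        t <- bitwAnd(bitwXor(X[1], X[i]), P)
        X[1] <- bitwXor(X[1], t)
        X[i] <- bitwXor(X[i], t)
      }
    }
    Q <- bitwShiftL(Q, 1)
  }
  X
}

hilbert_vertices <- function(order, dims) {
  npts <- 2^(dims * order)
  t(vapply(0:(npts - 1), hilbert_index_to_xyz, integer(dims),
           b = order, n = dims))
}

#' Hilbert space-filling capillary path
#'
#' Generates the vertex sequence of a Hilbert curve of the given order in
#' 2 or 3 dimensions, scaled by \code{step} (the grid pitch, um). With
#' \code{layers > 1}, copies are stacked along z at \code{layer_gap}
#' spacing; successive layers are traversed in alternating direction so
#' each vertical connecting segment joins coincident endpoints.
#'
#' @param order curve order (>= 1): \code{4^order} vertices in 2D,
#'   \code{8^order} in 3D.
#' @param dims 2 or 3.
#' @param step grid pitch between adjacent vertices (um).
#' @param layers number of stacked copies (default 1).
#' @param layer_gap vertical spacing between layers (um).
#' @param degree,corner_fillet_radius passed to
#'   \code{\link{centerline_path}}; the default (degree 1, no fillet)
#'   returns the exact polyline, whose non-adjacent segment spacing equals
#'   \code{step}.
#' @return A \code{centerline_path}.
#' @export
hilbert_path <- function(order, dims = 2, step = 100, layers = 1,
                         layer_gap = 100, degree = 1,
                         corner_fillet_radius = 0) {
  if (!dims %in% c(2, 3)) stop("unsupported dims: ", dims)
  if (order < 1 || order != round(order)) stop("order must be integer >= 1")
  if (layers < 1 || layers != round(layers)) stop("layers must be >= 1")
  if (step <= 0) stop("step must be > 0")
  xy <- hilbert_vertices(order, dims)
  pts <- if (dims == 2) cbind(xy, 0) else xy
  pts <- pts * step
  if (layers > 1) {
    if (layer_gap <= 0) stop("layer_gap must be > 0")
    stack <- lapply(seq_len(layers) - 1, function(k) {
      p <- pts
      if (k %% 2 == 1) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      p[, 3] <- p[, 3] + k * layer_gap
      p
    })
    pts <- do.call(rbind, stack)
  }
  centerline_path(pts, degree = degree,
                  corner_fillet_radius = corner_fillet_radius)
}

#' Helical capillary paths
#'
#' One or two phase-offset helices around the z axis (second strand offset
#' by pi, the double-helix configuration).
#'
#' @param radius helix radius (um).
#' @param pitch axial rise per turn (um).
#' @param turns number of turns (> 0, fractional allowed).
#' @param strands 1 or 2.
#' @param samples_per_turn path points per turn (>= 8).
#' @param degree spline degree for the returned paths.
#' @return List of \code{centerline_path} objects (length \code{strands}).
#' @export
helix_path <- function(radius, pitch, turns, strands = 1,
                       samples_per_turn = 36, degree = 3) {
  if (radius <= 0 || pitch <= 0) stop("radius and pitch must be > 0")
  if (turns <= 0) stop("turns must be > 0")
  if (!strands %in% c(1, 2)) stop("strands must be 1 or 2")
  if (samples_per_turn < 8) {
    stop("samples_per_turn < 8 would undersample the helix")
  }
  npts <- max(2, ceiling(samples_per_turn * turns)) + 1
  th <- seq(0, 2 * pi * turns, length.out = npts)
  make <- function(phase) {
    centerline_path(cbind(radius * cos(th + phase), radius * sin(th + phase),
                          pitch * th / (2 * pi)), degree = degree)
  }
  if (strands == 1) list(make(0)) else list(make(0), make(pi))
}

#' Rotation-minimizing frames along a path
#'
#' Computes moving frames (position, tangent, normal, binormal) at
#' \code{n_stations} arc-length-equidistant stations using the
#' double-reflection rotation-minimizing frame transport, which is well
#' defined on straight segments (where the Frenet frame is not) and
#' introduces no twist about the tangent.
#'
#' @param path a \code{centerline_path}.
#' @param n_stations number of stations (>= 2).
#' @return An object of class \code{path_frames}: list of matrices
#'   \code{position}, \code{tangent}, \code{normal}, \code{binormal}
#'   (each n x 3) and the station arc lengths \code{s}.
#' @export
compute_frames <- function(path, n_stations) {
  if (n_stations < 2) stop("n_stations must be >= 2")
  rmf_frames(path, seq(0, path$path_length, length.out = n_stations))
}

# rotation-minimizing frames at arbitrary (sorted, distinct) arc lengths;
# transport is propagated on the union with a fine uniform grid so frame
# accuracy does not depend on the caller's station spacing
rmf_frames <- function(path, s_req, n_prop = 400) {
  L <- path$path_length
  grid <- seq(0, L, length.out = n_prop)
  tol <- 1e-9 * max(1, L)
  # drop grid stations (nearly) coinciding with requested ones
  near <- vapply(grid, function(g) min(abs(g - s_req)) <= tol, logical(1))
  s_all <- sort(unique(c(s_req, grid[!near])))
  f <- rmf_propagate(path, s_all)
  idx <- match(s_req, s_all)
  structure(list(position = f$position[idx, , drop = FALSE],
                 tangent = f$tangent[idx, , drop = FALSE],
                 normal = f$normal[idx, , drop = FALSE],
                 binormal = f$binormal[idx, , drop = FALSE],
                 s = s_req),
            class = "path_frames")
}

rmf_propagate <- function(path, s) {
  pos <- path_point(path, s)
  tan_ <- path_tangent(path, s)
  n <- length(s)
  nor <- matrix(0, n, 3)
  # initial normal: in-plane direction z x t (so planar build-plane paths
  # keep in-plane normals); for near-vertical tangents fall back to the
  # projected x axis
  t0 <- tan_[1, ]
  r0 <- c(-t0[2], t0[1], 0)  # z x t
  if (sqrt(sum(r0^2)) < 1e-6) {
    ref <- c(1, 0, 0)
    r0 <- ref - sum(ref * t0) * t0
  }
  nor[1, ] <- r0 / sqrt(sum(r0^2))
  for (i in seq_len(n - 1)) {
    v1 <- pos[i + 1, ] - pos[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-24) stop("degenerate station spacing (duplicate points?)")
    rL <- nor[i, ] - (2 / c1) * sum(v1 * nor[i, ]) * v1
    tL <- tan_[i, ] - (2 / c1) * sum(v1 * tan_[i, ]) * v1
    v2 <- tan_[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    r2 <- if (c2 < 1e-24) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalise against accumulated numerical drift
    r2 <- r2 - sum(r2 * tan_[i + 1, ]) * tan_[i + 1, ]
    nor[i + 1, ] <- r2 / sqrt(sum(r2^2))
  }
  bin <- cbind(tan_[, 2] * nor[, 3] - tan_[, 3] * nor[, 2],
               tan_[, 3] * nor[, 1] - tan_[, 1] * nor[, 3],
               tan_[, 1] * nor[, 2] - tan_[, 2] * nor[, 1])
  structure(list(position = pos, tangent = tan_, normal = nor,
                 binormal = bin, s = s),
            class = "path_frames")
}

#' @export
print.path_frames <- function(x, ...) {
  cat("<path_frames> ", nrow(x$position), " stations over ",
      format(max(x$s), digits = 6), " um\n", sep = "")
  invisible(x)
}
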