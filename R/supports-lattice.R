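# Truncated-octahedron lattice supports: the space-filling unit cell tiles
# on a body-centred-cubic arrangement; its 36 edges become struts, struts
# intersecting the capillary envelope are culled, survivors are piped into
# capsules.

#' Lattice support specification
#'
#' @param cell_size edge-to-edge size of the cubic bounding cell of one
#'   truncated octahedron (um).
#' @param beam_diameter strut diameter (um).
#' @param bounding_box 2 x 3 matrix: rows = (min, max) corner of the
#'   axis-aligned region to fill (um).
#' @param clearance minimum gap kept between strut surface and capillary
#'   solid when culling (um). Default 2 um, half the smallest printed beam
#'   radius.
#' @return A \code{lattice_spec}.
#' @export
lattice_spec <- function(cell_size, beam_diameter, bounding_box,
                         clearance = 2) {
  bounding_box <- as.matrix(bounding_box)
  if (!all(dim(bounding_box) == c(2, 3))) {
    stop("bounding_box must be a 2 x 3 (min, max) matrix")
  }
  if (any(bounding_box[2, ] <= bounding_box[1, ])) {
    stop("bounding_box must have positive extent in all axes")
  }
  if (cell_size <= beam_diameter) {
    stop("cell_size must exceed beam_diameter")
  }
  if (any(cell_size > bounding_box[2, ] - bounding_box[1, ])) {
    stop("cell_size exceeds the bounding box extent")
  }
  structure(list(cell_type = "truncated_octahedron", cell_size = cell_size,
                 beam_diameter = beam_diameter,
                 bounding_box = bounding_box, clearance = clearance),
            class = "lattice_spec")
}

#' Strut set
#'
#' @param p0,p1 n x 3 matrices of endpoints (um).
#' @param radius strut radius (um); 0 for raw lattice edges.
#' @return A \code{strut_set}: tibble with endpoint and radius columns.
#' @export
strut_set <- function(p0, p1, radius = 0) {
  p0 <- matrix(as.double(p0), ncol = 3)
  p1 <- matrix(as.double(p1), ncol = 3)
  stopifnot(nrow(p0) == nrow(p1))
  out <- tibble::tibble(x0 = p0[, 1], y0 = p0[, 2], z0 = p0[, 3],
                        x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
                        radius = radius)
  class(out) <- c("strut_set", class(out))
  out
}

# the 36 edges of a unit truncated octahedron centred at the origin in a
# cube of side a: vertices are the permutations of (0, +-a/4, +-a/2),
# edges join vertex pairs at distance a * sqrt(2) / 4
trunc_oct_edges_unit <- function(a) {
  verts <- list()
  vals <- list(c(0, a / 4, a / 2), c(0, a / 4, -a / 2),
               c(0, -a / 4, a / 2), c(0, -a / 4, -a / 2))
  perm3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  seen <- new.env(hash = TRUE)
  for (vset in vals) {
    for (p in seq_len(nrow(perm3))) {
      v <- vset[perm3[p, ]]
      key <- paste(format(v, digits = 12), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        verts[[length(verts) + 1]] <- v
      }
    }
  }
  V <- do.call(rbind, verts)   # 24 vertices
  d2 <- as.matrix(dist(V))^2
  target <- (a * sqrt(2) / 4)^2
  E <- which(abs(d2 - target) < 1e-9 * a^2 & upper.tri(d2), arr.ind = TRUE)
  list(vertices = V, edges = E)  # 36 edges
}

#' Edge set of a truncated-octahedron lattice filling a box
#'
#' Tiles truncated-octahedron cells (body-centred-cubic arrangement) over
#' the bounding box, deduplicates shared edges and clips edges to the box.
#'
#' @param spec a \code{\link{lattice_spec}}.
#' @return A \code{\link{strut_set}} with radius 0.
#' @export
lattice_edges <- function(spec) {
  a <- spec$cell_size
  bb <- spec$bounding_box
  cell <- trunc_oct_edges_unit(a)
  # cell centres of the two interpenetrating cubic sublattices
  rng <- function(lo, hi) seq(floor(lo / a) * a, ceiling(hi / a) * a, by = a)
  centers <- list()
  for (off in list(c(0, 0, 0), c(a / 2, a / 2, a / 2))) {
    gx <- rng(bb[1, 1] - off[1], bb[2, 1] - off[1])
    gy <- rng(bb[1, 2] - off[2], bb[2, 2] - off[2])
    gz <- rng(bb[1, 3] - off[3], bb[2, 3] - off[3])
    g <- expand.grid(x = gx + off[1], y = gy + off[2], z = gz + off[3])
    centers[[length(centers) + 1]] <- as.matrix(g)
  }
  centers <- do.call(rbind, centers)
  # keep cells whose envelope can touch the box
  keep <- centers[, 1] > bb[1, 1] - a & centers[, 1] < bb[2, 1] + a &
    centers[, 2] > bb[1, 2] - a & centers[, 2] < bb[2, 2] + a &
    centers[, 3] > bb[1, 3] - a & centers[, 3] < bb[2, 3] + a
  centers <- centers[keep, , drop = FALSE]
  seen <- new.env(hash = TRUE, size = 64 * nrow(centers))
  p0 <- list(); p1 <- list()
  fmt <- function(v) paste(round(v, 6), collapse = ",")
  for (ci in seq_len(nrow(centers))) {
    cc <- centers[ci, ]
    Vc <- sweep(cell$vertices, 2, cc, "+")
    for (ei in seq_len(nrow(cell$edges))) {
      q0 <- Vc[cell$edges[ei, 1], ]
      q1 <- Vc[cell$edges[ei, 2], ]
      seg <- clip_segment_box(q0, q1, bb)
      if (is.null(seg)) next
      k0 <- fmt(seg[1, ]); k1 <- fmt(seg[2, ])
      key <- if (k0 < k1) paste(k0, k1) else paste(k1, k0)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        p0[[length(p0) + 1]] <- seg[1, ]
        p1[[length(p1) + 1]] <- seg[2, ]
      }
    }
  }
  strut_set(do.call(rbind, p0), do.call(rbind, p1), radius = 0)
}

# clip segment to an axis-aligned box (Liang-Barsky); NULL if outside
clip_segment_box <- function(q0, q1, bb) {
  d <- q1 - q0
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-15) {
      if (q0[ax] < bb[1, ax] - 1e-9 || q0[ax] > bb[2, ax] + 1e-9) {
        return(NULL)
      }
    } else {
      ta <- (bb[1, ax] - q0[ax]) / d[ax]
      tb <- (bb[2, ax] - q0[ax]) / d[ax]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  if (t1 - t0 < 1e-9) return(NULL)
  rbind(q0 + t0 * d, q0 + t1 * d)
}

#' Cull struts too close to the capillary solid
#'
#' Removes every strut whose segment comes within
#' \code{radius + clearance} of the capillary solid surface or enters its
#' interior, testing sampled points along the full segment (step = half
#' the strut radius, minimum 5 samples) rather than endpoints only, so
#' grazing struts are caught.
#'
#' @param struts a \code{\link{strut_set}} (radius may be 0; pass the
#'   intended beam radius via \code{radius} to pre-assign it).
#' @param capillary_solid watertight \code{surface_mesh} of the capillary.
#' @param clearance minimum surface-to-surface gap (um).
#' @param radius optional strut radius override (um).
#' @return The surviving \code{\link{strut_set}} (unchanged geometry).
#' @export
cull_struts <- function(struts, capillary_solid, clearance = 2,
                        radius = NULL) {
  if (!is.null(radius)) struts$radius <- radius
  if (nrow(struts) == 0) return(struts)
  # sample all struts, query the mesh once through a grid-accelerated
  # "within threshold" test, then confirm survivors are not inside the
  # solid (a short strut can float in the lumen away from all walls)
  pts <- list()
  owner <- list()
  rad <- struts$radius
  thr <- rad + clearance
  for (i in seq_len(nrow(struts))) {
    p0 <- c(struts$x0[i], struts$y0[i], struts$z0[i])
    p1 <- c(struts$x1[i], struts$y1[i], struts$z1[i])
    L <- sqrt(sum((p1 - p0)^2))
    step <- max(rad[i] / 2, min(L / 4, clearance / 2), 1e-6)
    ns <- max(5, ceiling(L / step) + 1)
    tt <- seq(0, 1, length.out = ns)
    pts[[i]] <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                      p0[2] + tt * (p1[2] - p0[2]),
                      p0[3] + tt * (p1[3] - p0[3]))
    owner[[i]] <- rep(i, ns)
  }
  P <- do.call(rbind, pts)
  ow <- unlist(owner)
  hit <- cpp_points_within_dist(P, capillary_solid$vertices,
                                capillary_solid$faces, max(thr))
  if (length(unique(thr)) > 1) {
    # mixed radii: re-test hits against each strut's own threshold
    d <- point_mesh_distance(P[hit, , drop = FALSE], capillary_solid)
    real <- d < thr[ow[hit]]
    hit[hit] <- real
  }
  keep <- !(seq_len(nrow(struts)) %in% ow[hit])
  if (any(keep)) {
    mids <- cbind((struts$x0 + struts$x1) / 2, (struts$y0 + struts$y1) / 2,
                  (struts$z0 + struts$z1) / 2)[keep, , drop = FALSE]
    inside <- points_in_mesh(mids, capillary_solid)
    keep[keep] <- !inside
  }
  struts[keep, , drop = FALSE]
}

#' Pipe struts into capsule solids
#'
#' Converts each strut segment into a capsule (cylinder with hemispherical
#' caps) of the given beam diameter and merges all capsules into one mesh
#' tagged \code{support}. Zero-length struts are skipped with a warning.
#'
#' @param struts a \code{\link{strut_set}}.
#' @param beam_diameter capsule diameter (um).
#' @param n_seg circumferential resolution of each capsule.
#' @return A \code{surface_mesh}.
#' @export
pipe_struts <- function(struts, beam_diameter, n_seg = 24) {
  if (beam_diameter <= 0) stop("beam_diameter must be > 0")
  if (nrow(struts) == 0) return(empty_mesh())
  parts <- list()
  skipped <- 0
  for (i in seq_len(nrow(struts))) {
    p0 <- c(struts$x0[i], struts$y0[i], struts$z0[i])
    p1 <- c(struts$x1[i], struts$y1[i], struts$z1[i])
    if (sqrt(sum((p1 - p0)^2)) < 1e-9) {
      skipped <- skipped + 1
      next
    }
    parts[[length(parts) + 1]] <- capsule_mesh(p0, p1, beam_diameter / 2,
                                               n_seg = n_seg,
                                               cap_rings = max(2, n_seg %/% 4))
  }
  if (skipped > 0) warning(skipped, " zero-length strut(s) skipped")
  mesh_merge(parts)
}

#' Connectivity report for a strut network
#'
#' Builds a graph over strut endpoints (merged within \code{tol}) and
#' reports connected components, flagging floating islands not anchored to
#' the base plane. Printability requires every component to reach the base.
#'
#' @param struts a \code{\link{strut_set}}.
#' @param base_z height of the base plane (um).
#' @param tol endpoint merge tolerance (um, default 0.1).
#' @return A tibble with one row per component: \code{component},
#'   \code{n_struts}, \code{anchored}, \code{min_z}.
#' @export
connectivity_check <- function(struts, base_z = 0, tol = 0.1) {
  n <- nrow(struts)
  if (n == 0) {
    return(tibble::tibble(component = integer(0), n_struts = integer(0),
                          anchored = logical(0), min_z = numeric(0)))
  }
  pts <- rbind(as.matrix(struts[, c("x0", "y0", "z0")]),
               as.matrix(struts[, c("x1", "y1", "z1")]))
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol),
               round(pts[, 3] / tol))
  node <- as.integer(factor(key, levels = unique(key)))
  # union-find over merged endpoints
  parent <- seq_len(max(node))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n)) {
    a <- find(node[i]); b <- find(node[n + i])
    if (a != b) parent[a] <- b
  }
  comp_of_strut <- vapply(seq_len(n), function(i) find(node[i]), integer(1))
  comp_id <- as.integer(factor(comp_of_strut))
  zmin <- pmin(struts$z0, struts$z1)
  rows <- lapply(sort(unique(comp_id)), function(cid) {
    sel <- comp_id == cid
    mz <- min(zmin[sel])
    tibble::tibble(component = cid, n_struts = sum(sel),
                   anchored = mz <= base_z + tol, min_z = mz)
  })
  out <- do.call(rbind, rows)
  attr(out, "strut_component") <- comp_id
  out
}

#' Drop strut components not anchored to the base
#'
#' Removes floating islands (e.g. short struts left inside the lumen
#' after culling) that \code{\link{connectivity_check}} flags.
#'
#' @inheritParams connectivity_check
#' @return The anchored subset of \code{struts}.
#' @export
drop_floating_struts <- function(struts, base_z = 0, tol = 0.1) {
  if (nrow(struts) == 0) return(struts)
  rep_ <- connectivity_check(struts, base_z, tol)
  comp <- attr(rep_, "strut_component")
  ok <- rep_$component[rep_$anchored]
  struts[comp %in% ok, , drop = FALSE]
}
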