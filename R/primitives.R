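# Watertight solid primitives used by the support and chip generators.
# All primitives return counter-clockwise-wound (outward normal) meshes.

# orthonormal basis perpendicular to unit vector d
perp_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# stitch two consecutive rings of n vertices into 2n triangles.
# i0, i1: starting indices (1-based) of the two rings; winding chosen so
# normals point away from the axis when ring i1 is "above" ring i0.
ring_band <- function(i0, i1, n) {
  j <- seq_len(n)
  jn <- c(seq_len(n)[-1], 1L)
  rbind(cbind(i0 + j - 1L, i0 + jn - 1L, i1 + j - 1L),
        cbind(i0 + jn - 1L, i1 + jn - 1L, i1 + j - 1L))
}

# triangle fan from a center vertex to a ring (cap); flip reverses winding
ring_fan <- function(center, i0, n, flip = FALSE) {
  j <- seq_len(n)
  jn <- c(seq_len(n)[-1], 1L)
  if (flip) cbind(center, i0 + jn - 1L, i0 + j - 1L)
  else cbind(center, i0 + j - 1L, i0 + jn - 1L)
}

#' Capsule (cylinder with hemispherical caps) between two points
#'
#' Used to realise lattice struts and polygonal-support beams as solid
#' "pipes with rounded caps".
#'
#' @param p0,p1 segment endpoints (um).
#' @param radius capsule radius (um).
#' @param n_seg circumferential segments (default 24, keeping the meshed
#'   volume within ~1\% of the analytic capsule volume).
#' @param cap_rings latitude rings per hemispherical cap.
#' @param provenance face tag.
#' @return Watertight \code{surface_mesh}.
#' @export
capsule_mesh <- function(p0, p1, radius, n_seg = 24, cap_rings = 6,
                         provenance = "support") {
  p0 <- as.double(p0); p1 <- as.double(p1)
  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  if (L <= 0) stop("zero-length capsule")
  if (radius <= 0) stop("radius must be > 0")
  d <- axis / L
  b <- perp_basis(d)
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  circ <- outer(cos(ang), b$e1) + outer(sin(ang), b$e2)  # n_seg x 3 unit

  rings <- list()
  # bottom hemisphere: from pole ring up to equator at p0
  phis <- seq(-pi / 2, 0, length.out = cap_rings + 1)[-1]
  for (phi in phis) {
    r <- radius * cos(phi)
    z <- radius * sin(phi)
    rings[[length(rings) + 1]] <- sweep(circ * r, 2, p0 + z * d, "+")
  }
  # top equator + hemisphere
  phis <- seq(0, pi / 2, length.out = cap_rings + 1)
  phis <- phis[-length(phis)]
  for (phi in phis) {
    r <- radius * cos(phi)
    z <- radius * sin(phi)
    rings[[length(rings) + 1]] <- sweep(circ * r, 2, p1 + z * d, "+")
  }
  nr <- length(rings)
  V <- do.call(rbind, rings)
  Vs <- rbind(V, p0 - radius * d, p1 + radius * d)
  pole0 <- nrow(V) + 1L
  pole1 <- nrow(V) + 2L
  Fb <- do.call(rbind, lapply(seq_len(nr - 1), function(k) {
    ring_band((k - 1L) * n_seg + 1L, k * n_seg + 1L, n_seg)
  }))
  Fb <- rbind(Fb,
              ring_fan(pole0, 1L, n_seg, flip = TRUE),
              ring_fan(pole1, (nr - 1L) * n_seg + 1L, n_seg, flip = FALSE))
  surface_mesh(Vs, Fb, provenance)
}

#' Conical frustum solid
#'
#' Vertical frustum used by the cone-support generator: radius tapers
#' linearly from \code{r_base} at \code{z0} to \code{r_top} at \code{z1}.
#'
#' @param center_xy length-2 centre of the axis in the build plane (um).
#' @param z0,z1 bottom and top heights (um), \code{z1 > z0}.
#' @param r_base,r_top bottom and top radii (um).
#' @param n_seg circumferential segments.
#' @param n_rings number of intermediate height rings on the lateral wall.
#' @param provenance face tag.
#' @return Watertight \code{surface_mesh}.
#' @export
frustum_mesh <- function(center_xy, z0, z1, r_base, r_top, n_seg = 32,
                         n_rings = 8, provenance = "support") {
  if (z1 <= z0) stop("z1 must exceed z0")
  if (r_base <= 0 || r_top <= 0) stop("radii must be > 0")
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  zs <- seq(z0, z1, length.out = n_rings + 1)
  rs <- r_base + (r_top - r_base) * (zs - z0) / (z1 - z0)
  V <- do.call(rbind, lapply(seq_along(zs), function(k) {
    cbind(center_xy[1] + rs[k] * cos(ang), center_xy[2] + rs[k] * sin(ang),
          zs[k])
  }))
  nr <- length(zs)
  V <- rbind(V, c(center_xy, z0), c(center_xy, z1))
  pole0 <- n_seg * nr + 1L
  pole1 <- n_seg * nr + 2L
  Fb <- do.call(rbind, lapply(seq_len(nr - 1), function(k) {
    ring_band((k - 1L) * n_seg + 1L, k * n_seg + 1L, n_seg)
  }))
  Fb <- rbind(Fb,
              ring_fan(pole0, 1L, n_seg, flip = TRUE),
              ring_fan(pole1, (nr - 1L) * n_seg + 1L, n_seg, flip = FALSE))
  surface_mesh(V, Fb, provenance)
}

#' Solid annular cylinder (collar ring / hollow nozzle port)
#'
#' A tube-of-revolution solid between inner radius \code{r_in} and outer
#' radius \code{r_out}, extruded along direction \code{axis} over length
#' \code{height}, centred at \code{center}. Watertight with a through-hole
#' (genus 1, Euler characteristic 0).
#'
#' @param center centre of the ring (um).
#' @param axis extrusion direction (normalised internally).
#' @param r_in,r_out inner and outer radii (um), \code{r_out > r_in > 0}.
#' @param height extrusion length (um).
#' @param n_seg circumferential segments.
#' @param provenance face tag.
#' @return Watertight \code{surface_mesh}.
#' @export
annular_cylinder_mesh <- function(center, axis = c(0, 0, 1), r_in, r_out,
                                  height, n_seg = 48,
                                  provenance = "support") {
  if (r_in <= 0 || r_out <= r_in) stop("need r_out > r_in > 0")
  if (height <= 0) stop("height must be > 0")
  d <- as.double(axis); d <- d / sqrt(sum(d^2))
  b <- perp_basis(d)
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  circ <- outer(cos(ang), b$e1) + outer(sin(ang), b$e2)
  c0 <- as.double(center) - d * height / 2
  c1 <- as.double(center) + d * height / 2
  ring <- function(cen, r) sweep(circ * r, 2, cen, "+")
  # rings: 1 outer-bottom, 2 outer-top, 3 inner-top, 4 inner-bottom
  V <- rbind(ring(c0, r_out), ring(c1, r_out), ring(c1, r_in), ring(c0, r_in))
  i <- function(k) (k - 1L) * n_seg + 1L
  Fb <- rbind(
    ring_band(i(1), i(2), n_seg),               # outer wall, normals out
    ring_band(i(2), i(3), n_seg),               # top annulus
    ring_band(i(3), i(4), n_seg),               # inner wall, normals in
    ring_band(i(4), i(1), n_seg))               # bottom annulus
  surface_mesh(V, Fb, provenance)
}

# simple ear-clipping triangulation of a simple polygon (n x 2, CCW or CW)
triangulate_polygon <- function(poly) {
  # drop consecutive (near-)duplicate vertices
  n <- nrow(poly)
  if (n >= 2) {
    scale <- max(abs(poly)) + 1
    d <- sqrt(rowSums((poly - poly[c(2:n, 1), , drop = FALSE])^2))
    poly <- poly[d > 1e-9 * scale, , drop = FALSE]
  }
  n <- nrow(poly)
  if (n < 3) stop("polygon needs at least 3 vertices")
  area2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  idx <- if (area2 < 0) rev(seq_len(n)) else seq_len(n)  # force CCW
  tris <- matrix(integer(0), 0, 3)
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  in_tri <- function(p, a, b, c_) {
    d1 <- cross2(a, b, p); d2 <- cross2(b, c_, p); d3 <- cross2(c_, a, p)
    (d1 >= -1e-12) && (d2 >= -1e-12) && (d3 >= -1e-12)
  }
  guard <- 0
  while (length(idx) > 3 && guard < 10 * n^2) {
    guard <- guard + 1
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      ia <- idx[if (k == 1) m else k - 1]
      ib <- idx[k]
      ic <- idx[if (k == m) 1 else k + 1]
      a <- poly[ia, ]; b <- poly[ib, ]; c_ <- poly[ic, ]
      if (cross2(a, b, c_) <= 1e-12) next  # reflex or degenerate
      others <- setdiff(idx, c(ia, ib, ic))
      blocked <- FALSE
      for (o in others) {
        if (in_tri(poly[o, ], a, b, c_)) { blocked <- TRUE; break }
      }
      if (!blocked) {
        tris <- rbind(tris, c(ia, ib, ic))
        idx <- idx[-k]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) stop("polygon triangulation failed (self-intersecting?)")
  }
  rbind(tris, idx)
}

# TRUE if any two non-adjacent polygon edges intersect
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || abs(i - j) == n - 1) next
      if (seg_int(poly[i, ], poly[if (i == n) 1 else i + 1, ],
                  poly[j, ], poly[if (j == n) 1 else j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Extrude a simple polygon into a watertight prism
#'
#' @param poly n x 2 matrix of polygon vertices (um), simple (non
#'   self-intersecting), any winding.
#' @param z0,z1 bottom and top heights (um).
#' @param provenance face tag.
#' @return Watertight \code{surface_mesh}.
#' @export
extrude_polygon_mesh <- function(poly, z0, z1, provenance = "chip") {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n >= 2) {  # drop consecutive duplicates so indices stay aligned
    scale <- max(abs(poly)) + 1
    d <- sqrt(rowSums((poly - poly[c(2:n, 1), , drop = FALSE])^2))
    poly <- poly[d > 1e-9 * scale, , drop = FALSE]
  }
  if (z1 <= z0) stop("z1 must exceed z0")
  if (polygon_self_intersects(poly)) stop("footprint polygon self-intersects")
  n <- nrow(poly)
  # normalise to CCW so side winding is consistent
  area2 <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  if (area2 < 0) poly <- poly[rev(seq_len(n)), , drop = FALSE]
  tri <- triangulate_polygon(poly)
  V <- rbind(cbind(poly, z0), cbind(poly, z1))
  top <- tri + n            # CCW seen from above -> outward up
  bot <- tri[, c(1, 3, 2), drop = FALSE]
  j <- seq_len(n)
  jn <- c(seq_len(n)[-1], 1L)
  side <- rbind(cbind(j, jn, n + j), cbind(jn, n + jn, n + j))
  surface_mesh(V, rbind(bot, top, side), provenance)
}

#' UV sphere (testing and calibration geometry)
#'
#' @param center centre (um).
#' @param radius radius (um).
#' @param n_seg longitudinal segments; latitudes are \code{n_seg / 2}.
#' @param provenance face tag.
#' @return Watertight \code{surface_mesh}.
#' @export
uv_sphere_mesh <- function(center = c(0, 0, 0), radius = 1, n_seg = 32,
                           provenance = "chip") {
  n_lat <- max(3L, as.integer(n_seg / 2))
  ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  phis <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)
  phis <- phis[-c(1, length(phis))]
  V <- do.call(rbind, lapply(phis, function(phi) {
    cbind(center[1] + radius * cos(phi) * cos(ang),
          center[2] + radius * cos(phi) * sin(ang),
          center[3] + radius * sin(phi))
  }))
  nr <- length(phis)
  V <- rbind(V, center - c(0, 0, radius), center + c(0, 0, radius))
  pole0 <- nr * n_seg + 1L
  pole1 <- nr * n_seg + 2L
  Fb <- do.call(rbind, lapply(seq_len(nr - 1), function(k) {
    ring_band((k - 1L) * n_seg + 1L, k * n_seg + 1L, n_seg)
  }))
  Fb <- rbind(Fb,
              ring_fan(pole0, 1L, n_seg, flip = TRUE),
              ring_fan(pole1, (nr - 1L) * n_seg + 1L, n_seg, flip = FALSE))
  surface_mesh(V, Fb, provenance)
}
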