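# Independent, pure-R oracles used to cross-check the compiled kernels and
# the parametric constructions.

# point-to-triangle distance (region classification, independent of the
# C++ implementation path)
r_point_tri_dist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

r_min_dist_to_mesh <- function(p, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  min(vapply(seq_len(nrow(F)), function(f) {
    r_point_tri_dist(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
  }, numeric(1)))
}

# Otsu threshold by exhaustive between-class variance maximisation
r_otsu <- function(m, levels = 256) {
  lo <- min(m); hi <- max(m)
  h <- hist(as.vector(m), breaks = seq(lo, hi, length.out = levels + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- mids[1]
  for (k in seq_len(levels - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- h$breaks[k + 1] }
  }
  thr
}

# calibration tube whose grid cells are exactly square (s_l = s_r =
# p_d + p_s), so side-pore elongation is measurable against a square
# baseline: pi * l_d is an exact multiple of the pitch
calibration_tube <- function(length_um = 1000, z = 0) {
  spec <- capillary_spec(lumen_diameter = 120 / pi, pore_diameter = 5,
                         pore_spacing = 5, membrane_thickness = 10)
  path <- centerline_path(cbind(seq(0, length_um, length.out = 11), 0, z),
                          degree = 1)
  grid <- subdivision_grid(path$path_length, spec)
  list(path = path, spec = spec, grid = grid)
}

# the layered-Hilbert reference chip: two stacked second-order Hilbert
# curves, 40 um lumen, 5 um pores at 8 um spacing, 10 um wall, 10 um
# lattice beams
reference_chip_config <- function(outdir, decimate = 0) {
  list(
    seed = 1,
    path = list(source = "hilbert", order = 2, dims = 2, step = 150,
                layers = 2, layer_gap = 120, degree = 3,
                corner_fillet_radius = 20),
    capillary = list(ld = 40, pd = 5, ps = 8, wall = 10),
    supports = list(strategy = "lattice", cell_size = 100,
                    beam_diameter = 10, clearance = 2, margin = 40),
    chip = list(),
    output = list(dir = outdir, decimate = decimate)
  )
}
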