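# Chip assembly: flat adhesion base below the scaffold, vertical nozzle
# ports sized for heat-shrink tubing, retaining walls, mesh decimation and
# STL export. The scaffold datum is the base top face at z = 0.

#' Chip specification
#'
#' @param base_thickness thickness of the flat adhesion base (um).
#' @param base_margin margin added around the scaffold footprint (um).
#' @param nozzle_outer_diameter outer diameter of the vertical nozzle
#'   ports (um); default 508 um = 0.020 inch, mating the inner diameter of
#'   the heat-shrink tubing interface.
#' @param nozzle_bore bore diameter, continuous with the capillary lumen
#'   (um).
#' @param nozzle_height port height above the base (um).
#' @param retaining_wall_height,retaining_wall_thickness dimensions of the
#'   resin retaining wall around each nozzle (um); the wall keeps sealing
#'   resin out of the microvasculature.
#' @return A \code{chip_spec}.
#' @export
chip_spec <- function(base_thickness = 20, base_margin = 100,
                      nozzle_outer_diameter = 508, nozzle_bore = 40,
                      nozzle_height = 300, retaining_wall_height = 100,
                      retaining_wall_thickness = 30) {
  vals <- c(base_thickness = base_thickness, base_margin = base_margin,
            nozzle_outer_diameter = nozzle_outer_diameter,
            nozzle_bore = nozzle_bore, nozzle_height = nozzle_height,
            retaining_wall_height = retaining_wall_height,
            retaining_wall_thickness = retaining_wall_thickness)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0) {
    stop("chip_spec: all dimensions must be > 0; offending: ",
         paste(bad, collapse = ", "))
  }
  if (nozzle_bore >= nozzle_outer_diameter) {
    stop("nozzle_bore must be smaller than nozzle_outer_diameter")
  }
  structure(as.list(vals), class = "chip_spec")
}

#' Flat chip base
#'
#' A watertight slab with its top face at z = 0, the scaffold datum.
#'
#' @param footprint n x 2 polygon outline (um), or NULL to derive the
#'   convex hull of \code{scaffold}'s plan projection plus the margin.
#' @param spec a \code{\link{chip_spec}}.
#' @param scaffold optional \code{surface_mesh} used to derive/validate
#'   the footprint.
#' @return A \code{surface_mesh} tagged \code{chip}.
#' @export
build_base <- function(footprint = NULL, spec, scaffold = NULL) {
  if (is.null(footprint)) {
    if (is.null(scaffold)) stop("need a footprint or a scaffold")
    footprint <- footprint_hull(scaffold, spec$base_margin)
  } else {
    footprint <- as.matrix(footprint)
    if (!is.null(scaffold)) {
      xy <- scaffold$vertices[, 1:2, drop = FALSE]
      if (any(xy[, 1] < min(footprint[, 1]) | xy[, 1] > max(footprint[, 1]) |
              xy[, 2] < min(footprint[, 2]) | xy[, 2] > max(footprint[, 2]))) {
        stop("footprint does not enclose the scaffold plan projection")
      }
    }
  }
  extrude_polygon_mesh(footprint, -spec$base_thickness, 0,
                       provenance = "chip")
}

#' Convex-hull footprint of a scaffold projection plus margin
#'
#' @param scaffold a \code{surface_mesh}.
#' @param margin outward offset applied to the hull (um).
#' @return n x 2 polygon matrix (counter-clockwise).
#' @export
footprint_hull <- function(scaffold, margin) {
  xy <- unique(round(scaffold$vertices[, 1:2, drop = FALSE], 6))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  poly <- xy[rev(h), , drop = FALSE]  # chull returns clockwise
  ctr <- colMeans(poly)
  d <- sweep(poly, 2, ctr)
  len <- sqrt(rowSums(d^2))
  poly + d / len * margin
}

#' Vertical nozzle ports
#'
#' Two hollow vertical ports whose bore is continuous with the capillary
#' lumen and whose outer surface mates the 0.020-inch inner-diameter
#' heat-shrink tubing, each wrapped by a retaining wall that keeps sealing
#' resin out of the scaffold. Ports stand on the base top (z = 0).
#'
#' @param path_ends 2 x 3 matrix: the two capillary end positions (um);
#'   ports are placed at their plan (x, y) locations.
#' @param spec a \code{\link{chip_spec}}.
#' @param with_retaining_wall include the annular retaining wall.
#' @return A \code{surface_mesh} tagged \code{chip}.
#' @export
build_nozzles <- function(path_ends, spec, with_retaining_wall = TRUE) {
  path_ends <- matrix(as.double(path_ends), ncol = 3)
  if (nrow(path_ends) != 2) stop("path_ends must give exactly two ends")
  if (any(path_ends[, 3] > spec$nozzle_height + 1e-9)) {
    stop("path end above nozzle_height: ports cannot reach the capillary")
  }
  parts <- list()
  for (i in 1:2) {
    ctr <- c(path_ends[i, 1], path_ends[i, 2], spec$nozzle_height / 2)
    parts[[length(parts) + 1]] <- annular_cylinder_mesh(
      ctr, axis = c(0, 0, 1), r_in = spec$nozzle_bore / 2,
      r_out = spec$nozzle_outer_diameter / 2, height = spec$nozzle_height,
      provenance = "chip")
    if (with_retaining_wall) {
      wall_in <- spec$nozzle_outer_diameter / 2 +
        spec$retaining_wall_thickness
      parts[[length(parts) + 1]] <- annular_cylinder_mesh(
        c(ctr[1], ctr[2], spec$retaining_wall_height / 2),
        axis = c(0, 0, 1), r_in = wall_in,
        r_out = wall_in + spec$retaining_wall_thickness,
        height = spec$retaining_wall_height, provenance = "chip")
    }
  }
  mesh_merge(parts)
}

#' Assemble chip components into one mesh
#'
#' Concatenates the component meshes into a single multi-component mesh;
#' per-face provenance is retained so downstream steps (design-mask
#' rendering, void analysis) can address components. Overlapping closed
#' components are treated as a CSG union by volume and void queries.
#'
#' @param components list of \code{surface_mesh} objects.
#' @return A \code{surface_mesh}.
#' @export
assemble <- function(components) {
  if (!is.list(components) || length(components) == 0) {
    stop("assemble() needs a non-empty list of meshes")
  }
  if (length(components) == 1) return(components[[1]])
  mesh_merge(components)
}

#' Decimate a mesh by edge collapse
#'
#' Iterative shortest-edge collapse with manifoldness (link condition) and
#' normal-flip guards; boundary edges are never collapsed. Watertight
#' input stays watertight. The symmetric Hausdorff distance between input
#' and output is estimated from sampled vertex distances and reported as
#' an attribute.
#'
#' @param mesh a \code{surface_mesh}.
#' @param reduction_fraction fraction of faces to remove, in (0, 1);
#'   default 0.95, the mesh-budget reduction used before slicing.
#' @return Decimated \code{surface_mesh} with attributes
#'   \code{hausdorff_um} and \code{achieved_reduction}.
#' @export
decimate <- function(mesh, reduction_fraction = 0.95) {
  if (!is.numeric(reduction_fraction) || reduction_fraction <= 0 ||
      reduction_fraction >= 1) {
    stop("reduction_fraction must be strictly between 0 and 1")
  }
  nf0 <- nrow(mesh$faces)
  target <- max(4L, as.integer(floor(nf0 * (1 - reduction_fraction))))
  res <- cpp_decimate(mesh$vertices, mesh$faces, target, 60L)
  out <- surface_mesh(res$vertices, res$faces,
                      provenance = mesh$provenance[1])
  achieved <- 1 - nrow(out$faces) / nf0
  if (achieved < reduction_fraction - 0.05) {
    stop("decimation stalled: achieved reduction ",
         round(achieved, 4), " < requested ", reduction_fraction)
  }
  # sampled two-sided vertex-to-surface distance
  samp <- function(m, k) {
    idx <- unique(as.integer(seq(1, nrow(m$vertices),
                                 length.out = min(k, nrow(m$vertices)))))
    m$vertices[idx, , drop = FALSE]
  }
  h1 <- max(point_mesh_distance(samp(out, 500), mesh))
  h2 <- max(point_mesh_distance(samp(mesh, 500), out))
  attr(out, "hausdorff_um") <- max(h1, h2)
  attr(out, "achieved_reduction") <- achieved
  out
}
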