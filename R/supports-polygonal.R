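#' Polygonal support specification
#'
#' Polygonal supports suspend a planar capillary above the substrate: at
#' each anchor position a circular collar wraps the capillary outer
#' surface, carried by \code{polygon_sides} vertical beams arranged in a
#' polygon and diagonal struts connecting the beam tops to the collar.
#'
#' @param polygon_sides number of beams (>= 3).
#' @param beam_diameter beam diameter (um).
#' @param collar_clearance radial gap between capillary outer surface and
#'   collar inner surface (um).
#' @param placement \code{"equidistant"} or \code{"at_fov_seams"}.
#' @param spacing anchor spacing for equidistant placement (um).
#' @param rotational_offset rotation of the beam polygon about the
#'   vertical axis (degrees).
#' @return A \code{polygonal_support_spec}.
#' @export
polygonal_support_spec <- function(polygon_sides = 4, beam_diameter = 15,
                                   collar_clearance = 0,
                                   placement = c("equidistant",
                                                 "at_fov_seams"),
                                   spacing = 250, rotational_offset = 0) {
  placement <- match.arg(placement)
  if (polygon_sides < 3) stop("polygon_sides must be >= 3")
  if (beam_diameter <= 0) stop("beam_diameter must be > 0")
  if (collar_clearance < 0) stop("collar_clearance must be >= 0")
  if (placement == "equidistant" && spacing <= 0) {
    stop("spacing must be > 0 for equidistant placement")
  }
  structure(list(polygon_sides = as.integer(polygon_sides),
                 beam_diameter = beam_diameter,
                 collar_clearance = collar_clearance,
                 placement = placement, spacing = spacing,
                 rotational_offset = rotational_offset),
            class = "polygonal_support_spec")
}

#' Anchor arc lengths for polygonal supports
#'
#' @param path a \code{centerline_path}.
#' @param spec a \code{\link{polygonal_support_spec}}.
#' @param layout \code{\link{fov_layout}}, required for
#'   \code{at_fov_seams} placement.
#' @return Numeric vector of arc lengths (um).
#' @export
support_positions <- function(path, spec, layout = NULL) {
  if (spec$placement == "equidistant") {
    n <- max(2, floor(path$path_length / spec$spacing) + 1)
    seq(0, path$path_length, length.out = n)
  } else {
    if (is.null(layout)) stop("at_fov_seams placement needs a fov_layout")
    predict_fov_seams(layout, path)$s
  }
}

#' Build polygonal support assemblies
#'
#' One assembly per anchor: collar ring around the capillary outer surface,
#' \code{polygon_sides} vertical beams from the base plane up to collar
#' height, and diagonal struts from each beam top to the collar. All parts
#' are watertight solids merged into one mesh tagged \code{support}.
#'
#' @param path the capillary centerline.
#' @param spec a \code{\link{polygonal_support_spec}}.
#' @param positions anchor arc lengths within \code{[0, P_l]} (um); see
#'   \code{\link{support_positions}}.
#' @param capillary_outer_diameter outer diameter of the (thickened)
#'   capillary the collar wraps (um).
#' @param base_z height of the base plane the beams stand on (um).
#' @return A \code{surface_mesh} (empty for empty \code{positions}).
#' @export
polygonal_supports <- function(path, spec, positions,
                               capillary_outer_diameter, base_z = 0) {
  if (length(positions) == 0) return(empty_mesh())
  if (any(positions < -1e-9 | positions > path$path_length + 1e-9)) {
    stop("positions must lie within [0, P_l]")
  }
  r_cap <- capillary_outer_diameter / 2
  bd <- spec$beam_diameter
  r_in <- r_cap + spec$collar_clearance
  r_out <- r_in + bd
  frames <- rmf_frames(path, sort(positions))
  parts <- list()
  for (i in seq_along(positions)) {
    ctr <- frames$position[i, ]
    tang <- frames$tangent[i, ]
    # the beam polygon lives in the cross-section plane spanned by the
    # horizontal normal m and the vertical
    m <- normalize3(c(-tang[2], tang[1], 0))
    if (sqrt(tang[1]^2 + tang[2]^2) < 1e-6) m <- c(1, 0, 0)
    r_poly <- r_out + 2 * bd
    if (ctr[3] - r_poly < base_z) {
      stop("support position s = ", format(frames$s[i], digits = 6),
           ": capillary underside is within beam-diameter clearance ",
           "of the base plane")
    }
    parts[[length(parts) + 1]] <- annular_cylinder_mesh(
      ctr, axis = tang, r_in = r_in, r_out = r_out, height = bd)
    ang0 <- (spec$rotational_offset + 180 / spec$polygon_sides) * pi / 180
    n <- spec$polygon_sides
    verts <- matrix(0, n, 3)
    dirs <- matrix(0, n, 3)
    for (kk in seq_len(n)) {
      a <- ang0 + 2 * pi * (kk - 1) / n
      dirs[kk, ] <- cos(a) * m + sin(a) * c(0, 0, 1)
      verts[kk, ] <- ctr + r_poly * dirs[kk, ]
    }
    for (kk in seq_len(n)) {
      nxt <- if (kk == n) 1 else kk + 1
      # polygon edge around the capillary
      parts[[length(parts) + 1]] <- capsule_mesh(verts[kk, ], verts[nxt, ],
                                                 bd / 2)
      # diagonal strut to the nearest collar point
      parts[[length(parts) + 1]] <- capsule_mesh(
        verts[kk, ], ctr + (r_in + bd / 2) * dirs[kk, ], bd / 2)
      # legs from below-axis vertices down-and-outward to the base plane
      # (slanted outward so they clear the capillary underside)
      if (dirs[kk, 3] < -0.2) {
        side <- sum(dirs[kk, ] * m)
        side <- if (abs(side) < 1e-9) 1 else sign(side)
        foot <- c(ctr[1] + side * r_poly * m[1],
                  ctr[2] + side * r_poly * m[2], base_z + bd / 2)
        parts[[length(parts) + 1]] <- capsule_mesh(verts[kk, ], foot,
                                                   bd / 2)
      }
    }
  }
  m <- mesh_merge(parts)
  attr(m, "n_assemblies") <- length(positions)
  m
}

normalize3 <- function(v) {
  l <- sqrt(sum(v^2))
  if (l < 1e-12) c(1, 0, 0) else v / l
}
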