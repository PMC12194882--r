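# Cone supports: mesoscale frusta printed on the base that prop up soft
# capillary scaffolds from below. Taper angles below ~15 degrees from
# vertical fail to print because overhanging geometry blocks the laser
# path, so the taper is validated and guaranteed by construction. The
# capillary envelope (outer surface inflated by a clearance) is subtracted
# so no cone material enters the perfusable volume.

#' Cone support specification
#'
#' @param taper_angle wall angle from vertical (degrees, >= 15).
#' @param tip_radius radius of the cone top face (um).
#' @param positions n x 2 matrix of anchor points in the build plane (um).
#' @param subtract_capillary logical; keep cone material out of the
#'   (inflated) capillary envelope (default TRUE).
#' @param clearance inflation of the capillary envelope before
#'   subtraction (um).
#' @return A \code{cone_support_spec}.
#' @export
cone_support_spec <- function(taper_angle = 15, tip_radius = 10, positions,
                              subtract_capillary = TRUE, clearance = 0) {
  if (taper_angle < 15) {
    stop("taper_angle must be >= 15 degrees (shallower cones shadow the ",
         "laser path and fail to print)")
  }
  positions <- matrix(as.double(positions), ncol = 2)
  if (tip_radius <= 0) stop("tip_radius must be > 0")
  structure(list(taper_angle = taper_angle, tip_radius = tip_radius,
                 positions = positions,
                 subtract_capillary = isTRUE(subtract_capillary),
                 clearance = clearance),
            class = "cone_support_spec")
}

# lowest z of the capillary envelope above plan position (x, y), or NA if
# the point is not under the capillary; envelope = centerline tube of
# radius r_env
envelope_underside_z <- function(path, r_env, x, y) {
  xyz <- path$dense$xyz
  rho2 <- (xyz[, 1] - x)^2 + (xyz[, 2] - y)^2
  under <- rho2 < r_env^2
  if (!any(under)) return(NA_real_)
  min(xyz[under, 3] - sqrt(r_env^2 - rho2[under]))
}

#' Build cone supports under a capillary
#'
#' Each anchor gets a conical frustum rising from the base plane to touch
#' the capillary underside, with wall taper equal to
#' \code{spec$taper_angle} (so the minimum facet taper of the generated
#' mesh is the specified angle). With \code{subtract_capillary}, any mesh
#' vertex falling inside the inflated capillary envelope is projected down
#' onto the envelope underside, conforming the cone top to the membrane
#' without entering the lumen. Anchors not under the capillary are built
#' to the fallback height and flagged in the contact report.
#'
#' @param spec a \code{\link{cone_support_spec}}.
#' @param path the capillary centerline (used for the analytic envelope).
#' @param capillary_outer_diameter outer diameter of the capillary (um).
#' @param base_z base plane height (um).
#' @param fallback_height frustum height used when an anchor misses the
#'   capillary (um).
#' @param n_seg circumferential resolution.
#' @return A \code{surface_mesh} tagged \code{support}, with a
#'   \code{contacts} attribute (tibble: anchor position, contact height,
#'   \code{hit} flag).
#' @export
cone_supports <- function(spec, path, capillary_outer_diameter,
                          base_z = 0, fallback_height = 50, n_seg = 48) {
  stopifnot(inherits(spec, "cone_support_spec"))
  r_env <- capillary_outer_diameter / 2 + spec$clearance
  tap <- spec$taper_angle * pi / 180
  parts <- list()
  contacts <- list()
  for (i in seq_len(nrow(spec$positions))) {
    x <- spec$positions[i, 1]
    y <- spec$positions[i, 2]
    z_top <- envelope_underside_z(path, r_env, x, y)
    hit <- !is.na(z_top)
    if (!hit) z_top <- base_z + fallback_height
    h <- z_top - base_z
    if (h <= 0) {
      stop("anchor (", x, ", ", y, "): capillary underside at or below ",
           "the base plane")
    }
    # planar facets of the triangulated frustum sit slightly steeper than
    # the analytic cone wall; boost the build angle until the realised
    # minimum facet taper meets the specified angle
    tap_build <- tap
    for (attempt in 1:5) {
      r_base <- spec$tip_radius + h * tan(tap_build)
      cone <- frustum_mesh(c(x, y), base_z, z_top, r_base,
                           spec$tip_radius, n_seg = n_seg, n_rings = 8)
      if (spec$subtract_capillary && hit) {
        cone <- project_out_of_envelope(cone, path, r_env)
      }
      short <- spec$taper_angle - min_facet_taper(cone)
      if (short <= 0) break
      tap_build <- tap_build + (short + 0.01) * pi / 180
    }
    parts[[length(parts) + 1]] <- cone
    contacts[[length(contacts) + 1]] <-
      tibble::tibble(x = x, y = y, contact_z = z_top, hit = hit)
  }
  m <- mesh_merge(parts)
  attr(m, "contacts") <- do.call(rbind, contacts)
  m
}

# push mesh vertices that fall inside the capillary envelope straight down
# onto the envelope underside (watertightness-preserving deformation)
project_out_of_envelope <- function(mesh, path, r_env) {
  V <- mesh$vertices
  xyz <- path$dense$xyz
  for (k in seq_len(nrow(V))) {
    rho2 <- (xyz[, 1] - V[k, 1])^2 + (xyz[, 2] - V[k, 2])^2
    d2 <- rho2 + (xyz[, 3] - V[k, 3])^2
    if (min(d2) >= r_env^2) next  # outside the envelope
    under <- rho2 < r_env^2
    znew <- min(xyz[under, 3] - sqrt(r_env^2 - rho2[under]))
    V[k, 3] <- min(V[k, 3], znew)
  }
  mesh$vertices <- V
  mesh
}

#' Minimum facet taper of a support mesh
#'
#' The taper of a facet is the angle between its plane and the vertical
#' axis (90 degrees for horizontal faces, 0 for vertical walls). The
#' printable-overhang requirement is that no lateral facet is steeper than
#' the specified minimum taper.
#'
#' @param mesh a \code{surface_mesh}.
#' @return Minimum facet taper in degrees over all non-degenerate faces.
#' @export
min_facet_taper <- function(mesh) {
  n <- face_normals(mesh)
  a <- face_areas(mesh)
  nz <- abs(n[a > 1e-9, 3])
  min(asin(pmin(1, nz)) * 180 / pi)
}
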