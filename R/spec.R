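#' Capillary design parameters
#'
#' The tunable parameters of the porous capillary membrane: lumen (inner)
#' diameter \code{l_d}, pore diameter \code{p_d}, edge-to-edge pore spacing
#' \code{p_s}, membrane wall thickness, the circumferential side-pore
#' elongation factor, and the number of subdivision-smoothing iterations.
#' The grid pitch along both surface directions is \code{p_d + p_s}.
#'
#' @param lumen_diameter inner (perfusable) diameter l_d (um).
#' @param pore_diameter target pore diameter p_d (um).
#' @param pore_spacing edge-to-edge pore spacing p_s (um).
#' @param membrane_thickness wall thickness (um).
#' @param side_pore_elongation circumferential elongation factor applied to
#'   side-facing pores to keep them from printing closed (default 1.5).
#' @param smoothing_iterations subdivision-smoothing iterations (default 1).
#' @return A validated \code{capillary_spec} object.
#' @export
capillary_spec <- function(lumen_diameter, pore_diameter, pore_spacing,
                           membrane_thickness, side_pore_elongation = 1.5,
                           smoothing_iterations = 1) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(lumen_diameter) && lumen_diameter > 0,
      "lumen_diameter must be > 0")
  chk(is.numeric(pore_diameter) && pore_diameter > 0,
      "pore_diameter must be > 0")
  chk(is.numeric(pore_spacing) && pore_spacing > 0,
      "pore_spacing must be > 0")
  chk(is.numeric(membrane_thickness) && membrane_thickness > 0,
      "membrane_thickness must be > 0")
  chk(side_pore_elongation >= 1, "side_pore_elongation must be >= 1")
  chk(smoothing_iterations >= 0 &&
        smoothing_iterations == round(smoothing_iterations),
      "smoothing_iterations must be a non-negative integer")
  if (length(problems) == 0) {
    chk(pi * lumen_diameter >= 3 * (pore_diameter + pore_spacing),
        paste0("circumference pi*l_d = ", round(pi * lumen_diameter, 3),
               " must admit at least 3 pore pitches (3*(p_d+p_s) = ",
               3 * (pore_diameter + pore_spacing), ")"))
  }
  if (length(problems) > 0) {
    stop("invalid capillary_spec:\n  ", paste(problems, collapse = "\n  "))
  }
  structure(list(lumen_diameter = lumen_diameter,
                 pore_diameter = pore_diameter,
                 pore_spacing = pore_spacing,
                 membrane_thickness = membrane_thickness,
                 side_pore_elongation = side_pore_elongation,
                 smoothing_iterations = smoothing_iterations),
            class = "capillary_spec")
}

#' @export
print.capillary_spec <- function(x, ...) {
  cat("<capillary_spec> l_d=", x$lumen_diameter, " p_d=", x$pore_diameter,
      " p_s=", x$pore_spacing, " wall=", x$membrane_thickness,
      " elong=", x$side_pore_elongation, "\n", sep = "")
  invisible(x)
}

#' Parametric subdivision grid of the capillary surface
#'
#' The pore layout follows from four relations: the number of axial
#' subdivisions \code{u = floor(P_l / (p_d + p_s))} (clamped to >= 1), the
#' number of circumferential subdivisions
#' \code{v = floor(pi l_d / (p_d + p_s))} (clamped to >= 3), and the
#' resulting cell side lengths \code{s_l = P_l / u} (axial) and
#' \code{s_r = pi l_d / v} (circumferential). Rounding down guarantees the
#' realised pitch is never below the requested one.
#'
#' @param path_length total capillary path length P_l (um).
#' @param spec a \code{\link{capillary_spec}}.
#' @param round_mode how the real-valued subdivision counts are made
#'   integer: \code{"floor"} (default), \code{"round"} or \code{"ceiling"}.
#' @return A \code{subdivision_grid} object with fields \code{u}, \code{v},
#'   \code{s_l}, \code{s_r}.
#' @export
subdivision_grid <- function(path_length, spec,
                             round_mode = c("floor", "round", "ceiling")) {
  round_mode <- match.arg(round_mode)
  stopifnot(inherits(spec, "capillary_spec"))
  if (!is.numeric(path_length) || path_length <= 0) {
    stop("path_length must be > 0")
  }
  pitch <- spec$pore_diameter + spec$pore_spacing
  if (pitch >= path_length && pitch >= pi * spec$lumen_diameter) {
    stop("degenerate grid: pore pitch ", pitch,
         " exceeds both path length and circumference")
  }
  rf <- switch(round_mode, floor = floor, round = round, ceiling = ceiling)
  u <- max(1L, as.integer(rf(path_length / pitch)))
  v <- max(3L, as.integer(rf(pi * spec$lumen_diameter / pitch)))
  structure(list(u = u, v = v,
                 s_l = path_length / u,
                 s_r = pi * spec$lumen_diameter / v,
                 path_length = path_length),
            class = "subdivision_grid")
}

#' @export
print.subdivision_grid <- function(x, ...) {
  cat("<subdivision_grid> u=", x$u, " v=", x$v, " s_l=",
      format(x$s_l, digits = 6), " s_r=", format(x$s_r, digits = 6),
      " (", x$u * x$v, " cells)\n", sep = "")
  invisible(x)
}
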