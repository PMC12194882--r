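#' Field-of-view stitching layout
#'
#' Two-photon lithography prints large scaffolds as tiles of the
#' objective's field of view; seams between tiles misalign unless the
#' structure is supported there. The layout models the seam lines as two
#' families of parallel lines rotated by \code{stitch_angle} from the x/y
#' axes with period \code{fov_width - overlap}.
#'
#' @param fov_width tile width (um). The width is objective-dependent and
#'   not universal; the default 400 um suits a 25x objective and is an
#'   assumption to be overridden per system.
#' @param overlap stitching overlap between adjacent tiles (um).
#' @param stitch_angle rotation of the tile grid (degrees).
#' @param origin length-2 tile-grid origin in the build plane (um).
#' @return A \code{fov_layout} object.
#' @export
fov_layout <- function(fov_width = 400, overlap = 0, stitch_angle = 0,
                       origin = c(0, 0)) {
  if (!(fov_width > overlap) || overlap < 0) {
    stop("need fov_width > overlap >= 0")
  }
  structure(list(fov_width = fov_width, overlap = overlap,
                 stitch_angle = stitch_angle,
                 origin = as.double(origin)),
            class = "fov_layout")
}

#' Predict FOV seam crossings along a path
#'
#' Projects the path to the build plane and intersects it with both seam
#' line families, returning all crossings sorted by arc length. Supports
#' placed at these positions anchor the capillary where tile misalignment
#' would otherwise deform it.
#'
#' @param layout a \code{\link{fov_layout}}.
#' @param path a \code{centerline_path}.
#' @return A tibble with columns \code{s} (arc length, um), \code{family}
#'   (1 or 2), \code{seam_index}, \code{x}, \code{y}; zero rows when the
#'   path fits inside one tile.
#' @export
predict_fov_seams <- function(layout, path) {
  period <- layout$fov_width - layout$overlap
  ang <- layout$stitch_angle * pi / 180
  # unit normals of the two line families
  normals <- rbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
  xyz <- path$dense$xyz
  sarc <- path$dense$s
  out <- list()
  for (fam in 1:2) {
    nvec <- normals[fam, ]
    d <- (xyz[, 1] - layout$origin[1]) * nvec[1] +
      (xyz[, 2] - layout$origin[2]) * nvec[2]
    k <- d / period
    kf <- floor(k)
    cross_idx <- which(kf[-1] != kf[-length(kf)])
    for (i in cross_idx) {
      # one or more integer levels crossed within this dense segment
      lo <- min(k[i], k[i + 1]); hi <- max(k[i], k[i + 1])
      for (lev in seq(ceiling(lo), floor(hi))) {
        if (abs(k[i + 1] - k[i]) < 1e-15) next
        t <- (lev - k[i]) / (k[i + 1] - k[i])
        if (t < 0 || t > 1) next
        out[[length(out) + 1]] <- c(
          s = sarc[i] + t * (sarc[i + 1] - sarc[i]),
          family = fam, seam_index = lev,
          x = xyz[i, 1] + t * (xyz[i + 1, 1] - xyz[i, 1]),
          y = xyz[i, 2] + t * (xyz[i + 1, 2] - xyz[i, 2]))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(s = numeric(0), family = integer(0),
                          seam_index = integer(0), x = numeric(0),
                          y = numeric(0)))
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, "s"]), , drop = FALSE]
  tibble::tibble(s = m[, "s"], family = as.integer(m[, "family"]),
                 seam_index = as.integer(m[, "seam_index"]),
                 x = m[, "x"], y = m[, "y"])
}
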