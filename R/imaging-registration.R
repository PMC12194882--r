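# Design-vs-print registration: binary target (design render) and
# experiment (print) masks are merged through colour channels -- target in
# green, experiment in red -- so yellow marks correct overlap, green
# missing material, red excess/deformed material and black correct void.

#' Pair of aligned design/experiment masks
#'
#' Alignment (cropping on matching reference features) is the caller's
#' responsibility; \code{\link{refine_alignment}} offers an optional
#' integer-shift refinement.
#'
#' @param target,experiment logical matrices of identical dimensions.
#' @param pixel_size physical pixel size (um/px).
#' @return A \code{mask_pair}.
#' @export
mask_pair <- function(target, experiment, pixel_size = 1) {
  target <- as.matrix(target)
  experiment <- as.matrix(experiment)
  if (!all(dim(target) == dim(experiment))) {
    stop("target and experiment masks must have identical dimensions")
  }
  chk <- function(m, nm) {
    if (is.logical(m)) return(m)
    if (all(m %in% c(0, 1))) return(m > 0.5)
    stop(nm, " mask is not binary")
  }
  structure(list(target = chk(target, "target"),
                 experiment = chk(experiment, "experiment"),
                 pixel_size = pixel_size),
            class = "mask_pair")
}

#' Registration map and overlap metrics
#'
#' @param pair a \code{\link{mask_pair}}.
#' @return A list with \code{composite} (EBImage RGB Image: target in the
#'   green channel, experiment in the red channel) and \code{result}, a
#'   \code{registration_result} with the four colour fractions (summing to
#'   1 over the frame) and overlap percentages under three normalisations:
#'   \code{overlap_percent} = yellow / (yellow + green + red) (the
#'   headline metric; void pixels excluded), \code{overlap_of_target} and
#'   \code{overlap_of_frame}.
#' @export
registration_map <- function(pair) {
  stopifnot(inherits(pair, "mask_pair"))
  t_ <- pair$target
  e <- pair$experiment
  npx <- length(t_)
  yellow <- sum(t_ & e) / npx
  green <- sum(t_ & !e) / npx
  red <- sum(!t_ & e) / npx
  black <- sum(!t_ & !e) / npx
  union_frac <- yellow + green + red
  res <- structure(list(
    yellow_fraction = yellow, green_fraction = green, red_fraction = red,
    black_fraction = black,
    overlap_percent = if (union_frac > 0) 100 * yellow / union_frac
                      else NA_real_,
    overlap_of_target = if (yellow + green > 0)
      100 * yellow / (yellow + green) else NA_real_,
    overlap_of_frame = 100 * yellow,
    n_pixels = npx), class = "registration_result")
  comp <- EBImage::rgbImage(red = EBImage::Image(t(e * 1)),
                            green = EBImage::Image(t(t_ * 1)))
  list(composite = comp, result = res)
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> overlap ", round(x$overlap_percent, 2),
      "% of union (yellow ", round(100 * x$yellow_fraction, 2),
      "%, green ", round(100 * x$green_fraction, 2),
      "%, red ", round(100 * x$red_fraction, 2),
      "%, black ", round(100 * x$black_fraction, 2), "%)\n", sep = "")
  invisible(x)
}

#' Tidy a registration result
#'
#' @param x a \code{registration_result}.
#' @param ... unused.
#' @return One-row tibble of all metrics.
#' @export
tidy.registration_result <- function(x, ...) {
  tibble::tibble(yellow_fraction = x$yellow_fraction,
                 green_fraction = x$green_fraction,
                 red_fraction = x$red_fraction,
                 black_fraction = x$black_fraction,
                 overlap_percent = x$overlap_percent,
                 overlap_of_target = x$overlap_of_target,
                 overlap_of_frame = x$overlap_of_frame)
}

#' Integer-shift alignment refinement (optional)
#'
#' Exhaustive search over integer shifts of the experiment mask within
#' \code{max_shift}, maximising the yellow (overlap) pixel count. Off by
#' default in the registration workflow, which assumes pre-aligned input.
#'
#' @param pair a \code{\link{mask_pair}}.
#' @param max_shift search radius (px).
#' @return The shifted \code{mask_pair}, with attribute \code{shift}.
#' @export
refine_alignment <- function(pair, max_shift = 10) {
  t_ <- pair$target
  e <- pair$experiment
  best <- c(0, 0)
  best_score <- -1
  for (dy in -max_shift:max_shift) {
    for (dx in -max_shift:max_shift) {
      es <- shift_mask(e, dy, dx)
      sc <- sum(t_ & es)
      if (sc > best_score) {
        best_score <- sc
        best <- c(dy, dx)
      }
    }
  }
  out <- mask_pair(t_, shift_mask(e, best[1], best[2]), pair$pixel_size)
  attr(out, "shift") <- best
  out
}

shift_mask <- function(m, dy, dx) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)) - dy
  xs <- seq_len(ncol(m)) - dx
  okY <- ys >= 1 & ys <= nrow(m)
  okX <- xs >= 1 & xs <= ncol(m)
  out[okY, okX] <- m[ys[okY], xs[okX]]
  out
}

#' Render a top-down design mask from a mesh
#'
#' Orthographic top-down silhouette of a mesh at the given resolution, the
#' digital reference for print-fidelity registration. Faces can be
#' excluded by provenance tag (e.g. cone supports are digitally
#' subtracted before comparison with prints).
#'
#' @param mesh a \code{surface_mesh}.
#' @param pixel_size um per pixel (> 0).
#' @param exclude_provenance character vector of face tags to omit.
#' @param bbox optional 2 x 2 matrix (min, max) x (x, y) of the render
#'   window (um); default: mesh extent plus one pixel.
#' @return Logical matrix (rows = y, increasing upward) with attributes
#'   \code{pixel_size} and \code{origin}.
#' @export
render_design_mask <- function(mesh, pixel_size, exclude_provenance = NULL,
                               bbox = NULL) {
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be > 0")
  }
  if (nrow(mesh$faces) == 0) stop("cannot render an empty mesh")
  keep <- !(mesh$provenance %in% (exclude_provenance %||% character(0)))
  if (!any(keep)) stop("all faces excluded by provenance")
  if (is.null(bbox)) {
    vid <- unique(as.vector(mesh$faces[keep, , drop = FALSE]))
    xy <- mesh$vertices[vid, 1:2, drop = FALSE]
    bbox <- rbind(apply(xy, 2, min) - pixel_size,
                  apply(xy, 2, max) + pixel_size)
  }
  nx <- max(1L, as.integer(ceiling((bbox[2, 1] - bbox[1, 1]) / pixel_size)))
  ny <- max(1L, as.integer(ceiling((bbox[2, 2] - bbox[1, 2]) / pixel_size)))
  img <- cpp_rasterize_topdown(mesh$vertices, mesh$faces, keep,
                               bbox[1, 1], bbox[1, 2], pixel_size, nx, ny)
  out <- img > 0
  attr(out, "pixel_size") <- pixel_size
  attr(out, "origin") <- bbox[1, ]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
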