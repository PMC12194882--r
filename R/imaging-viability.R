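# Live/dead viability counting from two-channel fluorescence images:
# calcein-AM (green, live) and ethidium homodimer-1 (red, dead nuclei).

#' Count live and dead cells
#'
#' Each channel is binarized (Otsu) and segmented into connected
#' components of at least \code{min_area_px} pixels. Red components mark
#' dead cells; a green component overlapping any red component is counted
#' as dead only (the dead stain marks nuclei of dying cells that may
#' still retain calcein signal).
#'
#' @param green,red numeric matrices in [0, 1], identical dimensions.
#' @param min_area_px minimum component area (px); the default 20 suits
#'   4x-magnification images.
#' @param pixel_size optional um per pixel, enabling the live-cell
#'   density (cells/mm^2).
#' @param split_touching split merged components by area: a component
#'   larger than 1.5x the median area counts as
#'   \code{round(area / median)} cells.
#' @return A \code{viability_result}: \code{live_count},
#'   \code{dead_count}, \code{viability_percent}, \code{density_mm2}
#'   (NA without \code{pixel_size}), plus detection centroids.
#' @export
count_live_dead <- function(green, red, min_area_px = 20,
                            pixel_size = NULL, split_touching = TRUE) {
  green <- as_gray_matrix(green)
  red <- as_gray_matrix(red)
  if (!all(dim(green) == dim(red))) {
    stop("green and red channels must have identical dimensions")
  }
  seg <- function(ch) {
    if (diff(range(ch)) < 1e-12) {
      return(label_components(matrix(FALSE, nrow(ch), ncol(ch))))
    }
    label_components(binarize(ch, "otsu"), min_area_px)
  }
  g <- seg(green)
  r <- seg(red)
  red_mask <- g$labels * 0L
  red_mask[r$labels > 0] <- 1L
  # green components overlapping red are reclassified dead-only
  overlapped <- unique(g$labels[g$labels > 0 & red_mask > 0])
  live_tab <- g$table[!(g$table$label %in% overlapped), , drop = FALSE]
  # area heuristic for touching cells: big blobs count as several
  multiplicity <- function(areas) {
    if (!split_touching || length(areas) == 0) return(rep(1L, length(areas)))
    med <- stats::median(areas)
    ifelse(areas > 1.5 * med, pmax(2L, round(areas / med)), 1L)
  }
  mult_live <- multiplicity(live_tab$area)
  mult_dead <- multiplicity(r$table$area)
  live <- sum(mult_live)
  dead <- sum(mult_dead)
  if (live + dead == 0) {
    stop("no cells detected in either channel: viability undefined")
  }
  dens <- NA_real_
  if (!is.null(pixel_size)) {
    area_mm2 <- length(green) * (pixel_size / 1000)^2
    dens <- live / area_mm2
  }
  structure(list(
    live_count = live, dead_count = dead,
    viability_percent = 100 * live / (live + dead),
    density_mm2 = dens,
    detections = tibble::tibble(
      x = c(rep(live_tab$x, mult_live), rep(r$table$x, mult_dead)),
      y = c(rep(live_tab$y, mult_live), rep(r$table$y, mult_dead)),
      class = c(rep("live", live), rep("dead", dead))),
    edits = tibble::tibble(x = numeric(0), y = numeric(0),
                           action = character(0)),
    pixel_size = pixel_size, n_pixels = length(green)),
    class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat("<viability_result> ", x$live_count, " live / ", x$dead_count,
      " dead; viability ", round(x$viability_percent, 2), "%\n", sep = "")
  invisible(x)
}

#' Apply manual corrections to a viability count
#'
#' Deterministically replays a list of edits -- adding missed cells or
#' removing false detections -- mirroring the manual verification pass of
#' GUI-based counting. All edits are retained in an audit log
#' (\code{$edits}).
#'
#' @param result a \code{viability_result}.
#' @param edits data frame with columns \code{x}, \code{y},
#'   \code{action} (\code{add_live}, \code{add_dead} or \code{remove}).
#' @param tol match radius (px) for \code{remove}.
#' @return Updated \code{viability_result}.
#' @export
apply_corrections <- function(result, edits, tol = 5) {
  stopifnot(inherits(result, "viability_result"))
  if (is.null(edits) || nrow(edits) == 0) return(result)
  det <- result$detections
  for (i in seq_len(nrow(edits))) {
    a <- edits$action[i]
    x <- edits$x[i]; y <- edits$y[i]
    if (a %in% c("add_live", "add_dead")) {
      det <- rbind(det, tibble::tibble(
        x = x, y = y, class = if (a == "add_live") "live" else "dead"))
    } else if (a == "remove") {
      if (nrow(det) == 0) stop("remove at (", x, ", ", y,
                               "): no detections present")
      d <- sqrt((det$x - x)^2 + (det$y - y)^2)
      if (min(d) > tol) {
        stop("remove at (", x, ", ", y, "): no detection within ", tol,
             " px")
      }
      det <- det[-which.min(d), , drop = FALSE]
    } else {
      stop("unknown edit action: ", a)
    }
  }
  live <- sum(det$class == "live")
  dead <- sum(det$class == "dead")
  if (live + dead == 0) stop("all detections removed: viability undefined")
  result$detections <- det
  result$live_count <- live
  result$dead_count <- dead
  result$viability_percent <- 100 * live / (live + dead)
  if (!is.null(result$pixel_size)) {
    result$density_mm2 <- live /
      (result$n_pixels * (result$pixel_size / 1000)^2)
  }
  result$edits <- rbind(result$edits, edits[, c("x", "y", "action")])
  result
}

#' Tidy a viability result
#' @param x a \code{viability_result}.
#' @param ... unused.
#' @return One-row tibble.
#' @export
glance.viability_result <- function(x, ...) {
  tibble::tibble(live_count = x$live_count, dead_count = x$dead_count,
                 viability_percent = x$viability_percent,
                 density_mm2 = x$density_mm2)
}
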