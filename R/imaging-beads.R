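# Bead-tracking velocimetry: extract bead trajectories across time-lapse
# frames and convert per-frame displacements into flow velocities.

#' Track beads across a time-lapse stack
#'
#' Auto mode detects beads per frame (threshold at a fraction of the frame
#' maximum, connected components, intensity-weighted centroids) and links
#' detections between consecutive frames by nearest neighbour within a
#' maximum-displacement gate, assigning closest pairs first. Manual mode
#' links caller-supplied per-frame click positions by row order, the
#' digital equivalent of GUI-clicked trajectories.
#'
#' @param frames 3D array (y, x, frame) or list of matrices, values in
#'   [0, 1]; at least 2 frames.
#' @param mode \code{"auto"} or \code{"manual"}.
#' @param points manual mode: list (one per frame) of n x 2 matrices of
#'   (x, y) positions; row i is bead i.
#' @param max_displacement linking gate (px/frame).
#' @param threshold_frac detection threshold as a fraction of the frame
#'   maximum intensity.
#' @param min_area_px minimum detection area (px).
#' @return A \code{bead_tracks} tibble: \code{track}, \code{frame},
#'   \code{x}, \code{y} (px); empty when nothing is detected.
#' @export
track_beads <- function(frames, mode = c("auto", "manual"), points = NULL,
                        max_displacement = 15, threshold_frac = 0.3,
                        min_area_px = 2) {
  mode <- match.arg(mode)
  if (is.list(frames)) {
    frames <- simplify2array(frames)
  }
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2) {
    stop("need an image stack with at least 2 frames")
  }
  nfr <- dim(frames)[3]
  if (mode == "manual") {
    if (is.null(points) || length(points) != nfr) {
      stop("manual mode needs one point set per frame")
    }
    rows <- list()
    for (f in seq_len(nfr)) {
      p <- matrix(as.double(points[[f]]), ncol = 2)
      if (nrow(p) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        track = seq_len(nrow(p)), frame = f, x = p[, 1], y = p[, 2])
    }
    out <- if (length(rows) == 0) {
      tibble::tibble(track = integer(0), frame = integer(0),
                     x = numeric(0), y = numeric(0))
    } else do.call(rbind, rows)
    class(out) <- c("bead_tracks", class(out))
    return(out)
  }
  detections <- lapply(seq_len(nfr), function(f) {
    img <- frames[, , f]
    mx <- max(img)
    if (mx <= 0) return(matrix(numeric(0), 0, 2))
    mask <- img > threshold_frac * mx
    lc <- label_components(mask, min_area_px)
    if (nrow(lc$table) == 0) return(matrix(numeric(0), 0, 2))
    # refine to intensity-weighted centroids
    cen <- t(vapply(lc$table$label, function(lb) {
      idx <- which(lc$labels == lb, arr.ind = TRUE)
      w <- img[idx]
      c(sum(idx[, 2] * w) / sum(w), sum(idx[, 1] * w) / sum(w))  # x, y
    }, numeric(2)))
    cen
  })
  # initialise tracks from frame-1 detections, then greedy closest-pair
  # linking frame by frame
  ntracks <- nrow(detections[[1]])
  if (ntracks == 0) {
    out <- tibble::tibble(track = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0))
    class(out) <- c("bead_tracks", class(out))
    return(out)
  }
  pos <- vector("list", ntracks)
  for (i in seq_len(ntracks)) {
    pos[[i]] <- tibble::tibble(track = i, frame = 1L,
                               x = detections[[1]][i, 1],
                               y = detections[[1]][i, 2])
  }
  last <- detections[[1]]
  active <- seq_len(ntracks)
  for (f in 2:nfr) {
    det <- detections[[f]]
    if (nrow(det) == 0 || length(active) == 0) {
      active <- integer(0)
      next
    }
    d <- outer(seq_along(active), seq_len(nrow(det)),
               Vectorize(function(i, j) {
                 sqrt((last[i, 1] - det[j, 1])^2 +
                        (last[i, 2] - det[j, 2])^2)
               }))
    pairs <- which(d <= max_displacement, arr.ind = TRUE)
    if (nrow(pairs) > 0) pairs <- pairs[order(d[pairs]), , drop = FALSE]
    used_t <- logical(length(active))
    used_d <- logical(nrow(det))
    newlast <- last
    keep <- logical(length(active))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (used_t[i] || used_d[j]) next
      used_t[i] <- TRUE
      used_d[j] <- TRUE
      tid <- active[i]
      pos[[tid]] <- rbind(pos[[tid]],
                          tibble::tibble(track = tid, frame = f,
                                         x = det[j, 1], y = det[j, 2]))
      newlast[i, ] <- det[j, ]
      keep[i] <- TRUE
    }
    last <- newlast[keep, , drop = FALSE]
    active <- active[keep]
  }
  out <- do.call(rbind, pos)
  class(out) <- c("bead_tracks", class(out))
  out
}

#' Flow velocity from bead tracks
#'
#' Per-track speed is the mean per-frame displacement magnitude converted
#' to physical units: \code{|displacement| * pixel_size / frame_interval}.
#' The estimate aggregates tracks as mean +- sample SD in mm/s.
#'
#' @param tracks a \code{bead_tracks} tibble (>= 2 points per used track).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames (> 0).
#' @return A \code{flow_estimate}: \code{mean_velocity}, \code{sd_velocity}
#'   (mm/s), \code{n_tracks}, and per-track speeds in
#'   \code{track_speeds}.
#' @export
estimate_velocity <- function(tracks, pixel_size, frame_interval) {
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  if (is.null(tracks) || nrow(tracks) == 0) {
    stop("no tracks to estimate velocity from")
  }
  ids <- unique(tracks$track)
  speeds <- vapply(ids, function(tid) {
    tr <- tracks[tracks$track == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) return(NA_real_)
    dx <- diff(tr$x)
    dy <- diff(tr$y)
    df <- diff(tr$frame)
    px_per_frame <- mean(sqrt(dx^2 + dy^2) / df)
    px_per_frame * pixel_size / frame_interval / 1000  # mm/s
  }, numeric(1))
  speeds <- speeds[!is.na(speeds)]
  if (length(speeds) == 0) stop("no track has >= 2 points")
  structure(list(mean_velocity = mean(speeds),
                 sd_velocity = if (length(speeds) > 1) sd(speeds) else 0,
                 n_tracks = length(speeds),
                 track_speeds = speeds),
            class = "flow_estimate")
}

#' @export
print.flow_estimate <- function(x, ...) {
  cat("<flow_estimate> ", round(x$mean_velocity, 3), " +- ",
      round(x$sd_velocity, 3), " mm/s over ", x$n_tracks, " tracks\n",
      sep = "")
  invisible(x)
}

#' Tidy / glance for flow estimates
#' @param x a \code{flow_estimate}.
#' @param ... unused.
#' @return \code{tidy}: per-track tibble; \code{glance}: one-row summary.
#' @export
tidy.flow_estimate <- function(x, ...) {
  tibble::tibble(track = seq_along(x$track_speeds),
                 speed_mm_s = x$track_speeds)
}

#' @rdname tidy.flow_estimate
#' @export
glance.flow_estimate <- function(x, ...) {
  tibble::tibble(mean_velocity = x$mean_velocity,
                 sd_velocity = x$sd_velocity, n_tracks = x$n_tracks)
}
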