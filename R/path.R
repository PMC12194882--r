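#' Capillary centerline path
#'
#' An ordered sequence of 3D points (um) interpolated by a spline that
#' serves as the central axis of a swept capillary. A cubic interpolating
#' spline (degree configurable; degree 1 gives the raw polyline)
#' approximates the NURBS axis used in CAD workflows, parameterised by
#' chord length and resampled densely for arc-length queries.
#'
#' @param points n x 3 numeric matrix of ordered control points (um).
#' @param degree spline degree: 1 (polyline) or 3 (cubic, default).
#' @param closed logical; closed loop paths join last to first point.
#' @param corner_fillet_radius if > 0, polyline corners are pre-filleted by
#'   cutting each corner at this distance (um) before spline fitting, which
#'   keeps sharp space-filling-curve corners from tightening below the
#'   swept-tube radius.
#' @param samples_per_segment dense sampling density used for arc-length
#'   parameterization.
#' @return A \code{centerline_path} object with fields \code{points},
#'   \code{degree}, \code{closed}, \code{path_length} (total arc length
#'   P_l, um) and internal dense samples.
#' @export
centerline_path <- function(points, degree = 3, closed = FALSE,
                            corner_fillet_radius = 0,
                            samples_per_segment = 20) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must have 3 columns (x, y, z)")
  if (nrow(points) < 2) stop("invalid path: need at least 2 points")
  if (any(!is.finite(points))) stop("invalid path: non-finite coordinates")
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                     points[-nrow(points), , drop = FALSE])^2))
  if (any(d < 1e-12)) {
    stop("invalid path: consecutive duplicate points at row ",
         which(d < 1e-12)[1] + 1)
  }
  if (!degree %in% c(1, 3)) stop("degree must be 1 or 3")
  if (corner_fillet_radius > 0 && nrow(points) > 2) {
    points <- fillet_polyline(points, corner_fillet_radius, closed)
  }
  dense <- densify_path(points, degree, closed, samples_per_segment)
  structure(
    list(points = points, degree = degree, closed = closed,
         path_length = dense$length, dense = dense),
    class = "centerline_path"
  )
}

# cut corners of a polyline at distance f along each adjacent segment
fillet_polyline <- function(points, f, closed) {
  n <- nrow(points)
  keep_first <- if (closed) NULL else points[1, , drop = FALSE]
  keep_last <- if (closed) NULL else points[n, , drop = FALSE]
  inner <- if (closed) seq_len(n) else 2:(n - 1)
  out <- list(keep_first)
  for (i in inner) {
    prev <- points[if (i == 1) n else i - 1, ]
    cur <- points[i, ]
    nxt <- points[if (i == n) 1 else i + 1, ]
    l1 <- sqrt(sum((cur - prev)^2))
    l2 <- sqrt(sum((nxt - cur)^2))
    # straight-through points are kept as-is
    u1 <- (cur - prev) / l1
    u2 <- (nxt - cur) / l2
    if (sum(u1 * u2) > 1 - 1e-9) {
      out[[length(out) + 1]] <- matrix(cur, 1)
      next
    }
    ff <- min(f, 0.45 * l1, 0.45 * l2)
    out[[length(out) + 1]] <- rbind(cur - u1 * ff, cur + u2 * ff)
  }
  out[[length(out) + 1]] <- keep_last
  do.call(rbind, out)
}

# dense sampling + cumulative arc length; spline interpolates per coordinate
# against the cumulative chord-length parameter
densify_path <- function(points, degree, closed, k) {
  if (closed) points <- rbind(points, points[1, , drop = FALSE])
  n <- nrow(points)
  chord <- c(0, cumsum(sqrt(rowSums((points[-1, , drop = FALSE] -
                                     points[-n, , drop = FALSE])^2))))
  tt <- unique(sort(c(chord, unlist(lapply(seq_len(n - 1), function(i) {
    seq(chord[i], chord[i + 1], length.out = k + 1)
  })))))
  if (degree == 1) {
    xyz <- cbind(approx(chord, points[, 1], tt)$y,
                 approx(chord, points[, 2], tt)$y,
                 approx(chord, points[, 3], tt)$y)
  } else {
    method <- if (closed) "periodic" else "natural"
    if (closed) {
      fx <- splinefun(chord, points[, 1], method = "periodic")
      fy <- splinefun(chord, points[, 2], method = "periodic")
      fz <- splinefun(chord, points[, 3], method = "periodic")
    } else {
      fx <- splinefun(chord, points[, 1], method = "natural")
      fy <- splinefun(chord, points[, 2], method = "natural")
      fz <- splinefun(chord, points[, 3], method = "natural")
    }
    xyz <- cbind(fx(tt), fy(tt), fz(tt))
  }
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  list(xyz = xyz, s = s, length = s[length(s)])
}

#' @export
print.centerline_path <- function(x, ...) {
  cat("<centerline_path> ", nrow(x$points), " points, degree ", x$degree,
      if (x$closed) ", closed" else "", ", P_l = ",
      format(x$path_length, digits = 6), " um\n", sep = "")
  invisible(x)
}

#' Evaluate a path at given arc lengths
#'
#' @param path a \code{centerline_path}.
#' @param s numeric vector of arc lengths in \code{[0, path_length]} (um).
#' @return n x 3 matrix of positions.
#' @export
path_point <- function(path, s) {
  s <- pmin(pmax(s, 0), path$path_length)
  cbind(approx(path$dense$s, path$dense$xyz[, 1], s)$y,
        approx(path$dense$s, path$dense$xyz[, 2], s)$y,
        approx(path$dense$s, path$dense$xyz[, 3], s)$y)
}

# unit tangents at arc lengths, by central differencing on the dense samples
path_tangent <- function(path, s) {
  h <- max(path$path_length * 1e-5, 1e-6)
  p1 <- path_point(path, pmax(s - h, 0))
  p2 <- path_point(path, pmin(s + h, path$path_length))
  t <- p2 - p1
  len <- sqrt(rowSums(t^2))
  t / len
}

#' Minimum distance between non-adjacent path segments (self-avoidance)
#'
#' Reports the minimum distance between all pairs of non-adjacent segments
#' of the path polyline, the self-avoidance diagnostic for space-filling
#' routings.
#'
#' @param path a \code{centerline_path}.
#' @param use \code{"vertices"} (control polyline, default) or
#'   \code{"spline"} (densely sampled spline).
#' @return Numeric scalar (um); \code{Inf} for paths with < 3 segments.
#' @export
min_self_distance <- function(path, use = c("vertices", "spline")) {
  use <- match.arg(use)
  pts <- if (use == "vertices") path$points else {
    path$dense$xyz[seq(1, nrow(path$dense$xyz), length.out =
                       min(nrow(path$dense$xyz), 400)), , drop = FALSE]
  }
  n <- nrow(pts) - 1
  if (n < 3) return(Inf)
  best <- Inf
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (path$closed && i == 1 && j == n) next
      d <- segment_segment_distance(pts[i, ], pts[i + 1, ],
                                    pts[j, ], pts[j + 1, ])
      if (d < best) best <- d
    }
  }
  best
}

# closest distance between two 3D segments (clamped quadratic minimisation)
segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-18 && e <= 1e-18) return(sqrt(sum(r * r)))
  if (a <= 1e-18) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= 1e-18) {
      t <- 0; s <- min(max(-c_ / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-18) min(max((b * f - c_ * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(max(-c_ / a, 0), 1)
      } else if (t > 1) {
        t <- 1; s <- min(max((b - c_) / a, 0), 1)
      }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

#' Import a centerline path from CSV
#'
#' One point per row as \code{x,y,z}; an optional header row is
#' auto-detected and lines starting with \code{#} are ignored.
#'
#' @param file path to the CSV file.
#' @param units_scale multiplier applied to all coordinates to convert to
#'   micrometres (default 1: file already in um).
#' @param ... further arguments passed to \code{\link{centerline_path}}.
#' @return A \code{centerline_path}.
#' @export
load_path_csv <- function(file, units_scale = 1, ...) {
  lines <- readLines(file, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("invalid path: empty CSV")
  parse_row <- function(ln) suppressWarnings(as.numeric(strsplit(
    trimws(ln), "\\s*,\\s*")[[1]]))
  first <- parse_row(lines[1])
  start <- 1L
  if (any(is.na(first))) {  # header row
    start <- 2L
    if (length(lines) < 2) stop("invalid path: fewer than 2 points")
  }
  rows <- lapply(lines[start:length(lines)], parse_row)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != 3 || any(is.na(rows[[i]]))) {
      stop("malformed CSV row at line ", lineno[start - 1L + i], ": '",
           lines[start - 1L + i], "'")
    }
  }
  pts <- do.call(rbind, rows) * units_scale
  if (nrow(pts) < 2) stop("invalid path: fewer than 2 points")
  centerline_path(pts, ...)
}
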