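# Porous capillary membrane generation: sweep the lumen cylinder along the
# centerline, subdivide it into the parametric pore grid, cut picture-frame
# pores, elongate side pores, thicken to a solid wall.

# surface point and outward radial direction at (s, theta) given frames
sweep_point <- function(frames, idx, theta, radius) {
  radial <- cos(theta) * frames$normal[idx, ] +
    sin(theta) * frames$binormal[idx, ]
  list(pos = frames$position[idx, ] + radius * radial, radial = radial)
}

# minimum radius of curvature of the densely sampled centerline
path_min_bend_radius <- function(path) {
  xyz <- path$dense$xyz
  n <- nrow(xyz)
  if (n < 3) return(Inf)
  i <- 2:(n - 1)
  a <- xyz[i - 1, , drop = FALSE]
  b <- xyz[i, , drop = FALSE]
  c_ <- xyz[i + 1, , drop = FALSE]
  ab <- b - a; bc <- c_ - b; ac <- c_ - a
  la <- sqrt(rowSums(ab^2)); lb <- sqrt(rowSums(bc^2))
  lc <- sqrt(rowSums(ac^2))
  cr <- cbind(ab[, 2] * bc[, 3] - ab[, 3] * bc[, 2],
              ab[, 3] * bc[, 1] - ab[, 1] * bc[, 3],
              ab[, 1] * bc[, 2] - ab[, 2] * bc[, 1])
  denom <- 2 * sqrt(rowSums(cr^2))
  r <- ifelse(denom < 1e-12, Inf, la * lb * lc / denom)
  min(r)
}

#' Sweep the lumen cylinder along a path
#'
#' Builds the u x v quad grid (triangulated) on the cylinder of diameter
#' \code{l_d} swept along the path with rotation-minimizing frames, the
#' blank membrane surface that \code{\link{cut_pores}} subdivides.
#' Circumferential index 0 is placed at the frame normal direction.
#'
#' @param path a \code{centerline_path}; its length must match the grid's.
#' @param grid a \code{\link{subdivision_grid}}.
#' @param spec a \code{\link{capillary_spec}}.
#' @return A \code{surface_mesh} with sweep metadata attached; open at both
#'   ends (or seamed to itself for closed paths).
#' @export
sweep_shell <- function(path, grid, spec) {
  stopifnot(inherits(path, "centerline_path"),
            inherits(grid, "subdivision_grid"),
            inherits(spec, "capillary_spec"))
  if (abs(grid$path_length - path$path_length) >
      1e-6 * max(1, path$path_length)) {
    stop("grid path_length does not match path")
  }
  u <- grid$u; v <- grid$v
  R <- spec$lumen_diameter / 2
  rmin <- path_min_bend_radius(path)
  if (rmin < R) {
    warning("tube self-intersection risk: minimum bend radius ",
            format(rmin, digits = 4), " um < lumen radius ", R, " um")
  }
  s <- grid$s_l * (0:u)
  frames <- rmf_frames(path, s)
  theta <- 2 * pi * (seq_len(v) - 1) / v
  nring <- if (path$closed) u else u + 1
  V <- matrix(0, nring * v, 3)
  radial <- matrix(0, nring * v, 3)
  param <- matrix(0, nring * v, 2)
  for (i in seq_len(nring)) {
    rad <- outer(cos(theta), frames$normal[i, ]) +
      outer(sin(theta), frames$binormal[i, ])
    rows <- (i - 1) * v + seq_len(v)
    V[rows, ] <- sweep(rad * R, 2, frames$position[i, ], "+")
    radial[rows, ] <- rad
    param[rows, ] <- cbind(s[i], theta)
  }
  ringmap <- function(i) if (path$closed) ((i - 1) %% nring) + 1 else i
  Fb <- do.call(rbind, lapply(seq_len(u), function(i) {
    i0 <- (ringmap(i) - 1L) * v
    i1 <- (ringmap(i + 1) - 1L) * v
    j <- seq_len(v)
    jn <- c(seq_len(v)[-1], 1L)
    # axial = "up", circumferential CCW: outward normals
    rbind(cbind(i0 + j, i0 + jn, i1 + jn), cbind(i0 + j, i1 + jn, i1 + j))
  }))
  m <- surface_mesh(V, Fb, "membrane")
  attr(m, "sweep") <- list(path = path, grid = grid, spec = spec)
  attr(m, "radial") <- radial
  attr(m, "param") <- param
  m
}

# core builder: pored membrane with per-cell circumferential elongation
# factors (length u*v, cell (i,j) at index (j-1)*u + i)
build_pored_membrane <- function(path, grid, spec, factors) {
  u <- grid$u; v <- grid$v
  R <- spec$lumen_diameter / 2
  s_l <- grid$s_l; s_r <- grid$s_r
  p_s <- spec$pore_spacing
  h_l <- p_s / 2
  if (s_l - p_s <= 1e-9) {
    stop("empty pore: frame inset p_s/2 = ", h_l,
         " leaves no axial opening in cells of length s_l = ",
         format(s_l, digits = 6))
  }
  closed <- path$closed
  ns <- if (closed) 3L * u else 3L * u + 1L
  s_vals <- numeric(ns)
  for (i in seq_len(u)) {
    s_vals[3 * (i - 1) + 1] <- (i - 1) * s_l
    s_vals[3 * (i - 1) + 2] <- (i - 1) * s_l + h_l
    s_vals[3 * (i - 1) + 3] <- i * s_l - h_l
  }
  if (!closed) s_vals[ns] <- u * s_l
  frames <- rmf_frames(path, if (closed) s_vals else s_vals)
  srow <- function(i) if (closed) ((i - 1L) %% (3L * u)) + 1L else i

  vmap <- new.env(hash = TRUE, size = 20 * u * v)
  Vlist <- vector("list", 16 * u * v)
  radial_list <- vector("list", 16 * u * v)
  param_list <- vector("list", 16 * u * v)
  nV <- 0L
  get_vertex <- function(si, theta) {
    th <- theta %% (2 * pi)
    if (abs(th - 2 * pi) < 1e-12) th <- 0
    key <- paste(si, format(th, digits = 15))
    id <- vmap[[key]]
    if (!is.null(id)) return(id)
    sp <- sweep_point(frames, si, th, R)
    nV <<- nV + 1L
    Vlist[[nV]] <<- sp$pos
    radial_list[[nV]] <<- sp$radial
    param_list[[nV]] <<- c(s_vals[si], th)
    vmap[[key]] <- nV
    nV
  }

  theta_edge <- 2 * pi * (0:v) / v
  faces <- vector("list", u * v)
  pores <- vector("list", u * v)
  for (j in seq_len(v)) {
    th0 <- theta_edge[j]
    th1 <- theta_edge[j + 1]
    for (i in seq_len(u)) {
      fct <- factors[(j - 1) * u + i]
      open_w <- fct * (s_r - p_s)
      if (open_w <= 1e-9) {
        stop("empty pore at cell (", i, ",", j, "): circumferential inset ",
             "leaves no opening")
      }
      inset_arc <- (s_r - open_w) / 2
      if (inset_arc <= 1e-9) {
        stop("pore elongation merges adjacent pores at cell (", i, ",", j,
             "): circumferential inset ", format(inset_arc, digits = 4),
             " um <= 0")
      }
      h_th <- inset_arc / R
      h_th0 <- (p_s / 2) / R  # default inset on shared cell-boundary rows
      srows <- c(srow(3L * (i - 1L) + 1L), srow(3L * (i - 1L) + 2L),
                 srow(3L * (i - 1L) + 3L), srow(3L * i + 1L))
      # the outer rows (cell boundaries, shared with axial neighbours)
      # always use the default inset so adjacent cells with different
      # elongation factors still share identical edge partitions
      vid <- matrix(0L, 4, 4)
      for (a in 1:4) {
        hh <- if (a %in% c(1, 4)) h_th0 else h_th
        thetas <- c(th0, th0 + hh, th1 - hh, th1)
        for (b in 1:4) vid[a, b] <- get_vertex(srows[a], thetas[b])
      }
      cf <- vector("list", 8)
      k <- 0
      for (a in 1:3) {
        for (b in 1:3) {
          if (a == 2 && b == 2) next
          k <- k + 1
          cf[[k]] <- rbind(c(vid[a, b], vid[a, b + 1], vid[a + 1, b + 1]),
                           c(vid[a, b], vid[a + 1, b + 1], vid[a + 1, b]))
        }
      }
      faces[[(j - 1) * u + i]] <- do.call(rbind, cf)
      sc <- ((i - 1) + 0.5) * s_l
      thc <- (th0 + th1) / 2
      ctr <- sweep_point(frames, srow(3L * (i - 1L) + 2L), thc, R)
      pores[[(j - 1) * u + i]] <- list(
        i = i, j = j, s = sc, theta = thc %% (2 * pi), factor = fct,
        corners = c(vid[2, 2], vid[2, 3], vid[3, 2], vid[3, 3]),
        normal = ctr$radial)
    }
  }
  V <- do.call(rbind, Vlist[seq_len(nV)])
  m <- surface_mesh(V, do.call(rbind, faces), "membrane")
  attr(m, "sweep") <- list(path = path, grid = grid, spec = spec)
  attr(m, "radial") <- do.call(rbind, radial_list[seq_len(nV)])
  attr(m, "param") <- do.call(rbind, param_list[seq_len(nV)])
  attr(m, "pores") <- pores
  attr(m, "factors") <- factors
  m
}

#' Cut picture-frame pores into a swept shell
#'
#' Every grid cell becomes a frame around a rectangular opening inset by
#' \code{p_s / 2} on each side, so the opening is approximately
#' \code{p_d} x \code{p_d} when the cell pitch equals \code{p_d + p_s}.
#' The result is an open surface with one boundary loop per pore plus the
#' two end loops (open paths).
#'
#' @param shell output of \code{\link{sweep_shell}} (supplies the sweep
#'   metadata; the pored surface is rebuilt parametrically).
#' @param grid,spec the same grid and spec used for the shell.
#' @return An open \code{surface_mesh} with pore metadata attached.
#' @export
cut_pores <- function(shell, grid, spec) {
  sw <- attr(shell, "sweep")
  if (is.null(sw)) stop("shell lacks sweep metadata; use sweep_shell()")
  if (!identical(unclass(sw$grid)[c("u", "v")],
                 unclass(grid)[c("u", "v")])) {
    stop("grid does not match the grid the shell was swept with")
  }
  build_pored_membrane(sw$path, grid, spec, rep(1, grid$u * grid$v))
}

#' Elongate side-facing pores circumferentially
#'
#' Pores whose outward normals lie within \code{side_cone_deg} of the
#' horizontal plane print closed because of the anisotropic (elongated
#' vertical) writing voxel; stretching their openings circumferentially by
#' \code{spec$side_pore_elongation} compensates. Top- and bottom-facing
#' pores are unchanged.
#'
#' @param shell a pored membrane from \code{\link{cut_pores}}.
#' @param spec the \code{\link{capillary_spec}} (supplies the factor).
#' @param side_cone_deg classification half-angle from the horizontal
#'   plane (default 30).
#' @return The rebuilt \code{surface_mesh} with elongated side pores.
#' @export
elongate_side_pores <- function(shell, spec, side_cone_deg = 30) {
  sw <- attr(shell, "sweep")
  pores <- attr(shell, "pores")
  if (is.null(sw) || is.null(pores)) {
    stop("shell lacks pore metadata; use cut_pores()")
  }
  grid <- sw$grid
  nz <- vapply(pores, function(p) abs(p$normal[3]), numeric(1))
  side <- nz <= sin(side_cone_deg * pi / 180) + 1e-12
  factors <- rep(1, length(pores))
  idx <- vapply(pores, function(p) (p$j - 1L) * grid$u + p$i, numeric(1))
  factors[idx[side]] <- spec$side_pore_elongation
  build_pored_membrane(sw$path, grid, spec, factors)
}

#' Thicken an open shell into a watertight solid membrane
#'
#' Offsets every vertex along its outward radial direction and bridges all
#' boundary loops, turning pore openings into through-channels and the tube
#' ends into annular caps. In \code{outward} mode the lumen surface is
#' preserved, so \code{l_d} remains the inner (perfusable) diameter.
#'
#' @param shell open membrane surface with radial metadata
#'   (\code{\link{sweep_shell}} or \code{\link{cut_pores}} output).
#' @param thickness membrane wall thickness (um, > 0).
#' @param mode \code{"outward"} (default) or \code{"symmetric"}.
#' @return A watertight \code{surface_mesh}; for a membrane with P pores
#'   the Euler characteristic is -2P.
#' @export
thicken <- function(shell, thickness, mode = c("outward", "symmetric")) {
  mode <- match.arg(mode)
  if (!is.numeric(thickness) || thickness <= 0) {
    stop("thickness must be > 0")
  }
  radial <- attr(shell, "radial")
  sw <- attr(shell, "sweep")
  if (is.null(radial)) stop("shell lacks radial metadata")
  if (!is.null(sw)) {
    rmin <- path_min_bend_radius(sw$path)
    r_out <- sw$spec$lumen_diameter / 2 +
      if (mode == "outward") thickness else thickness / 2
    if (rmin <= r_out) {
      stop("thickening self-intersects: outer radius ", r_out,
           " um >= minimum bend radius ", format(rmin, digits = 4), " um")
    }
  }
  V <- shell$vertices
  N <- nrow(V)
  if (mode == "outward") {
    Vin <- V
    Vout <- V + thickness * radial
  } else {
    Vin <- V - (thickness / 2) * radial
    Vout <- V + (thickness / 2) * radial
  }
  F <- shell$faces
  # directed boundary edges (appear once): bridge inner loop to outer loop
  de <- rbind(F[, c(1, 2), drop = FALSE], F[, c(2, 3), drop = FALSE],
              F[, c(3, 1), drop = FALSE])
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  bnd <- de[cnt[key] == 1L, , drop = FALSE]
  a <- bnd[, 1]; b <- bnd[, 2]
  bridges <- rbind(cbind(a, b, b + N), cbind(a, b + N, a + N))
  Fsolid <- rbind(F[, c(1, 3, 2), drop = FALSE],  # lumen surface, flipped
                  F + N,                          # outer surface
                  bridges)
  m <- surface_mesh(rbind(Vin, Vout), Fsolid, "membrane")
  for (at in c("sweep", "pores", "factors")) {
    attr(m, at) <- attr(shell, at)
  }
  attr(m, "lumen_vertex_count") <- N
  m
}

#' Per-pore size table
#'
#' Reports, for every pore, its arc-length position, angular position and
#' effective diameter (the largest inscribed circle of the rectangular
#' opening, i.e. the smaller of the axial and circumferential extents
#' measured on the mesh). On curved paths this captures pores constricting
#' on interior curves and widening on exterior curves.
#'
#' @param mesh a pored membrane (\code{\link{cut_pores}},
#'   \code{\link{elongate_side_pores}} or \code{\link{thicken}} output).
#' @param path optional; defaults to the path stored in the mesh metadata.
#' @return A tibble with columns \code{pore_id}, \code{s}, \code{theta},
#'   \code{axial_um}, \code{circ_um}, \code{diameter_um},
#'   \code{elongation}, \code{normal_z}.
#' @export
pore_size_profile <- function(mesh, path = NULL) {
  pores <- attr(mesh, "pores")
  if (is.null(pores) || length(pores) == 0) {
    return(tibble::tibble(pore_id = integer(0), s = numeric(0),
                          theta = numeric(0), axial_um = numeric(0),
                          circ_um = numeric(0), diameter_um = numeric(0),
                          elongation = numeric(0), normal_z = numeric(0)))
  }
  V <- mesh$vertices
  rows <- lapply(seq_along(pores), function(k) {
    p <- pores[[k]]
    cn <- p$corners  # (s-,th-), (s-,th+), (s+,th-), (s+,th+)
    axial <- (sqrt(sum((V[cn[3], ] - V[cn[1], ])^2)) +
              sqrt(sum((V[cn[4], ] - V[cn[2], ])^2))) / 2
    circ <- (sqrt(sum((V[cn[2], ] - V[cn[1], ])^2)) +
             sqrt(sum((V[cn[4], ] - V[cn[3], ])^2))) / 2
    c(k, p$s, p$theta, axial, circ, min(axial, circ), p$factor,
      p$normal[3])
  })
  m <- do.call(rbind, rows)
  tibble::tibble(pore_id = as.integer(m[, 1]), s = m[, 2], theta = m[, 3],
                 axial_um = m[, 4], circ_um = m[, 5], diameter_um = m[, 6],
                 elongation = m[, 7], normal_z = m[, 8])
}
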