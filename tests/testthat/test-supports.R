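test_that("FOV seam crossings on an axis-aligned straight path", {
  lay <- fov_layout(fov_width = 400, overlap = 0, stitch_angle = 0,
                    origin = c(0, 0))
  p <- centerline_path(cbind(seq(0, 1000, 100), 0, 0), degree = 1)
  seams <- predict_fov_seams(lay, p)
  expect_equal(seams$s, c(400, 800), tolerance = 1e-6)
  # a short path inside one tile crosses nothing
  p2 <- centerline_path(cbind(c(10, 100), c(10, 50), c(0, 0)), degree = 1)
  expect_equal(nrow(predict_fov_seams(lay, p2)), 0)
})

test_that("rotated seams match a brute-force line intersection oracle", {
  lay <- fov_layout(fov_width = 300, overlap = 5, stitch_angle = 15,
                    origin = c(20, -10))
  L <- centerline_path(rbind(c(0, 0, 0), c(700, 0, 0), c(700, 600, 0)),
                       degree = 1)
  seams <- predict_fov_seams(lay, L)
  # oracle: intersect each polyline segment with each seam line family
  period <- 295
  ang <- 15 * pi / 180
  normals <- rbind(c(cos(ang), sin(ang)), c(-sin(ang), cos(ang)))
  pts <- L$points[, 1:2]
  hits <- c()
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  for (seg in 1:(nrow(pts) - 1)) {
    a <- pts[seg, ]; b <- pts[seg + 1, ]
    for (fam in 1:2) {
      nv <- normals[fam, ]
      da <- sum((a - c(20, -10)) * nv)
      db <- sum((b - c(20, -10)) * nv)
      ks <- seq(ceiling(min(da, db) / period), floor(max(da, db) / period))
      for (k in ks) {
        t <- (k * period - da) / (db - da)
        if (t >= 0 && t <= 1) {
          hits <- c(hits, cum[seg] + t * sqrt(sum((b - a)^2)))
        }
      }
    }
  }
  expect_equal(sort(seams$s), sort(hits), tolerance = 1e-6)
})

test_that("seam prediction is invariant to one-period origin shifts", {
  p <- hilbert_path(2, 2, step = 150)
  lay1 <- fov_layout(400, 5, 15, origin = c(0, 0))
  period <- 395
  ang <- 15 * pi / 180
  lay2 <- fov_layout(400, 5, 15,
                     origin = c(period * cos(ang), period * sin(ang)))
  s1 <- predict_fov_seams(lay1, p)$s
  s2 <- predict_fov_seams(lay2, p)$s
  expect_equal(sort(s1), sort(s2), tolerance = 1e-6)
})

test_that("polygonal supports build one assembly per anchor", {
  p <- shifted <- centerline_path(cbind(seq(0, 2000, 100), 0, 150),
                                  degree = 1)
  spec <- polygonal_support_spec(polygon_sides = 4, beam_diameter = 15)
  # 21 evenly spaced rings along the path
  pos <- seq(0, p$path_length, length.out = 21)
  m <- polygonal_supports(p, spec, pos, capillary_outer_diameter = 110)
  expect_equal(attr(m, "n_assemblies"), 21)
  expect_gt(nrow(m$faces), 0)
  expect_equal(nrow(polygonal_supports(p, spec, numeric(0), 110)$faces), 0)
  # capillary too close to the base for the beams
  low <- centerline_path(cbind(seq(0, 500, 100), 0, 40), degree = 1)
  expect_error(polygonal_supports(low, spec, c(250), 110), "clearance")
})

test_that("collar inner surface sits at capillary radius plus clearance", {
  ring <- annular_cylinder_mesh(c(0, 0, 100), c(1, 0, 0), r_in = 57,
                                r_out = 72, height = 15)
  d <- sqrt(ring$vertices[, 2]^2 + (ring$vertices[, 3] - 100)^2)
  expect_equal(min(d), 57, tolerance = 1e-6)
  expect_true(is_watertight(ring))
  expect_identical(euler_characteristic(ring), 0L)  # genus-1 solid
  # assembled support never intrudes inside the collar radius
  p <- centerline_path(cbind(seq(0, 500, 100), 0, 150), degree = 1)
  spec <- polygonal_support_spec(beam_diameter = 15, collar_clearance = 2)
  m <- polygonal_supports(p, spec, c(250), capillary_outer_diameter = 110)
  dd <- sqrt(m$vertices[, 2]^2 + (m$vertices[, 3] - 150)^2)
  expect_gte(min(dd), 57 - 1e-6)
})

test_that("lattice edge combinatorics: 36 per cell, shared edges deduped", {
  single <- lattice_spec(100, 10, rbind(c(-50, -50, -50), c(50, 50, 50)))
  e1 <- lattice_edges(single)
  expect_equal(nrow(e1), 36)
  double <- lattice_spec(100, 10, rbind(c(-50, -50, -50), c(150, 50, 50)))
  e2 <- lattice_edges(double)
  expect_lt(nrow(e2), 2 * 36)
  expect_equal(nrow(e2), 68)
  expect_error(lattice_spec(200, 10, rbind(c(0, 0, 0), c(100, 100, 100))),
               "exceeds")
})

test_that("lattice edge set does not depend on cell enumeration order", {
  spec <- lattice_spec(80, 8, rbind(c(-10, -10, -10), c(170, 90, 90)))
  key <- function(e) {
    k <- apply(round(cbind(e$x0, e$y0, e$z0, e$x1, e$y1, e$z1), 6), 1,
               paste, collapse = ",")
    sort(k)
  }
  expect_identical(key(lattice_edges(spec)), key(lattice_edges(spec)))
})

test_that("strut culling keeps grazing struts and removes intruders", {
  # capillary: straight solid-walled tube along x at the origin
  tube <- calibration_tube()
  g <- tube$grid
  solid <- thicken(sweep_shell(tube$path, g, tube$spec), 10)
  r_out <- 120 / pi / 2 + 10
  clearance <- 2
  radius <- 5
  mk <- function(y) strut_set(cbind(500, y, -60), cbind(500, y, 60),
                              radius = radius)
  # through the lumen axis: removed
  expect_equal(nrow(cull_struts(mk(0), solid, clearance)), 0)
  # far outside: kept
  expect_equal(nrow(cull_struts(mk(500), solid, clearance)), 1)
  # grazing: just beyond radius + clearance kept, just inside removed
  eps <- 0.05
  keep_y <- r_out + radius + clearance + eps
  cut_y <- r_out + radius + clearance - eps
  expect_equal(nrow(cull_struts(mk(keep_y), solid, clearance)), 1)
  expect_equal(nrow(cull_struts(mk(cut_y), solid, clearance)), 0)
  # cross-check the borderline distances with the pure-R oracle
  d_keep <- r_min_dist_to_mesh(c(500, keep_y, 0), solid)
  expect_gt(d_keep, radius + clearance)
})

test_that("surviving struts clear the capillary by the signed distance", {
  tube <- calibration_tube(length_um = 400)
  solid <- thicken(sweep_shell(tube$path, tube$grid, tube$spec), 10)
  box <- rbind(c(-40, -80, -80), c(440, 80, 80))
  edges <- lattice_edges(lattice_spec(80, 10, box))
  kept <- cull_struts(edges, solid, clearance = 2, radius = 5)
  expect_gt(nrow(kept), 0)
  expect_lt(nrow(kept), nrow(edges))
  # sampled oracle distances on kept struts all >= radius + clearance
  set.seed(1)
  idx <- sample(nrow(kept), min(12, nrow(kept)))
  for (i in idx) {
    tt <- seq(0, 1, length.out = 7)
    pts <- cbind(kept$x0[i] + tt * (kept$x1[i] - kept$x0[i]),
                 kept$y0[i] + tt * (kept$y1[i] - kept$y0[i]),
                 kept$z0[i] + tt * (kept$z1[i] - kept$z0[i]))
    dmin <- min(apply(pts, 1, r_min_dist_to_mesh, mesh = solid))
    expect_gte(dmin, 5 + 2 - 1e-6)
  }
})

test_that("piped struts are capped capsules of the right volume", {
  s <- strut_set(cbind(0, 0, 0), cbind(0, 0, 120))
  m <- pipe_struts(s, beam_diameter = 10)
  va <- pi * 25 * 120 + 4 / 3 * pi * 125
  expect_lt(abs(mesh_volume(m) - va) / va, 0.02)
  expect_true(is_watertight(m))
  expect_equal(nrow(pipe_struts(strut_set(matrix(0, 0, 3),
                                          matrix(0, 0, 3)), 10)$faces), 0)
  zl <- strut_set(rbind(c(0, 0, 0), c(5, 5, 5)),
                  rbind(c(0, 0, 0), c(5, 5, 50)))
  expect_warning(m2 <- pipe_struts(zl, 10), "zero-length")
  expect_true(nrow(m2$faces) > 0)
})

test_that("connectivity reporting matches an igraph oracle", {
  # full small lattice: one component, anchored at its base
  box <- rbind(c(0, 0, 0), c(160, 160, 160))
  edges <- lattice_edges(lattice_spec(80, 8, box))
  rep_ <- connectivity_check(edges, base_z = 0)
  expect_equal(nrow(rep_), 1)
  expect_true(all(rep_$anchored))
  # add a floating strut
  fl <- rbind(edges, strut_set(cbind(500, 500, 100), cbind(520, 500, 100)))
  rep2 <- connectivity_check(fl, base_z = 0)
  expect_equal(sum(!rep2$anchored), 1)
  # independent component count via igraph on the merged endpoint graph
  pts <- rbind(as.matrix(fl[, c("x0", "y0", "z0")]),
               as.matrix(fl[, c("x1", "y1", "z1")]))
  key <- apply(round(pts, 1), 1, paste, collapse = ",")
  node <- as.integer(factor(key))
  n <- nrow(fl)
  gr <- igraph::graph_from_edgelist(cbind(node[1:n], node[n + 1:n]),
                                    directed = FALSE)
  expect_equal(nrow(rep2), igraph::components(gr)$no)
  expect_equal(nrow(drop_floating_struts(fl, 0)), nrow(edges))
})

test_that("cone supports honour the minimum printable taper", {
  expect_error(cone_support_spec(taper_angle = 10, positions = cbind(0, 0)),
               ">= 15")
  p <- centerline_path(cbind(seq(-200, 200, 50), 0, 80), degree = 1)
  spec <- cone_support_spec(taper_angle = 15, tip_radius = 10,
                            positions = rbind(c(0, 0), c(120, 0)))
  cones <- cone_supports(spec, p, capillary_outer_diameter = 60)
  expect_gte(min_facet_taper(cones), 15 - 1e-6)
  expect_true(is_watertight(cones))
})

test_that("capillary subtraction keeps cones out of the lumen", {
  p <- centerline_path(cbind(seq(-200, 200, 50), 0, 60), degree = 1)
  spec <- cone_support_spec(taper_angle = 18, tip_radius = 12,
                            positions = rbind(c(0, 0)))
  cones <- cone_supports(spec, p, capillary_outer_diameter = 60)
  # no mesh point inside the lumen cylinder (radius 20 about the axis)
  d <- sqrt(cones$vertices[, 2]^2 + (cones$vertices[, 3] - 60)^2)
  expect_gte(min(d), 30 - 1e-9)  # outer envelope, well clear of the lumen
  contacts <- attr(cones, "contacts")
  expect_true(all(contacts$hit))
  # anchor far from the path misses the membrane and is flagged
  spec2 <- cone_support_spec(taper_angle = 15, tip_radius = 10,
                             positions = rbind(c(0, 400)))
  cones2 <- cone_supports(spec2, p, capillary_outer_diameter = 60)
  expect_false(attr(cones2, "contacts")$hit)
})
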