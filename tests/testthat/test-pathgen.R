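test_that("CSV import parses points, headers and comments, scales units", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# capillary axis", "x,y,z", "0,0,0", "100,0,0"), f)
  p <- load_path_csv(f)
  expect_s3_class(p, "centerline_path")
  expect_equal(p$path_length, 100)
  # unit scaling: mm input to um
  p2 <- load_path_csv(f, units_scale = 1000)
  expect_equal(p2$path_length, 100000)
})

test_that("CSV import of a Hilbert polyline recovers the chord-sum length", {
  h <- hilbert_path(2, 2, step = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write.table(h$points, f, sep = ",", row.names = FALSE, col.names = FALSE)
  p <- load_path_csv(f, degree = 1)
  # 4^2 = 16 vertices, 15 unit steps of 100 um
  expect_equal(nrow(p$points), 16)
  expect_equal(p$path_length, 1500)
})

test_that("CSV import rejects malformed rows, naming the line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "a,b,c"), f)
  expect_error(load_path_csv(f), "line 2")
  writeLines("1,2,3", f)
  expect_error(load_path_csv(f), "2 points")
})

test_that("paths reject duplicates and degenerate input", {
  expect_error(centerline_path(rbind(c(0, 0, 0), c(0, 0, 0))), "duplicate")
  expect_error(centerline_path(rbind(c(0, 0, 0))), "2 points")
  p <- centerline_path(rbind(c(0, 0, 0), c(50, 0, 0), c(50, 80, 0)))
  # arc length of the dense samples matches the stored total to 0.1%
  seg <- sqrt(rowSums(diff(p$dense$xyz)^2))
  expect_lt(abs(sum(seg) - p$path_length) / p$path_length, 1e-3)
})

test_that("Hilbert curves have the right vertex counts and lengths", {
  h1 <- hilbert_path(1, 2, step = 100)
  expect_equal(nrow(h1$points), 4)
  expect_equal(h1$path_length, 300)
  h2 <- hilbert_path(2, 2, step = 100)
  expect_equal(nrow(h2$points), 16)
  expect_equal(h2$path_length, 1500)
  h3 <- hilbert_path(1, 3, step = 100)
  expect_equal(nrow(h3$points), 8)
  expect_equal(h3$path_length, 700)
  expect_error(hilbert_path(1, 4), "dims")
  expect_error(hilbert_path(0, 2), "order")
})

test_that("Hilbert self-avoidance: non-adjacent segment gap equals step", {
  for (ord in 2:3) {
    h <- hilbert_path(ord, 2, step = 100)
    expect_equal(min_self_distance(h), 100, tolerance = 1e-12)
  }
})

test_that("stacked Hilbert layers join through a vertical connector", {
  h <- hilbert_path(2, 2, step = 100, layers = 2, layer_gap = 80)
  expect_equal(nrow(h$points), 32)
  z <- h$points[, 3]
  expect_setequal(unique(z), c(0, 80))
  # the connector joins coincident (x, y): layer 2 is reversed
  expect_equal(h$points[16, 1:2], h$points[17, 1:2])
  expect_equal(h$path_length, 2 * 1500 + 80)
})

test_that("helix arc length matches the closed form", {
  hp <- helix_path(radius = 50, pitch = 100, turns = 2,
                   samples_per_turn = 64)
  expect_length(hp, 1)
  exact <- 2 * sqrt((2 * pi * 50)^2 + 100^2)
  expect_lt(abs(hp[[1]]$path_length - exact) / exact, 0.005)
  expect_error(helix_path(50, 100, 0), "turns")
  expect_error(helix_path(50, 100, 1, samples_per_turn = 4), "undersample")
})

test_that("double helix strands stay two radii apart at matched samples", {
  hp <- helix_path(radius = 50, pitch = 100, turns = 1.5, strands = 2,
                   samples_per_turn = 36)
  expect_length(hp, 2)
  d <- sqrt(rowSums((hp[[1]]$points - hp[[2]]$points)[, 1:2, drop = FALSE]^2))
  expect_equal(d, rep(100, length(d)), tolerance = 1e-9)
})

test_that("frames on a straight line are identical and twist-free", {
  p <- centerline_path(rbind(c(0, 0, 0), c(0, 0, 500)), degree = 1)
  fr <- compute_frames(p, 11)
  expect_equal(max(apply(fr$normal, 2, function(x) diff(range(x)))), 0,
               tolerance = 1e-12)
  # orthonormal right-handed triads
  expect_equal(rowSums(fr$tangent * fr$normal), rep(0, 11),
               tolerance = 1e-9)
  expect_equal(rowSums(fr$tangent^2), rep(1, 11), tolerance = 1e-9)
  tb <- fr$tangent[1, ]
  cross <- c(fr$normal[1, 2] * fr$binormal[1, 3] -
               fr$normal[1, 3] * fr$binormal[1, 2],
             fr$normal[1, 3] * fr$binormal[1, 1] -
               fr$normal[1, 1] * fr$binormal[1, 3],
             fr$normal[1, 1] * fr$binormal[1, 2] -
               fr$normal[1, 2] * fr$binormal[1, 1])
  expect_equal(sum(cross * tb), 1, tolerance = 1e-9)
})

test_that("frames on a planar circle stay in plane with zero net twist", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  p <- centerline_path(cbind(200 * cos(th), 200 * sin(th), 0),
                       closed = TRUE)
  fr <- compute_frames(p, 41)
  # rotation-minimizing normals of a planar curve remain in the plane
  expect_lt(max(abs(fr$normal[, 3])), 1e-6)
})

test_that("rotation-minimizing frames agree with a fine-step oracle", {
  th <- seq(0, 4 * pi, length.out = 200)
  p <- centerline_path(cbind(50 * cos(th), 50 * sin(th),
                             100 * th / (2 * pi)))
  coarse <- compute_frames(p, 25)
  fine <- capforge:::rmf_frames(p, coarse$s, n_prop = 8000)
  ang <- acos(pmin(1, abs(rowSums(coarse$normal * fine$normal))))
  expect_lt(max(ang), 1e-4)
  # helix RMF normals differ from the (inward-pointing) Frenet normals
  frenet <- -cbind(cos(th), sin(th), 0)[1, ]
  expect_gt(acos(abs(sum(coarse$normal[nrow(coarse$normal), ] *
                           frenet))), 0.01)
})

test_that("arc-length stations are uniformly spaced", {
  h <- hilbert_path(2, 2, step = 100, degree = 3, corner_fillet_radius = 20)
  fr <- compute_frames(h, 40)
  gaps <- sqrt(rowSums(diff(fr$position)^2))
  target <- h$path_length / 39
  # chord gaps dip below arc spacing only at corners; station arc spacing
  # itself is exact by construction
  expect_equal(diff(fr$s)[1], target, tolerance = 1e-9)
  expect_lt(max(abs(diff(fr$s) - target)) / target, 0.005)
})
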