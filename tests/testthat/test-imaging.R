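test_that("binarization recovers a two-level image exactly", {
  img <- matrix(0.1, 40, 40)
  img[10:20, 5:30] <- 0.9
  expect_identical(binarize(img), img > 0.5)
  expect_true(all(binarize(img + 0.05, method = "fixed", threshold = 0)))
  expect_error(binarize(matrix(0.5, 10, 10)), "constant")
})

test_that("contrast stretch plus Otsu matches the histogram oracle", {
  set.seed(11)
  img <- matrix(runif(80 * 60)^2, 60, 80)
  img[20:40, 30:60] <- pmin(1, img[20:40, 30:60] + 0.55)
  stretched <- pmin(1, pmax(0, (img - 0.5) * 1.3 + 0.5))
  oracle <- stretched > r_otsu(stretched)
  got <- binarize(img, contrast_stretch = 30)
  expect_gt(mean(got == oracle), 0.995)
})

test_that("design-mask rendering: silhouettes at known areas", {
  cube <- extrude_polygon_mesh(rbind(c(0, 0), c(100, 0), c(100, 100),
                                     c(0, 100)), 0, 30)
  mk <- render_design_mask(cube, pixel_size = 2)
  expect_equal(sum(mk) * 4, 100 * 100, tolerance = 0.05)
  side <- sqrt(sum(mk))
  expect_equal(side * 2, 100, tolerance = 2 * 2)  # +- 1 px
  expect_error(render_design_mask(cube, 0), "pixel_size")
  # provenance exclusion drops support faces from the render
  sup <- mesh_translate(uv_sphere_mesh(radius = 40, n_seg = 16,
                                       provenance = "support"),
                        c(300, 50, 0))
  both <- assemble(list(cube, sup))
  m_all <- render_design_mask(both, 2)
  m_mem <- render_design_mask(both, 2, exclude_provenance = "support")
  expect_gt(sum(m_all), sum(m_mem))
  # a cylinder viewed top-down projects length x diameter
  tube <- calibration_tube(length_um = 500)
  solid <- thicken(sweep_shell(tube$path, tube$grid, tube$spec), 8)
  mc <- render_design_mask(solid, 1)
  od <- 120 / pi + 16
  expect_equal(sum(mc), 500 * od, tolerance = 0.02 * 500 * od)
})

test_that("registration fractions: identity, misses and offsets", {
  g <- synth_mask_pair(seed = 2)
  t_ <- g$target
  # identical masks: full overlap, nothing missing or excess
  r <- registration_map(mask_pair(t_, t_))$result
  expect_equal(r$overlap_percent, 100)
  expect_equal(r$green_fraction, 0)
  expect_equal(r$red_fraction, 0)
  # blank experiment: everything designed is missing
  r2 <- registration_map(mask_pair(t_, t_ & FALSE))$result
  expect_equal(r2$green_fraction, mean(t_))
  expect_equal(r2$overlap_percent, 0)
  # two 100 x 100 squares offset by 20 px: 80 x 100 overlap
  A <- matrix(FALSE, 200, 200); A[51:150, 51:150] <- TRUE
  B <- matrix(FALSE, 200, 200); B[51:150, 71:170] <- TRUE
  r3 <- registration_map(mask_pair(A, B))$result
  expect_equal(r3$yellow_fraction, 80 * 100 / 4e4)
  expect_equal(r3$green_fraction, 20 * 100 / 4e4)
  expect_equal(r3$red_fraction, 20 * 100 / 4e4)
  expect_equal(r3$yellow_fraction + r3$green_fraction + r3$red_fraction +
                 r3$black_fraction, 1, tolerance = 1e-9)
  expect_error(mask_pair(A, matrix(FALSE, 10, 10)), "dimensions")
})

test_that("overlap metric is invariant under joint in-bounds shifts", {
  g <- synth_mask_pair(seed = 3, erosion_px = 2)
  crop <- function(m, dy, dx) m[(21 + dy):(200 + dy), (21 + dx):(200 + dx)]
  r0 <- registration_map(mask_pair(crop(g$target, 0, 0),
                                   crop(g$experiment, 0, 0)))$result
  r1 <- registration_map(mask_pair(crop(g$target, 10, -5),
                                   crop(g$experiment, 10, -5)))$result
  expect_equal(r0$overlap_percent, r1$overlap_percent, tolerance = 2)
})

test_that("alignment refinement undoes a known integer shift", {
  # an aperiodic disk field has an unambiguous correlation peak
  m <- synth_live_dead(30, 1, seed = 4)$green > 0.5
  e <- capforge:::shift_mask(m, 3, -4)
  ref <- refine_alignment(mask_pair(m, e), max_shift = 6)
  expect_equal(attr(ref, "shift"), c(-3, 4))
  expect_equal(registration_map(ref)$result$overlap_percent, 100,
               tolerance = 0.5)
})

test_that("bead tracking: single bead, crossing beads, empty frames", {
  # single bead moving 10 px/frame
  mkframe <- function(x, y) {
    img <- matrix(0, 60, 200)
    xs <- matrix(rep(1:200, each = 60), 60, 200)
    ys <- matrix(rep(1:60, 200), 60, 200)
    0.9 * exp(-((xs - x)^2 + (ys - y)^2) / (2 * 1.5^2))
  }
  frames <- simplify2array(lapply(0:5, function(i) mkframe(30 + 10 * i, 30)))
  tr <- track_beads(frames, "auto")
  expect_equal(length(unique(tr$track)), 1)
  est <- estimate_velocity(tr, pixel_size = 1, frame_interval = 0.01)
  expect_equal(est$mean_velocity, 10 * 1 / 0.01 / 1000, tolerance = 1e-3)
  # two beads crossing in x while separated in y: unbroken tracks
  f2 <- simplify2array(lapply(0:5, function(i) {
    mkframe(40 + 10 * i, 20) + mkframe(90 - 10 * i, 40)
  }))
  tr2 <- track_beads(f2, "auto", max_displacement = 14)
  expect_equal(length(unique(tr2$track)), 2)
  counts <- table(tr2$track)
  expect_true(all(counts == 6))
  # each track keeps a constant lane
  lanes <- tapply(tr2$y, tr2$track, function(y) diff(range(y)))
  expect_lt(max(lanes), 2)
  # empty frames
  tr3 <- track_beads(array(0, c(20, 20, 3)), "auto")
  expect_equal(nrow(tr3), 0)
})

test_that("velocity estimation: units, aggregation and errors", {
  tracks <- tibble::tibble(track = rep(1:2, each = 3),
                           frame = rep(1:3, 2),
                           x = c(0, 10, 20, 0, 20, 40), y = 0)
  class(tracks) <- c("bead_tracks", class(tracks))
  est <- estimate_velocity(tracks, pixel_size = 1, frame_interval = 0.01)
  expect_equal(est$mean_velocity, 1.5)  # 1.0 and 2.0 mm/s
  expect_equal(est$sd_velocity, sd(c(1, 2)))
  expect_equal(est$n_tracks, 2)
  # linear in pixel_size, inverse-linear in frame_interval
  e2 <- estimate_velocity(tracks, 2, 0.01)
  e3 <- estimate_velocity(tracks, 1, 0.02)
  expect_equal(e2$mean_velocity, 2 * est$mean_velocity)
  expect_equal(e3$mean_velocity, est$mean_velocity / 2)
  expect_error(estimate_velocity(tracks, 1, 0), "frame_interval")
  expect_error(estimate_velocity(tracks[0, ], 1, 0.01), "no tracks")
})

test_that("manual tracking links supplied click positions by order", {
  pts <- lapply(0:4, function(i) cbind(c(10 + 5 * i, 50), c(20, 30 + 2 * i)))
  tr <- track_beads(array(0, c(50, 80, 5)), "manual", points = pts)
  expect_equal(length(unique(tr$track)), 2)
  est <- estimate_velocity(tr, 1, 0.001)
  expect_equal(sort(est$track_speeds), c(2, 5), tolerance = 1e-9)
})

test_that("live/dead counting recovers construction counts exactly", {
  ld <- synth_live_dead(50, 10, seed = 8)
  v <- count_live_dead(ld$green, ld$red)
  expect_equal(v$live_count, 50)
  expect_equal(v$dead_count, 10)
  expect_equal(v$viability_percent, 100 * 50 / 60, tolerance = 1e-9)
  # exact for other seeds too
  for (s in c(21, 99)) {
    ld2 <- synth_live_dead(30, 15, seed = s)
    v2 <- count_live_dead(ld2$green, ld2$red)
    expect_equal(v2$live_count, 30)
    expect_equal(v2$dead_count, 15)
  }
  expect_error(count_live_dead(matrix(0, 5, 5), matrix(0, 5, 5)),
               "undefined")
})

test_that("double-stained cells count as dead only", {
  g <- matrix(0, 60, 60); r <- matrix(0, 60, 60)
  disk <- function(m, cy, cx) {
    for (y in 1:60) for (x in 1:60) {
      if ((y - cy)^2 + (x - cx)^2 <= 16) m[y, x] <- 0.9
    }
    m
  }
  g <- disk(g, 15, 15)   # live-only cell
  g <- disk(g, 45, 45)   # double-stained cell
  r <- disk(r, 45, 45)
  v <- count_live_dead(g, r, min_area_px = 10)
  expect_equal(v$live_count, 1)
  expect_equal(v$dead_count, 1)
})

test_that("touching disks split by area agree with a watershed oracle", {
  set.seed(5)
  img <- matrix(0, 120, 160)
  centers <- rbind(c(30, 30), c(30, 39), c(80, 100), c(90, 40), c(40, 120),
                   c(47, 128), c(100, 140))
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    for (y in 1:120) for (x in 1:160) {
      if ((y - cy)^2 + (x - cx)^2 <= 36) img[y, x] <- 0.9
    }
  }
  red <- matrix(0, 120, 160); red[5:8, 5:10] <- 0  # empty red channel
  red[110:118, 5:13] <- 0.9  # one dead cell so viability is defined
  v <- count_live_dead(img, red, min_area_px = 15)
  mask <- img > 0.5
  ws <- EBImage::watershed(EBImage::distmap(EBImage::Image(t(mask))), 1)
  n_ws <- max(EBImage::imageData(ws))
  expect_equal(v$live_count, n_ws, tolerance = 0.05 * n_ws)
})

test_that("manual corrections update counts deterministically", {
  ld <- synth_live_dead(50, 10, seed = 12)
  v <- count_live_dead(ld$green, ld$red)
  expect_identical(apply_corrections(v, NULL), v)
  v2 <- apply_corrections(v, tibble::tibble(
    x = c(1, 3), y = c(1, 3), action = c("add_live", "add_live")))
  expect_equal(v2$live_count, 52)
  expect_equal(v2$viability_percent, 100 * 52 / 62, tolerance = 1e-9)
  # add then remove at the same spot restores the counts
  v3 <- apply_corrections(v, tibble::tibble(
    x = c(7, 7), y = c(9, 9), action = c("add_dead", "remove")))
  expect_equal(v3$live_count, v$live_count)
  expect_equal(v3$dead_count, v$dead_count)
  expect_equal(nrow(v3$edits), 2)  # audit log keeps both edits
  expect_error(apply_corrections(v, tibble::tibble(
    x = 1e5, y = 1e5, action = "remove")), "within")
})

test_that("fixture generators are deterministic and truthful", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- synth_fixtures("sem_mask_pair", seed = 5, dir = d1)
  f2 <- synth_fixtures("sem_mask_pair", seed = 5, dir = d2)
  expect_identical(unname(tools::md5sum(f1$files)),
                   unname(tools::md5sum(f2$files)))
  expect_error(synth_fixtures("nope"), "unknown fixture kind")
  # erosion fraction round-trips through the registration analysis
  g <- synth_mask_pair(seed = 31, erosion_px = 2)
  r <- registration_map(mask_pair(g$target, g$experiment))$result
  expect_equal(r$green_fraction, g$truth$green, tolerance = 0.01)
  # movie at the flow-test working point recovers the speed within 2%
  mv <- synth_bead_movie(1.83, n_frames = 15, seed = 6)
  tr <- track_beads(mv$frames, "auto")
  est <- estimate_velocity(tr, mv$pixel_size, mv$frame_interval)
  expect_equal(est$mean_velocity, 1.83, tolerance = 0.02 * 1.83)
})
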