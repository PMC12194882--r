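test_that("chip base is a watertight slab of the right volume", {
  spec <- chip_spec(base_thickness = 20)
  fp <- rbind(c(0, 0), c(1000, 0), c(1000, 800), c(0, 800))
  base <- build_base(fp, spec)
  expect_true(is_watertight(base))
  expect_equal(mesh_volume(base), 1000 * 800 * 20, tolerance = 1e-3)
  expect_equal(range(base$vertices[, 3]), c(-20, 0))
  # self-intersecting footprint rejected
  bow <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(build_base(bow, spec), "self-intersect")
})

test_that("footprint hull encloses the scaffold with its margin", {
  sph <- uv_sphere_mesh(center = c(50, 20, 100), radius = 80, n_seg = 24)
  spec <- chip_spec(base_margin = 50)
  hull <- footprint_hull(sph, 50)
  # every hull vertex sits ~margin outside the projected sphere circle
  d <- sqrt((hull[, 1] - 50)^2 + (hull[, 2] - 20)^2)
  expect_true(all(d > 80 & d < 80 + 55))
  base <- build_base(NULL, spec, scaffold = sph)
  expect_true(is_watertight(base))
  # footprint smaller than the scaffold projection is rejected
  small <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_error(build_base(small, spec, scaffold = sph), "enclose")
})

test_that("nozzle ports mate the tubing with a through-bore", {
  spec <- chip_spec(nozzle_bore = 40, nozzle_outer_diameter = 508,
                    nozzle_height = 300)
  ends <- rbind(c(0, 0, 50), c(2000, 0, 50))
  noz <- build_nozzles(ends, spec, with_retaining_wall = FALSE)
  expect_true(is_watertight(noz))
  # annular wall thickness (508 - 40) / 2 = 234 um
  d <- sqrt((noz$vertices[, 1] - 0)^2 + noz$vertices[, 2]^2)
  d <- d[noz$vertices[, 1] < 1000]
  expect_equal(min(d), 20, tolerance = 1e-6)
  expect_equal(max(d), 254, tolerance = 1e-6)
  expect_equal(max(d) - min(d), 234, tolerance = 1e-6)
  # the bore is open: axis points are void (not inside the solid)
  axis_pts <- cbind(0, 0, seq(5, 295, length.out = 20))
  expect_false(any(points_in_mesh(axis_pts, noz)))
  # unreachable path ends
  expect_error(build_nozzles(rbind(c(0, 0, 500), c(100, 0, 50)), spec),
               "reach")
})

test_that("lumen-to-nozzle void forms one connected channel", {
  # straight capillary ending under two nozzle ports: walk the void along
  # lumen axis and up both bores; every probe must be outside the solid
  tube <- calibration_tube(length_um = 600, z = 150)
  solid <- thicken(sweep_shell(tube$path, tube$grid, tube$spec), 10)
  spec <- chip_spec(nozzle_bore = 30, nozzle_outer_diameter = 200,
                    nozzle_height = 150)
  noz <- build_nozzles(rbind(c(0, 0, 150), c(600, 0, 150)), spec)
  chip <- assemble(list(solid, noz))
  probes <- rbind(cbind(seq(10, 590, 20), 0, 150),
                  cbind(0, 0, seq(10, 115, 15)),
                  cbind(600, 0, seq(10, 115, 15)))
  for (comp in list(solid, noz)) {
    expect_false(any(points_in_mesh(probes, comp)))
  }
  expect_equal(nrow(chip$faces), nrow(solid$faces) + nrow(noz$faces))
})

test_that("assembly concatenates components and keeps provenance", {
  a <- uv_sphere_mesh(center = c(0, 0, 0), radius = 10, n_seg = 16)
  b <- mesh_translate(uv_sphere_mesh(radius = 10, n_seg = 16,
                                     provenance = "support"), c(50, 0, 0))
  m <- assemble(list(a, b))
  expect_equal(nrow(m$faces), nrow(a$faces) + nrow(b$faces))
  expect_setequal(unique(m$provenance), c("chip", "support"))
  expect_identical(assemble(list(a)), a)
  expect_error(assemble(list()), "non-empty")
})

test_that("overlapping assembly has union volume below the volume sum", {
  a <- extrude_polygon_mesh(rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40)),
                            0, 40)
  b <- mesh_translate(a, c(20, 0, 0))
  # voxel union oracle: probe a grid, point in either component
  gx <- seq(-5, 65, 2); gy <- seq(-5, 45, 2); gz <- seq(-5, 45, 2)
  P <- as.matrix(expand.grid(gx, gy, gz))
  inA <- points_in_mesh(P, a)
  inB <- points_in_mesh(P, b)
  vox <- 2^3
  v_union <- sum(inA | inB) * vox
  expect_lt(v_union, mesh_volume(a) + mesh_volume(b))
  expect_equal(v_union, 40 * 40 * 60, tolerance = 0.05)
})

test_that("decimation keeps watertightness and stays near the surface", {
  sp <- uv_sphere_mesh(radius = 100, n_seg = 64)
  d <- decimate(sp, 0.5)
  expect_true(is_watertight(d))
  expect_lte(nrow(d$faces), 0.5 * nrow(sp$faces))
  expect_lt(attr(d, "hausdorff_um"), 1)  # < 1% of the radius
  expect_error(decimate(sp, 0), "between 0 and 1")
  expect_error(decimate(sp, 1), "between 0 and 1")
})

test_that("binary STL round-trips exactly", {
  m <- uv_sphere_mesh(radius = 55.5, n_seg = 20)
  f <- withr::local_tempfile(fileext = ".stl")
  export_stl(m, f)
  m2 <- import_stl(f)
  expect_identical(nrow(m2$faces), nrow(m$faces))
  # vertex coordinates survive to float32 precision
  expect_lt(max(abs(range(m2$vertices) - range(m$vertices))), 1e-4)
  # a second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".stl")
  export_stl(m2, f2)
  m3 <- import_stl(f2)
  expect_identical(m3$vertices, m2$vertices)
  # normals are recomputed from winding: volume sign preserved
  expect_gt(mesh_volume(m2), 0)
})

test_that("binary STL layout: 84-byte preamble plus 50 bytes per facet", {
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(1:3))
  f <- withr::local_tempfile(fileext = ".stl")
  export_stl(tri, f)
  expect_identical(file.size(f), 84 + 50)
  raw <- readBin(f, "raw", 134)
  expect_identical(readBin(raw[81:84], "integer", size = 4,
                           endian = "little"), 1L)
  expect_error(export_stl(tri, "/nonexistent-dir/x.stl"), "cannot write")
})
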