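test_that("volume is count times voxel volume, zero for empty masks", {
  empty <- VoxelGrid(array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  expect_identical(cartilageVolume(empty), 0)
  expect_identical(cartilageSurface(empty), 0)
  full <- VoxelGrid(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  expect_equal(cartilageVolume(full), 1000)
  # anisotropic spacing enters the voxel volume
  aniso <- VoxelGrid(array(TRUE, c(10, 10, 10)), c(0.45, 0.45, 0.40))
  expect_equal(cartilageVolume(aniso), 1000 * 0.45 * 0.45 * 0.40)
  m <- morphometryAll(empty)
  expect_equal(c(m@cg_v, m@cg_s, m@cg_th), c(0, 0, 0))
})

test_that("sphere volume and surface match the analytic oracle", {
  r <- 3
  g <- ball_mask(r = r, h = 0.1)
  expect_lt(abs(cartilageVolume(g) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3),
            0.01)
  expect_lt(abs(cartilageSurface(g) - 4 * pi * r^2) / (4 * pi * r^2), 0.02)
})

test_that("box surface matches 2(ab+bc+ca) within 3 percent", {
  g <- box_mask(c(20, 20, 5), h = 0.1)
  expect_lt(abs(cartilageSurface(g) - 1200) / 1200, 0.03)
  expect_equal(cartilageVolume(g), 2000, tolerance = 1e-12)
})

test_that("slab thickness map: interior near truth, bounded maximum", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(10, 10)), 0.1)
  tm <- thicknessMap(ph@grid)
  expect_lte(max(tm@values), 1.2 + 2 * 0.1)
  expect_equal(meanThickness(tm), 1.2, tolerance = 0.05 / 1.2)
  # interior voxels (away from the lateral rim) sit at the slab thickness
  interior <- tm@values[30:70, 30:70, ]
  interior <- interior[interior > 0]
  expect_true(all(abs(interior - 1.2) <= 0.1 + 1e-9))
})

test_that("spherical shell wall thickness is recovered", {
  ph <- makePhantom(phantomSpec("spherical_shell", thickness = 1,
                                r_inner = 4), 0.1)
  tm <- thicknessMap(ph@grid)
  vals <- tm@values[tm@mask]
  expect_true(all(abs(vals - 1) <= 0.1 + 1e-9))
})

test_that("degenerate and error cases of the thickness map", {
  one <- hand_mask(cbind(3, 3, 3))
  tm <- thicknessMap(one)
  expect_equal(tm@values[3, 3, 3], 1, tolerance = 1e-9)
  empty <- VoxelGrid(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(thicknessMap(empty), "no foreground")
  expect_error(meanThickness(new("ThicknessMap",
                                 values = array(0, c(2, 2, 2)),
                                 mask = array(FALSE, c(2, 2, 2)),
                                 spacing = c(1, 1, 1))),
               "empty")
})

test_that("two-region sheet of equal volumes averages to 1.5 mm", {
  # widths 20 and 10 mm, thicknesses 1 and 2 mm: equal volumes
  h <- 0.1
  nx <- 320; ny <- 60; nz <- 40
  arr <- array(FALSE, c(nx, ny, nz))
  arr[11:210, 11:50, 11:20] <- TRUE    # 20 x 4 x 1 mm
  arr[211:310, 11:50, 11:30] <- TRUE   # 10 x 4 x 2 mm
  g <- VoxelGrid(arr, rep(h, 3))
  expect_equal(meanThickness(thicknessMap(g)), 1.5, tolerance = 0.05 / 1.5)
})

test_that("mean thickness of the map equals the bundled Cg.Th exactly", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(6, 6)), 0.15)
  m <- morphometryAll(ph@grid, "s")
  expect_identical(meanThickness(thicknessMap(ph@grid)), m@cg_th)
})

test_that("10 mm cube at 0.2 mm: volume and inscribed-sphere oracles", {
  g <- box_mask(c(10, 10, 10), h = 0.2)
  m <- morphometryAll(g, "cube")
  expect_lt(abs(m@cg_v - 1000) / 1000, 0.01)
  # the largest inscribed sphere has the edge length as diameter; the
  # volume-weighted mean is smaller because no such sphere reaches the
  # cube edges and corners
  tm <- thicknessMap(g)
  expect_lt(abs(max(tm@values) - 10) / 10, 0.05)
  expect_gt(m@cg_th, 0.75 * 10)
  expect_lte(m@cg_th, 10)
})

test_that("thickness map matches the brute-force covering-sphere oracle", {
  arr <- array(FALSE, c(10, 9, 8))
  arr[3:8, 3:7, 3:6] <- TRUE    # 6 x 5 x 4 voxel box at 1 mm
  g <- VoxelGrid(arr, c(1, 1, 1))
  tm <- thicknessMap(g)
  oracle <- thickness_oracle(arr, 1)
  # agreement within one voxel: the ridge-midpoint refinement can
  # overestimate near corner medial ridges by up to half a voxel in radius
  expect_lt(max(abs(tm@values - oracle)), 1 + 1e-9)
  expect_lt(abs(meanThickness(tm) - mean(oracle[arr])), 0.35)
})

test_that("metrics are translation invariant and volume is monotone", {
  arr <- array(FALSE, c(24, 24, 24))
  arr[5:10, 6:12, 7:9] <- TRUE
  a <- VoxelGrid(arr, c(0.3, 0.3, 0.3))
  arrB <- array(FALSE, c(24, 24, 24))
  arrB[10:15, 9:15, 13:15] <- TRUE
  b <- VoxelGrid(arrB, c(0.3, 0.3, 0.3))
  ma <- morphometryAll(a); mb <- morphometryAll(b)
  expect_equal(ma@cg_v, mb@cg_v)
  expect_equal(ma@cg_s, mb@cg_s)
  expect_equal(ma@cg_th, mb@cg_th)
  # A subset of B: volume monotone
  arrC <- arr; arrC[4:12, 5:14, 6:11] <- TRUE
  expect_lte(cartilageVolume(a), cartilageVolume(VoxelGrid(arrC, rep(0.3, 3))))
})

test_that("anisotropic masks are analysed on the isotropic grid", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(8, 8)),
                    c(0.45, 0.45, 0.1))
  m <- morphometryAll(ph@grid, "aniso")
  expect_equal(m@spacing_used, rep(0.1, 3))
  expect_equal(m@cg_th, 1.2, tolerance = 0.06 / 1.2)
  tm <- thicknessMap(ph@grid)
  expect_equal(tm@spacing, rep(0.1, 3))
})

test_that("surface mesh export writes a consistent PLY", {
  g <- ball_mask(r = 1.2, h = 0.2)
  p <- file.path(tempdir(), "mesh.ply")
  writeSurfacePLY(g, p, thickness = thicknessMap(g))
  lines <- readLines(p)
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("element face", lines, value = TRUE)))
  expect_identical(nv, 3L * nf)
  expect_gt(nf, 0)
})
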