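test_that("NIfTI and MetaImage round trips preserve data and spacing", {
  g <- box_mask(c(2, 2, 1), h = 0.5)
  gray <- GrayscaleVolume(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
                          c(0.45, 0.45, 0.40))
  for (ext in c("nii.gz", "nii", "mha", "mhd")) {
    p <- file.path(tempdir(), paste0("rt_mask.", ext))
    writeVolume(g, p)
    back <- readVolume(p)
    expect_s4_class(back, "VoxelGrid")
    expect_identical(voxelData(back), voxelData(g))
    expect_equal(voxelSpacing(back), voxelSpacing(g), tolerance = 1e-6)

    p2 <- file.path(tempdir(), paste0("rt_gray.", ext))
    writeVolume(gray, p2)
    back2 <- readVolume(p2)
    expect_s4_class(back2, "GrayscaleVolume")
    expect_equal(voxelData(back2), voxelData(gray), tolerance = 1e-12)
  }
})

test_that("10x10x10 mask at (0.45,0.45,0.40) round trips exactly", {
  arr <- array(stats::runif(1000) > 0.5, c(10, 10, 10))
  g <- VoxelGrid(arr, c(0.45, 0.45, 0.40))
  p <- file.path(tempdir(), "rt10.nii.gz")
  writeVolume(g, p)
  back <- readVolume(p)
  expect_identical(voxelData(back), arr)
  expect_equal(voxelSpacing(back), c(0.45, 0.45, 0.40), tolerance = 1e-6)
})

test_that("missing spacing metadata is an explicit error, never a default", {
  # MetaImage header without ElementSpacing
  p <- file.path(tempdir(), "nospacing.mha")
  con <- file(p, "wb")
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False", "DimSize = 2 2 2",
               "ElementType = MET_UCHAR", "ElementDataFile = LOCAL"), con)
  writeBin(rep(1L, 8), con, size = 1)
  close(con)
  expect_error(readVolume(p), "spacing unknown")
  # but an explicit override works
  g <- readVolume(p, spacing = c(1, 1, 1))
  expect_s4_class(g, "VoxelGrid")
  expect_error(readVolume(file.path(tempdir(), "does_not_exist.nii")),
               "not found")
  bad <- file.path(tempdir(), "unsupported.xyz")
  writeLines("not a volume", bad)
  expect_error(readVolume(bad), "format")
})

test_that("PNG slice stacks import with a JSON spacing sidecar", {
  skip_if_not_installed("png")
  dir <- file.path(tempdir(), "stack1")
  dir.create(dir, showWarnings = FALSE)
  arr <- array(stats::runif(4 * 5 * 3) > 0.5, c(4, 5, 3))
  for (k in 1:3)
    png::writePNG(t(arr[, , k]) * 1, file.path(dir, sprintf("s%03d.png", k)))
  expect_error(readVolume(dir), "spacing unknown")
  jsonlite::write_json(list(spacing_mm = c(0.45, 0.45, 0.4)),
                       file.path(dir, "spacing.json"), auto_unbox = TRUE)
  g <- readVolume(dir)
  expect_identical(voxelData(g), arr)
  expect_equal(voxelSpacing(g), c(0.45, 0.45, 0.4))
})

test_that("X/Z upscale preset gives the expected grid", {
  arr <- array(FALSE, c(10, 10, 10)); arr[4:6, 4:6, 4:6] <- TRUE
  g <- VoxelGrid(arr, c(0.45, 0.45, 0.40))
  up <- upscaleXZ(g, 5)
  expect_identical(dim(up), c(50L, 10L, 50L))
  expect_equal(voxelSpacing(up), c(0.09, 0.45, 0.08))
})

test_that("resampling to the current spacing is the identity", {
  arr <- array(stats::runif(1000) > 0.6, c(10, 10, 10))
  g <- VoxelGrid(arr, c(0.45, 0.45, 0.40))
  for (interp in c("nearest", "linear")) {
    same <- resampleGrid(g, voxelSpacing(g), interp)
    expect_identical(voxelData(same), arr)
  }
})

test_that("resampling preserves mask volume within the boundary tolerance", {
  # margin chosen so the slab faces fall between voxel centres (the
  # generic alignment; a face exactly on a centre makes the coarse
  # rasterisation itself lossy, which is not what this invariant tests)
  ph <- makePhantom(phantomSpec("slab", thickness = 1.6,
                                lateral_extent = c(10, 10)),
                    c(0.45, 0.45, 0.40), margin = 1.2)
  iso <- resampleGrid(ph@grid, rep(0.1, 3))
  # conservation of the mask volume (count x voxel volume) ...
  vm <- cartilageVolume(ph@grid)
  expect_lt(abs(cartilageVolume(iso) - vm) / vm, 0.02)
  # ... and agreement with the analytic slab volume
  expect_lt(abs(cartilageVolume(iso) - ph@truth$cg_v) / ph@truth$cg_v, 0.02)
})

test_that("fine-then-back resampling only changes a 1-voxel boundary shell", {
  g <- ball_mask(r = 2, h = 0.4)
  back <- resampleGrid(resampleGrid(g, rep(0.1, 3)), rep(0.4, 3))
  expect_identical(dim(back), dim(g))
  changed <- voxelData(back) != voxelData(g)
  # boundary shell: foreground/background voxels adjacent to the surface
  d_in <- auriMorph:::cpp_edt(voxelData(g), dim(g), voxelSpacing(g))
  d_out <- auriMorph:::cpp_edt(!voxelData(g), dim(g), voxelSpacing(g))
  shell <- pmin(d_in, d_out) <= 0.4 + 1e-9
  expect_true(all(shell[changed]))
})

test_that("degenerate resampling targets are rejected", {
  g <- box_mask(c(2, 2, 1), h = 0.5)
  expect_error(resampleGrid(g, c(100, 100, 100)), "too coarse")
  expect_error(resampleGrid(g, c(-1, 1, 1)), "positive")
})

test_that("mask constructor rejects non-binary data and bad spacing", {
  expect_error(VoxelGrid(array(c(0, 1, 2, 0), c(2, 2, 1)), c(1, 1, 1)),
               "\\{0, 1\\}")
  expect_error(VoxelGrid(array(FALSE, c(2, 2, 2)), c(1, 0, 1)),
               "positive")
  expect_error(GrayscaleVolume(array(c(1, NA, 1, 1), c(2, 2, 1)), c(1, 1, 1)),
               "finite")
})
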