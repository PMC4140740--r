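test_that("the truncated kernel is renormalised: constants are preserved", {
  vol <- GrayscaleVolume(array(3.7, c(6, 6, 6)), rep(0.1, 3))
  f <- gaussianFilterVolume(vol, sigma = 1.2, support = 1)
  expect_equal(voxelData(f), voxelData(vol), tolerance = 1e-12)
})

test_that("impulse response equals the renormalised 3^3 kernel", {
  arr <- array(0, c(7, 7, 7)); arr[4, 4, 4] <- 1
  f <- gaussianFilterVolume(GrayscaleVolume(arr, rep(1, 3)),
                            sigma = 1.2, support = 1)
  w1 <- exp(-(-1:1)^2 / (2 * 1.2^2)); w1 <- w1 / sum(w1)
  kern <- outer(outer(w1, w1), w1)
  expect_equal(voxelData(f)[3:5, 3:5, 3:5], kern, tolerance = 1e-12)
  expect_equal(sum(voxelData(f)), 1, tolerance = 1e-12)
  expect_equal(voxelData(f)[4, 4, 4], kern[2, 2, 2], tolerance = 1e-12)
})

test_that("separable filtering matches brute-force convolution, twice too", {
  set.seed(42)
  arr <- array(rnorm(9 * 8 * 7), c(9, 8, 7))
  vol <- GrayscaleVolume(arr, rep(1, 3))
  once <- gaussianFilterVolume(vol, 1.2, 1)
  expect_equal(voxelData(once), brute_gauss3(arr, 1.2, 1), tolerance = 1e-12)
  twice <- gaussianFilterVolume(once, 1.2, 1)
  expect_equal(voxelData(twice), brute_gauss3(brute_gauss3(arr, 1.2, 1),
                                              1.2, 1),
               tolerance = 1e-12)
})

test_that("filtering never leaves the input value range", {
  set.seed(1)
  arr <- array(rnorm(1000), c(10, 10, 10))
  f <- gaussianFilterVolume(GrayscaleVolume(arr, rep(1, 3)), 0.8, 2)
  expect_gte(min(voxelData(f)), min(arr) - 1e-12)
  expect_lte(max(voxelData(f)), max(arr) + 1e-12)
})

test_that("filter parameter validation", {
  vol <- GrayscaleVolume(array(0, c(3, 3, 3)), rep(1, 3))
  expect_error(gaussianFilterVolume(vol, sigma = 0), "sigma")
  expect_error(gaussianFilterVolume(vol, sigma = 1, support = 0), "support")
  expect_error(attenuationThreshold(vol, 2.2, 0.9), "lo must be <")
})

test_that("the attenuation window is closed on both ends", {
  vol <- GrayscaleVolume(array(c(0.8, 0.9, 2.2, 2.3, 1.5, 0.2, 3, 0.89),
                               c(2, 2, 2)), rep(1, 3))
  m <- attenuationThreshold(vol, 0.9, 2.2)
  expect_identical(as.vector(voxelData(m)),
                   c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  lo <- attenuationThreshold(GrayscaleVolume(array(0.2, c(3, 3, 3)),
                                             rep(1, 3)), 0.9, 2.2)
  expect_false(any(voxelData(lo)))
  hi <- attenuationThreshold(GrayscaleVolume(array(1.5, c(3, 3, 3)),
                                             rep(1, 3)), 0.9, 2.2)
  expect_true(all(voxelData(hi)))
})

test_that("segmentation is invariant to offsets only with shifted windows", {
  set.seed(3)
  arr <- array(runif(512, 0, 3), c(8, 8, 8))
  vol <- GrayscaleVolume(arr, rep(1, 3))
  shifted <- GrayscaleVolume(arr + 0.5, rep(1, 3))
  m0 <- segmentCT(vol, ctParams())
  m_shift <- segmentCT(shifted, ctParams(atten_lo = 1.4, atten_hi = 2.7))
  expect_identical(voxelData(m0), voxelData(m_shift))
  m_same <- segmentCT(shifted, ctParams())
  expect_false(identical(voxelData(m0), voxelData(m_same)))
})

test_that("noisy phantom CT is segmented to within 3 percent volume", {
  ph <- makePhantom(phantomSpec("spherical_shell", thickness = 1,
                                r_inner = 4), 0.1)
  ct <- emulateCT(ph, rep(0.1, 3), cartilage_atten = 1.5,
                  background_atten = 0.2, noise_sd = 0.1, seed = 7)
  m <- segmentCT(ct, ctParams())
  v <- cartilageVolume(m)
  expect_lt(abs(v - ph@truth$cg_v) / ph@truth$cg_v, 0.03)
})

test_that("attenuation above the window is rejected by the chain", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(5, 5)), 0.15)
  ct <- emulateCT(ph, rep(0.15, 3), cartilage_atten = 2.5,
                  background_atten = 0.2, noise_sd = 0)
  # partial-volume and filter smearing drag boundary values through the
  # window, so only a thin ring at the boundary can survive: the object
  # interior must never be segmented
  m2 <- segmentCT(ct, ctParams())
  seg <- voxelData(m2)
  d_bg <- auriMorph:::cpp_edt(!voxelData(ph@grid), dim(ph@grid),
                              voxelSpacing(ph@grid))
  expect_false(any(seg & d_bg > 0.4))
  expect_lt(cartilageVolume(m2), ph@truth$cg_v)
})

test_that("noise-free segmentation differs only in a 1-voxel shell", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(6, 6)), 0.1)
  ct <- emulateCT(ph, rep(0.1, 3), noise_sd = 0)
  m <- segmentCT(ct, ctParams())
  ideal <- voxelData(ph@grid)
  got <- voxelData(m)
  expect_identical(dim(got), dim(ideal))
  changed <- got != ideal
  d_in <- auriMorph:::cpp_edt(ideal, dim(ideal), rep(0.1, 3))
  d_out <- auriMorph:::cpp_edt(!ideal, dim(ideal), rep(0.1, 3))
  shell <- pmin(d_in, d_out) <= 0.1 + 1e-9
  expect_true(all(shell[changed]))
})

test_that("misclassification grows monotonically with noise", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(6, 6)), 0.15)
  ideal <- voxelData(ph@grid)
  err <- sapply(c(0.05, 0.25, 0.6), function(s) {
    ct <- emulateCT(ph, rep(0.15, 3), noise_sd = s, seed = 11)
    sum(voxelData(segmentCT(ct, ctParams())) != ideal)
  })
  expect_true(all(diff(err) > 0))
})

test_that("largest-component selection keeps the bigger blob", {
  arr <- array(FALSE, c(12, 6, 6))
  arr[2:5, 2:4, 2:4] <- TRUE     # 36 voxels
  arr[8:10, 2:3, 2:3] <- TRUE    # 12 voxels, disconnected
  vol <- GrayscaleVolume(arr * 1.5 + (!arr) * 0.2, rep(1, 3))
  m1 <- segmentCT(vol, ctParams(sigma = 0.2))
  expect_equal(sum(voxelData(m1)), 48)
  m2 <- segmentCT(vol, ctParams(sigma = 0.2, keep_largest_component = TRUE))
  expect_equal(sum(voxelData(m2)), 36)
  expect_true(all(which(voxelData(m2)) %in% which(arr)))
})

test_that("segmentCT writes the mask with a provenance sidecar", {
  vol <- GrayscaleVolume(array(c(1.5, 0.2), c(4, 4, 4)), rep(1, 3))
  p <- file.path(tempdir(), "seg.nii.gz")
  m <- segmentCT(vol, ctParams(), out_path = p)
  expect_true(file.exists(p))
  side <- jsonlite::read_json(paste0(p, ".params.json"),
                              simplifyVector = TRUE)
  expect_equal(side$sigma, 1.2)
  expect_equal(side$atten_hi_per_cm, 2.2)
  expect_identical(voxelData(readVolume(p)), voxelData(m))
})
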