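test_that("phantom truth: closed forms for slab and shell", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(30, 30)), 0.2)
  expect_equal(ph@truth$cg_v, 1080)
  expect_equal(ph@truth$cg_s, 2 * (900 + 36 + 36))
  expect_equal(ph@truth$cg_th, 1.2)
  expect_identical(ph@truth$method, "closed_form")
  expect_lt(abs(cartilageVolume(ph@grid) - 1080) / 1080, 0.01)

  sh <- makePhantom(phantomSpec("spherical_shell", thickness = 1,
                                r_inner = 8), 0.2)
  expect_equal(sh@truth$cg_v, 4 / 3 * pi * (9^3 - 8^3))
  expect_equal(sh@truth$cg_s, 4 * pi * (9^2 + 8^2))
})

test_that("bent-sheet truth is quadrature-based and consistent", {
  spec <- phantomSpec("bent_sheet", thickness = 1.15,
                      modulation = list(amplitude = 0.2, length_scale = 6))
  ph <- makePhantom(spec, 0.1, seed = 3)
  expect_identical(ph@truth$method, "quadrature")
  # rasterised volume close to the quadrature volume
  expect_lt(abs(cartilageVolume(ph@grid) - ph@truth$cg_v) / ph@truth$cg_v,
            0.02)
  # without modulation the numerical truth approaches the cylinder-sector
  # closed forms
  spec0 <- phantomSpec("bent_sheet", thickness = 1.15)
  t0 <- makePhantom(spec0, 0.15)@truth
  expect_equal(t0$cg_v, 20 * 24 * 1.15, tolerance = 1e-3)
  expect_equal(t0$cg_th, 1.15, tolerance = 1e-6)
})

test_that("slab-limit layer relation: V / ((S/2) Th) tends to 1", {
  ratio <- sapply(c(10, 30, 100, 300), function(L) {
    tr <- auriMorph:::.phantom_truth(
      phantomSpec("slab", thickness = 1.2, lateral_extent = c(L, L)))
    tr$cg_v / ((tr$cg_s / 2) * tr$cg_th)
  })
  expect_true(all(diff(abs(ratio - 1)) < 0))
  expect_lt(abs(ratio[4] - 1), 0.01)
})

test_that("too-coarse rasterisation is refused with the required spacing", {
  expect_error(makePhantom(phantomSpec("slab", thickness = 0.2,
                                       lateral_extent = c(10, 10)), 0.45),
               "spacing too coarse")
})

test_that("a null rater reproduces the phantom mask exactly", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(8, 8)), 0.15)
  out <- simulateRater(ph, raterModel(bias = 0, noise_amplitude = 0))
  expect_identical(voxelData(out), voxelData(ph@grid))
  # VoxelGrid input path too
  out2 <- simulateRater(ph@grid, raterModel(bias = 0, noise_amplitude = 0))
  expect_identical(voxelData(out2), voxelData(ph@grid))
})

test_that("a +1 voxel bias thickens a slab by two voxel sizes", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(20, 20)), 0.1)
  g <- simulateRater(ph, raterModel(bias = 1, noise_amplitude = 0,
                                    voxel_mm = 0.1))
  d_th <- meanThickness(thicknessMap(g)) - meanThickness(thicknessMap(ph@grid))
  expect_equal(d_th, 0.2, tolerance = 0.03 / 0.2)
})

test_that("rater masks are deterministic given the seed", {
  ph <- makePhantom(phantomSpec("bent_sheet", thickness = 1.15), 0.12)
  m <- raterModel(bias = 0.1, noise_amplitude = 0.4, seed = 77)
  a <- simulateRater(ph, m)
  b <- simulateRater(ph, m)
  expect_identical(voxelData(a), voxelData(b))
  m2 <- m; m2@seed <- 78L
  expect_false(identical(voxelData(simulateRater(ph, m2)), voxelData(a)))
})

test_that("zero-bias symmetric noise leaves the volume unbiased", {
  # short correlation length so that per-seed volume fluctuations average
  # out over a modest number of seeds
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(15, 15)), 0.1)
  v0 <- cartilageVolume(ph@grid)
  vols <- sapply(1:40, function(s)
    cartilageVolume(simulateRater(ph, raterModel(bias = 0,
                                                 noise_amplitude = 0.25,
                                                 noise_length_scale = 3,
                                                 seed = 100 + s))))
  expect_lt(abs(mean(vols) - v0) / v0, 0.01)
})

test_that("larger perturbation amplitude raises thickness variability", {
  ph <- makePhantom(phantomSpec("slab", thickness = 1.2,
                                lateral_extent = c(10, 10)), 0.15)
  th_at <- function(amp) sapply(1:10, function(s)
    meanThickness(thicknessMap(simulateRater(
      ph, raterModel(bias = 0, noise_amplitude = amp, seed = 200 + s)))))
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(th_at(0.5)), cv(th_at(0.25)))
})

test_that("the synthetic cohort has the full 14 x 3 design", {
  pop <- populationSpec(n_subjects = 14L, seed = 2L)
  raters <- defaultRaters(2L)
  # generation only; morphometry of the cohort is exercised elsewhere
  cohort <- simulatePopulation(pop, raters)
  expect_identical(nrow(cohort$manifest), 42L)
  expect_identical(length(cohort$masks), 14L)
  expect_true(all(vapply(cohort$masks, length, 1L) == 3L))
  expect_identical(nrow(cohort$truth), 14L)
  # stratified population moments: thickness SD is the specified 0.10 up
  # to the deterministic quantile shrinkage
  expect_equal(sd(cohort$truth$thickness_mm), 0.0985, tolerance = 0.05)
  expect_equal(mean(cohort$truth$thickness_mm), 1.15, tolerance = 1e-6)
  # deterministic regeneration
  again <- simulatePopulation(pop, raters)
  s <- cohort$manifest$subject_id[7]; r <- cohort$manifest$rater_id[7]
  expect_identical(voxelData(again$masks[[s]][[r]]),
                   voxelData(cohort$masks[[s]][[r]]))
  expect_error(simulatePopulation(pop, list()), "empty")
})

test_that("CT emulation: interior value, determinism, partial volume", {
  ph <- makePhantom(phantomSpec("spherical_shell", thickness = 1.2,
                                r_inner = 3), 0.1)
  ct <- emulateCT(ph, rep(0.1, 3), cartilage_atten = 1.5,
                  background_atten = 0.2, noise_sd = 0, seed = 5)
  vals <- voxelData(ct)
  # interior voxels at the cartilage attenuation, background at background
  expect_equal(max(vals), 1.5, tolerance = 1e-9)
  expect_equal(min(vals), 0.2, tolerance = 1e-9)
  # the curved boundary produces partial-volume voxels strictly in between
  expect_true(any(vals > 0.3 & vals < 1.4))
  ct2 <- emulateCT(ph, rep(0.1, 3), noise_sd = 0.1, seed = 5)
  ct3 <- emulateCT(ph, rep(0.1, 3), noise_sd = 0.1, seed = 5)
  expect_identical(voxelData(ct2), voxelData(ct3))
  expect_error(emulateCT(ph, rep(0.1, 3), cartilage_atten = 7),
               "attenuation")
})

test_that("accuracy specimens carry both chains and stratified truth", {
  specs <- simulateAccuracySpecimens(
    n = 3, seed = 9,
    geometry = list(arc_length = 8, axial_length = 8, bend_radius = 12,
                    mod_amplitude = 0.15, mod_length = 5))
  expect_length(specs, 3)
  for (sp in specs) {
    expect_s4_class(sp$mri_mask, "VoxelGrid")
    expect_s4_class(sp$ct, "GrayscaleVolume")
    expect_equal(voxelSpacing(sp$mri_mask), c(0.09, 0.45, 0.08))
    expect_equal(voxelSpacing(sp$ct), rep(0.1, 3))
  }
  th <- vapply(specs, function(s) s$truth$cg_th, 1)
  expect_gt(sd(th), 0)
})
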