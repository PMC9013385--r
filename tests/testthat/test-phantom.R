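test_that("phantom generation is a pure function of its spec", {
  ph1 <- generate_phantom(tiny_phantom_spec(seed = 7))
  ph2 <- generate_phantom(tiny_phantom_spec(seed = 7))
  expect_identical(ph1$image$voxels, ph2$image$voxels)
  expect_identical(ph1$labels$masks, ph2$labels$masks)
  ph3 <- generate_phantom(tiny_phantom_spec(seed = 8))
  expect_false(identical(ph1$image$voxels, ph3$image$voxels))
})

test_that("lobes partition the whole-liver mask by construction", {
  ph <- generate_phantom(tiny_phantom_spec())
  m <- ph$labels$masks
  s <- m$left_lobe + m$right_lobe + m$caudate_lobe
  expect_true(all(s <= 1))               # pairwise disjoint
  expect_identical(s, m$whole)           # union equals whole
  expect_gt(sum(m$caudate_lobe), 0)
  expect_gt(sum(m$right_lobe), sum(m$caudate_lobe))
})

test_that("voxelised volume matches the analytic ellipsoid volume at 1 mm", {
  spec <- iso_phantom_spec()
  ph <- generate_phantom(spec)
  vox_mL <- mask_volume(ph$labels, "whole")
  analytic_mL <- (4 / 3) * pi *
    (prod(spec$liver_semi_axes) + prod(spec$caudate_semi_axes)) / 1000
  expect_lt(abs(vox_mL - analytic_mL) / analytic_mL, 0.05)
})

test_that("mask volume scales cubically with the semi-axes", {
  base <- phantom_spec(shape = c(40L, 56L, 60L), spacing = c(1, 1, 1),
                       liver_semi_axes = c(7, 9, 10),
                       lobe_plane = list(normal = c(0, 0, 1), offset_mm = 3),
                       caudate_semi_axes = c(3, 3, 3),
                       caudate_center = c(20.5, 43, 24), seed = 2)
  doubled <- phantom_spec(shape = c(40L, 56L, 60L), spacing = c(1, 1, 1),
                          liver_semi_axes = 2 * c(7, 9, 10),
                          lobe_plane = list(normal = c(0, 0, 1), offset_mm = 6),
                          caudate_semi_axes = 2 * c(3, 3, 3),
                          caudate_center = c(20.5, 50, 24), seed = 2)
  v1 <- mask_volume(generate_phantom(base)$labels, "whole")
  v2 <- mask_volume(generate_phantom(doubled)$labels, "whole")
  expect_lt(abs(v2 / v1 - 8) / 8, 0.05)
})

test_that("mean intensity inside the liver approaches liver_hu as noise vanishes", {
  spec0 <- tiny_phantom_spec()
  spec0$noise_sd <- 0
  ph0 <- generate_phantom(spec0)
  inside <- ph0$image$voxels[ph0$labels$masks$whole == 1]
  outside <- ph0$image$voxels[ph0$labels$masks$whole == 0]
  expect_equal(unique(inside), spec0$liver_hu)
  expect_equal(unique(outside), spec0$background_hu)
  ph15 <- generate_phantom(tiny_phantom_spec())
  expect_lt(abs(mean(ph15$image$voxels[ph15$labels$masks$whole == 1]) - 60), 1)
})

test_that("a caudate crossing the lobe plane into the left half-space is refused", {
  spec <- tiny_phantom_spec()
  # move the caudate to the far left (high column index = left half-space side)
  spec$caudate_center <- spec$liver_center + c(0, 0, 30)
  expect_error(generate_phantom(spec), "left-lobe half-space")
})

test_that("spec validation enforces the small-caudate and noise invariants", {
  expect_error(phantom_spec(caudate_semi_axes = c(40, 50, 60)), "small")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("cohorts are reproducible, jittered and distinct", {
  base <- tiny_phantom_spec()
  co1 <- generate_cohort(4, base, seed = 31)
  co2 <- generate_cohort(4, base, seed = 31)
  expect_identical(lapply(co1, function(x) x$image$voxels),
                   lapply(co2, function(x) x$image$voxels))
  vox <- lapply(co1, function(x) x$image$voxels)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(identical(vox[[i]], vox[[j]]))
  }
  zero <- list(size_frac = 0, center_mm = 0, noise_frac = 0)
  co0 <- generate_cohort(1, base, jitter = zero, seed = 31)
  solo <- generate_phantom(co0[[1]]$spec)
  expect_identical(co0[[1]]$image$voxels, solo$image$voxels)
  expect_equal(co0[[1]]$spec$liver_semi_axes, base$liver_semi_axes)
  expect_error(generate_cohort(0, base), ">= 1")
})

test_that("a written cohort produces a manifest io_ct can consume", {
  d <- withr::local_tempdir()
  co <- generate_cohort(2, tiny_phantom_spec(), seed = 5)
  manifest <- write_phantom_cohort(co, d)
  m <- read_manifest(manifest)
  expect_equal(nrow(m), 2)
  v <- read_volume(m$image_path[1])
  expect_equal(v$voxels, co[[1]]$image$voxels, tolerance = 1e-5)
  lab <- read_mask(m$mask_path[2])
  expect_equal(lab$masks$whole, co[[2]]$labels$masks$whole, ignore_attr = TRUE)
})
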