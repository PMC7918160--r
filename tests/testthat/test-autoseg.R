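## noiseless phantom helpers shared across the auto-segmentation tests
flat_image <- function(grid, value = 1) {
  SUVImage(grid, array(value, dim = gridShape(grid)))
}

test_that("backgroundSUV averages voxels whose centers fall in the ROI", {
  g <- ImageGrid(c(20, 20, 20))
  expect_equal(backgroundSUV(flat_image(g), backgroundROI("sphere", c(9, 9, 9), 3)), 1)

  ## box ROI covering exactly one 3-voxel column with known values
  vals <- array(5, c(20, 20, 20))
  vals[9:11, 10, 10] <- c(1, 2, 3)
  ## need >= 10 voxels: use a wider box and place known values across it
  vals2 <- array(0, c(20, 20, 20))
  vals2[8:12, 9:11, 9:11] <- 2
  img2 <- SUVImage(g, vals2)
  roi <- backgroundROI("box", c(9, 9, 9), c(2, 1, 1))
  expect_equal(backgroundSUV(img2, roi), 2)

  ## noisy phantom background recovered within a few standard errors
  set.seed(99)
  noisy <- SUVImage(g, array(pmax(rnorm(8000, 1, 0.05), 0), c(20, 20, 20)))
  b <- backgroundSUV(noisy, backgroundROI("sphere", c(9, 9, 9), 5))
  expect_lt(abs(b - 1), 0.05)
})

test_that("degenerate background ROIs are rejected", {
  g <- ImageGrid(c(20, 20, 20))
  img <- flat_image(g)
  expect_error(backgroundSUV(img, backgroundROI("sphere", c(40, 9, 9), 3)),
               class = "roiOutsideGridError")
  expect_error(backgroundSUV(img, backgroundROI("sphere", c(9, 9, 9), 1)),
               class = "degenerateBackgroundError")
  zero <- SUVImage(g, array(0, c(20, 20, 20)))
  expect_error(backgroundSUV(zero, backgroundROI("sphere", c(9, 9, 9), 3)),
               class = "degenerateBackgroundError")
})

test_that("thresholdGTV recovers a hard-edged sphere exactly", {
  g <- ImageGrid(c(30, 30, 30))
  ctr <- c(14, 14, 14); r <- 6
  sph <- voxelizeSphere(g, ctr, r)
  vals <- array(1, c(30, 30, 30)); vals[maskVoxels(sph)] <- 3
  img <- SUVImage(g, vals)
  spec <- thresholdSpec(1, min_component_ccm = 0)
  got <- thresholdGTV(img, spec, 2)
  expect_identical(maskVoxels(got), maskVoxels(sph))
  ## threshold is inclusive: voxels exactly at m*b are kept
  vals2 <- array(1, c(30, 30, 30)); vals2[maskVoxels(sph)] <- 2
  expect_identical(maskVoxels(thresholdGTV(SUVImage(g, vals2), spec, 2)),
                   maskVoxels(sph))
  ## nothing exceeds the threshold: empty mask, not an error
  vals3 <- array(1, c(30, 30, 30)); vals3[maskVoxels(sph)] <- 1.8
  expect_equal(sum(maskVoxels(thresholdGTV(SUVImage(g, vals3), spec, 2))), 0)
})

test_that("threshold masks are nested and volumes non-increasing in multiplier", {
  ps <- phantomSpec(noise_sd = 0.1)
  ph <- generatePhantom(ps, 7)
  b <- backgroundSUV(ph$suv, backgroundROI("sphere", c(20, 20, 20), 6))
  gtvs <- generateFapiGTVs(ph$suv, NULL, thresholdSpec(b))
  expect_length(gtvs, 3)
  v <- vapply(gtvs, volumeCcm, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_true(all(maskVoxels(gtvs[["2.5"]]) <= maskVoxels(gtvs[["2"]])))
  expect_true(all(maskVoxels(gtvs[["2"]]) <= maskVoxels(gtvs[["1.5"]])))
})

test_that("noiseless Gaussian lesion matches the analytic threshold radius", {
  ## 1 mm isotropic grid, B = 1, P = 9, sigma = 10 mm
  g <- ImageGrid(c(72, 72, 72))
  ctr <- c(35.5, 35.5, 35.5)
  ps <- phantomSpec(pet_grid = g, noise_sd = 0,
                    lesions = list(list(center = ctr, sigma_mm = 10, peak = 9)))
  ph <- generatePhantom(ps, 1)
  spec <- thresholdSpec(1)
  for (m in c(1.5, 2, 2.5)) {
    r_m <- analyticThresholdRadius(1, 9, 10, m)
    v_analytic <- 4 / 3 * pi * r_m^3 / 1000
    mask <- thresholdGTV(ph$suv, spec, m)
    expect_lt(abs(volumeCcm(mask) - v_analytic) / v_analytic, 0.05)
    ## and the mask is exactly the voxelized analytic sphere
    expect_identical(maskVoxels(mask), maskVoxels(voxelizeSphere(g, ctr, r_m)))
  }
})

test_that("image scaling leaves threshold masks unchanged", {
  ps <- phantomSpec(noise_sd = 0.05)
  ph <- generatePhantom(ps, 3)
  roi <- backgroundROI("sphere", c(20, 20, 20), 6)
  gtvs1 <- generateFapiGTVs(ph$suv, roi, thresholdSpec(1))
  scaled <- SUVImage(imageGrid(ph$suv), suvValues(ph$suv) * 3.7)
  gtvs2 <- generateFapiGTVs(scaled, roi, thresholdSpec(1))
  for (m in names(gtvs1))
    expect_identical(maskVoxels(gtvs1[[m]]), maskVoxels(gtvs2[[m]]))
})

test_that("small components are removed and search regions restrict output", {
  g <- ImageGrid(c(30, 30, 30))
  vals <- array(1, c(30, 30, 30))
  main <- voxelizeSphere(g, c(10, 10, 10), 5)
  vals[maskVoxels(main)] <- 3
  vals[25, 25, 25] <- 3                       # single-voxel noise component
  img <- SUVImage(g, vals)
  got <- thresholdGTV(img, thresholdSpec(1), 2)   # default min 0.1 ccm
  expect_identical(maskVoxels(got), maskVoxels(main))
  keep_all <- thresholdGTV(img, thresholdSpec(1, min_component_ccm = 0), 2)
  expect_equal(sum(maskVoxels(keep_all)), sum(maskVoxels(main)) + 1)
  ## search region excluding the main lesion removes it
  region <- voxelizeSphere(g, c(25, 25, 25), 4)
  got2 <- thresholdGTV(img, thresholdSpec(1, min_component_ccm = 0,
                                          search_region = region), 2)
  expect_identical(which(maskVoxels(got2)), which(vals == 3 & !maskVoxels(main)))
})

test_that("edits operate on 26-connected components and are idempotent", {
  g <- ImageGrid(c(30, 30, 30))
  a <- voxelizeSphere(g, c(8, 8, 8), 4)
  b <- voxelizeSphere(g, c(22, 22, 22), 4)
  both <- BinaryMask(g, maskVoxels(a) | maskVoxels(b))

  expect_identical(maskVoxels(applyEdits(both, editList())), maskVoxels(both))

  rm_b <- editList(list(op = "remove_component", seed = c(22, 22, 22)))
  edited <- applyEdits(both, rm_b)
  expect_identical(maskVoxels(edited), maskVoxels(a))
  ## idempotent: the second application is a warned no-op
  expect_warning(twice <- applyEdits(edited, rm_b), "no component")
  expect_identical(maskVoxels(twice), maskVoxels(edited))

  only_a <- applyEdits(a, editList(list(op = "remove_component", seed = c(8, 8, 8))))
  expect_equal(sum(maskVoxels(only_a)), 0)

  add_b <- editList(list(op = "add_component", seed = c(22, 22, 22), donor = both))
  expect_identical(maskVoxels(applyEdits(a, add_b)), maskVoxels(both))

  sub <- editList(list(op = "subtract_mask", mask = b))
  expect_identical(maskVoxels(applyEdits(both, sub)), maskVoxels(a))

  expect_warning(applyEdits(a, editList(list(op = "remove_component",
                                             seed = c(28, 28, 28)))), "no component")
  ## a removed satellite stays absent from every threshold mask
  vals <- array(1, c(30, 30, 30))
  vals[maskVoxels(a)] <- 4; vals[maskVoxels(b)] <- 4
  gtvs <- generateFapiGTVs(SUVImage(g, vals), NULL, thresholdSpec(1), edits = rm_b)
  for (m in names(gtvs))
    expect_equal(sum(maskVoxels(gtvs[[m]]) & maskVoxels(b)), 0)
})

test_that("26-connectivity joins diagonal neighbours into one component", {
  g <- ImageGrid(c(4, 4, 4))
  v <- array(FALSE, c(4, 4, 4)); v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE
  lab <- connectedComponents(BinaryMask(g, v))
  expect_equal(max(lab), 1)
  v[4, 4, 4] <- TRUE
  expect_equal(max(connectedComponents(BinaryMask(g, v))), 2)
})
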