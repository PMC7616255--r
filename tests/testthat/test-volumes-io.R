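# NIfTI round-trips, cube extraction geometry and paste-back contracts.

make_nifti_pair <- function(img, msk, spacing = c(1, 1, 1)) {
  ip <- tempfile(fileext = ".nii.gz")
  mp <- tempfile(fileext = ".nii.gz")
  write_volume_pair(volume_pair(img, msk, spacing), ip, mp)
  c(ip, mp)
}

test_that("NIfTI pairs round-trip with binarized masks", {
  set.seed(701)
  img <- array(runif(16^3, 0, 100), rep(16, 3))
  msk <- array(0L, rep(16, 3)); msk[5:8, 6:9, 7:10] <- 1L
  paths <- make_nifti_pair(img, msk)
  pair <- load_volume_pair(paths[1], paths[2])
  expect_equal(pair$image, img, tolerance = 1e-6)
  expect_identical(pair$mask, msk)
  expect_equal(pair$voxel_spacing, c(1, 1, 1))
  # mask stored with values {0, 255} still binarizes to {0, 1}
  m255 <- msk * 255L
  paths <- make_nifti_pair(img, m255)
  # write raw 255 values directly (volume_pair would binarize them first)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(m255), dim(m255))), paths[2])
  pair <- load_volume_pair(paths[1], paths[2])
  expect_identical(sort(unique(as.vector(pair$mask))), c(0L, 1L))
  expect_identical(pair$mask, msk)
})

test_that("shape mismatch and non-3D inputs are rejected with named shapes", {
  img <- array(runif(16^3), rep(16, 3))
  msk <- array(0L, rep(8, 3)); msk[2:3, 2:3, 2:3] <- 1L
  ip <- tempfile(fileext = ".nii.gz"); mp <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), ip)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(msk), dim(msk))), mp)
  expect_error(load_volume_pair(ip, mp), "16x16x16.*8x8x8")
  expect_error(volume_pair(img, msk), "mismatch")
})

test_that("extract_cube centres on the foreground centroid and normalizes", {
  img <- array(runif(32^3, 10, 90), rep(32, 3))
  msk <- array(0L, rep(32, 3))
  msk[11, 11, 11] <- 1L  # voxel (10,10,10) 0-based
  pair <- volume_pair(img, msk)
  rec <- extract_cube(pair, side = 16)
  expect_identical(rec$origin, rep(2L, 3L))       # 10 - 16/2
  expect_true(all(rec$cube >= 0 & rec$cube <= 1))
  expect_equal(min(rec$cube), 0); expect_equal(max(rec$cube), 1)
  expect_equal(sum(rec$mask), 1L)
  # normalization inverts within float tolerance
  den <- denormalize_cube(rec$cube, rec$intensity_window)
  expect_equal(den[9, 9, 9], img[11, 11, 11], tolerance = 1e-12)
  # all foreground voxels of the source are contained in the cube
  spec <- phantom_spec(side = 32, volume_range = c(100, 600), seed = 2)
  m2 <- generate_mask(spec)
  rec2 <- extract_cube(volume_pair(img, m2), side = 24)
  expect_equal(sum(rec2$mask), sum(m2))
})

test_that("extract_cube zero-pads at borders and flags bad inputs", {
  img <- array(runif(16^3, 5, 6), rep(16, 3))
  msk <- array(0L, rep(16, 3)); msk[1:2, 1:2, 1:2] <- 1L
  rec <- extract_cube(volume_pair(img, msk), side = 12)
  expect_equal(sum(rec$mask), 8L)             # foreground retained
  expect_true(any(rec$cube == 0))             # zero padding present
  expect_error(extract_cube(volume_pair(img, array(0L, rep(16, 3)))), "empty")
  wide <- array(0L, rep(16, 3)); wide[1, 1, 1] <- 1L; wide[16, 1, 1] <- 1L
  expect_error(extract_cube(volume_pair(img, wide), side = 8), "side >= 16")
  # constant image: degenerate window maps to all zeros
  cimg <- array(5, rep(16, 3))
  cmsk <- array(0L, rep(16, 3)); cmsk[8:9, 8:9, 8:9] <- 1L
  rec <- extract_cube(volume_pair(cimg, cmsk), side = 8)
  expect_true(all(rec$cube == 0))
})

test_that("paste_cube honours no-op, hard replacement and round-trip contracts", {
  set.seed(702)
  img <- array(runif(24^3, 10, 50), rep(24, 3))
  msk <- array(0L, rep(24, 3)); msk[10:14, 10:14, 10:14] <- 1L
  pair <- volume_pair(img, msk)
  rec <- extract_cube(pair, side = 12)
  # empty new mask: volume untouched
  out <- paste_cube(pair, rec, array(0.5, rep(12, 3)), array(0L, rep(12, 3)))
  expect_identical(out$image, pair$image)
  # blend_sigma = 0, all-ones mask: cube region exactly replaced
  newc <- array(runif(12^3), rep(12, 3))
  out <- paste_cube(pair, rec, newc, array(1L, rep(12, 3)), blend_sigma = 0)
  o <- rec$origin
  got <- out$image[(o[1] + 1):(o[1] + 12), (o[2] + 1):(o[2] + 12), (o[3] + 1):(o[3] + 12)]
  expect_equal(got, denormalize_cube(newc, rec$intensity_window), tolerance = 1e-12)
  # paste then re-extract with the unchanged cube reproduces the original
  out <- paste_cube(pair, rec, rec$cube, rec$mask, blend_sigma = 0)
  expect_equal(out$image, pair$image, tolerance = 1e-12)
  expect_error(paste_cube(pair, list(cube = rec$cube, origin = c(50L, 0L, 0L),
                                     intensity_window = rec$intensity_window),
                          newc, array(1L, rep(12, 3))), "out of bounds")
})
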