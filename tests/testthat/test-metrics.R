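# Image-quality and mask-agreement metrics against closed forms,
# brute-force evaluation, and the scikit-image SSIM reference.

test_that("PSNR matches closed forms and brute-force evaluation", {
  set.seed(601)
  x <- array(runif(8^3), rep(8, 3))
  expect_identical(psnr(x, x), Inf)
  y <- x + 0.1  # constant offset: PSNR = 20*log10(1/0.1)
  expect_equal(psnr(x, y), 20, tolerance = 1e-12)
  z <- array(runif(8^3), rep(8, 3))
  brute <- 10 * log10(1 / (sum((x - z)^2) / length(x)))
  expect_equal(psnr(x, z), brute, tolerance = 1e-9)
  expect_error(psnr(x, array(0, rep(4, 3))), "mismatch")
})

test_that("NMSE matches its definition in percent", {
  set.seed(602)
  x <- array(runif(8^3), rep(8, 3))
  expect_equal(nmse(x, x), 0)
  expect_equal(nmse(array(0, dim(x)), x), 100)
  g <- array(runif(8^3), rep(8, 3))
  brute <- 100 * sum((g - x)^2) / sum(x^2)
  expect_equal(nmse(g, x), brute, tolerance = 1e-9)
  expect_error(nmse(g, array(0, dim(x))), "all-zero")
})

test_that("3D SSIM satisfies identity/dissimilarity and matches scikit-image", {
  set.seed(603)
  x <- array(runif(16^3), rep(16, 3))
  expect_equal(ssim3d(x, x), 1, tolerance = 1e-12)
  expect_lt(ssim3d(x, 1 - x), 1)
  expect_error(ssim3d(x, x, window = 17), "window")
  # reference implementation (scikit-image, Gaussian weights, sigma 1.5)
  y <- pmin(pmax(x + 0.1 * array(rnorm(16^3), rep(16, 3)), 0), 1)
  xf <- tempfile(); yf <- tempfile(); rf <- tempfile()
  writeLines(sprintf("%.17g", as.vector(x)), xf)
  writeLines(sprintf("%.17g", as.vector(y)), yf)
  script <- paste(
    "import numpy as np, sys",
    "from skimage.metrics import structural_similarity",
    sprintf("x = np.loadtxt(%s).reshape((16,16,16), order='F')", shQuote(xf)),
    sprintf("y = np.loadtxt(%s).reshape((16,16,16), order='F')", shQuote(yf)),
    "s = structural_similarity(x, y, gaussian_weights=True, sigma=1.5, data_range=1.0)",
    sprintf("open(%s,'w').write('%%.15f' %% s)", shQuote(rf)), sep = "\n")
  status <- system2("python", c("-c", shQuote(script)))
  skip_if(status != 0, "python/scikit-image unavailable")
  ref <- as.numeric(readLines(rf, warn = FALSE))
  expect_equal(ssim3d(x, y, window = 11), ref, tolerance = 1e-6)
})

test_that("mask agreement matches hand-computed cases", {
  d <- rep(12L, 3L)
  a <- array(0L, d); a[3:6, 3:6, 3:6] <- 1L
  r <- mask_agreement(a, a)
  expect_equal(r$dice, 1); expect_equal(r$jaccard, 1)
  expect_equal(r$asd, 0); expect_equal(r$hd95, 0)
  # two single-voxel masks 4 voxels apart: dice 0, all distances 4
  p <- array(0L, d); p[2, 2, 2] <- 1L
  q <- array(0L, d); q[6, 2, 2] <- 1L
  r <- mask_agreement(p, q)
  expect_equal(r$dice, 0)
  expect_equal(r$asd, 4)
  expect_equal(r$hd95, 4)
  # a contained in b with |a| = |b|/2: dice = 2|a|/(|a|+2|a|) = 2/3
  b <- array(0L, d); b[1:4, 1:4, 1:2] <- 1L     # 32 voxels
  s <- array(0L, d); s[1:4, 1:4, 1] <- 1L       # 16 voxels
  r <- mask_agreement(s, b)
  expect_equal(r$dice, 2 / 3)
  expect_equal(r$jaccard, 0.5)
  # empty-mask sentinels
  e <- array(0L, d)
  expect_equal(mask_agreement(e, e)$dice, 1)
  r <- mask_agreement(e, b)
  expect_equal(r$dice, 0)
  expect_true(is.na(r$asd))
  # anisotropic spacing scales distances
  r <- mask_agreement(p, q, spacing = c(0.5, 1, 1))
  expect_equal(r$asd, 2)
})

test_that("metrics degrade monotonically with increasing noise", {
  set.seed(604)
  x <- array(runif(16^3, 0.2, 0.8), rep(16, 3))
  noise <- array(rnorm(16^3), rep(16, 3))
  amps <- c(0.01, 0.03, 0.06, 0.12, 0.2)
  ps <- ss <- nm <- numeric(5)
  for (i in seq_along(amps)) {
    y <- pmin(pmax(x + amps[i] * noise, 0), 1)
    ps[i] <- psnr(x, y); ss[i] <- ssim3d(x, y); nm[i] <- nmse(y, x)
  }
  expect_true(all(diff(ps) < 0))
  expect_true(all(diff(ss) < 0))
  expect_true(all(diff(nm) > 0))
})

test_that("Otsu support extraction recovers a high-contrast region", {
  set.seed(605)
  m <- generate_mask(phantom_spec(side = 16, volume_range = c(60, 200), seed = 4))
  x <- array(runif(16^3, 0.3, 0.5), rep(16, 3))
  x[m == 1] <- runif(sum(m), 0.75, 0.95)
  sup <- lesion_support(x)
  expect_gt(mask_agreement(sup, m)$dice, 0.95)
})
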