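# SSIM, bead fitting, resolution maps.

test_that("ssim matches its definition on canonical cases", {
  set.seed(0)
  x <- matrix(runif(128 * 128), 128, 128)
  expect_identical(ssim(x, x, dataRange = 1), 1)
  y <- matrix(runif(128 * 128), 128, 128)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  # two independent noise fields are structurally dissimilar
  set.seed(1)
  z <- matrix(rnorm(128 * 128), 128, 128)
  set.seed(2)
  w <- matrix(rnorm(128 * 128), 128, 128)
  expect_lt(abs(ssim(z, w, dataRange = diff(range(c(z, w))))), 0.05)
  # constant-vs-constant closed form: (2ab + C1) / (a^2 + b^2 + C1)
  a <- 0.3; b <- 0.7; C1 <- (0.01 * 1)^2
  big <- 16
  expect_equal(ssim(matrix(a, big, big), matrix(b, big, big), dataRange = 1),
               (2 * a * b + C1) / (a^2 + b^2 + C1), tolerance = 1e-9)
  expect_error(ssim(x, matrix(0, 4, 4)), "shape")
  expect_error(ssim(x, x, dataRange = 0), "dataRange")
})

test_that("gaussian fits recover position and width without bias", {
  expect_identical(nrow(detectAndFitBeads(matrix(0, 32, 32))), 0L)
  one <- gaussianSpotsImage(41, cbind(21.4, 20.7), sigma = 2, amplitude = 3)
  fit <- detectAndFitBeads(one, detectionThreshold = 5, expectedFwhmPx = 4.7)
  expect_identical(nrow(fit), 1L)
  expect_equal(fit$fwhm, 4.71, tolerance = 0.05 / 4.71)
  expect_equal(fit$x, 21.4, tolerance = 0.05)
  expect_equal(fit$y, 20.7, tolerance = 0.05)
  # FWHM estimator unbiased within 2% across sigma in [1, 6]
  for (s in c(1, 2, 3, 4.5, 6)) {
    img <- gaussianSpotsImage(61, cbind(31, 31), sigma = s)
    f <- detectAndFitBeads(img, detectionThreshold = 4,
                           expectedFwhmPx = 2.3548 * s)
    expect_equal(f$sigma[1], s, tolerance = 0.02)
  }
})

test_that("a planted 50-bead field is recovered against its table", {
  set.seed(10)
  n <- 256
  pos <- NULL
  while (is.null(pos) || nrow(pos) < 50) {
    cand <- cbind(runif(200, 15, n - 15), runif(200, 15, n - 15))
    keep <- rep(TRUE, nrow(cand))
    for (i in 2:nrow(cand))
      if (any(sqrt(rowSums((cand[seq_len(i - 1), , drop = FALSE] -
                            matrix(cand[i, ], i - 1, 2, byrow = TRUE))^2))
              < 14)) keep[i] <- FALSE
    pos <- cand[keep, , drop = FALSE][seq_len(min(50, sum(keep))), ]
  }
  img <- gaussianSpotsImage(n, pos, sigma = 1.8, amplitude = 5)
  det <- detectAndFitBeads(img, detectionThreshold = 6, expectedFwhmPx = 4.2)
  expect_gte(nrow(det), 48)
  dmin <- beadMatchDistances(det, data.frame(x_px = pos[, 1],
                                             y_px = pos[, 2]))
  expect_gte(sum(dmin < 1), 48)
})

test_that("resolution maps bin FWHM by radius", {
  flat <- data.frame(x = c(40, 60, 80, 30, 64), y = c(64, 40, 80, 30, 64),
                     fwhm = rep(3.3, 5))
  rm1 <- resolutionMap(flat, fieldSize = 128)
  expect_true(all(rm1$meanFwhm[rm1$n > 0] == 3.3))
  single <- resolutionMap(flat[5, ], fieldSize = 128)
  expect_identical(sum(single$n), 1L)
  expect_error(resolutionMap(flat[0, ], fieldSize = 128), "at least one")
  # radially growing FWHM gives monotone bin means
  set.seed(3)
  r <- runif(60, 0, 60)
  th <- runif(60, 0, 2 * pi)
  grow <- data.frame(x = 64.5 + r * cos(th), y = 64.5 + r * sin(th),
                     fwhm = 2 + 0.05 * r)
  rmG <- resolutionMap(grow, fieldSize = 128, nBins = 4)
  mm <- rmG$meanFwhm[rmG$n > 0]
  expect_true(all(diff(mm) > 0))
  # unit conversion
  rmU <- resolutionMap(flat, fieldSize = 128, voxelSizeUm = 10)
  expect_equal(rmU$meanFwhmUm[rmU$n > 0], rep(33, sum(rmU$n > 0)))
})

test_that("mip takes the per-position maximum across slices", {
  v <- array(0, c(3, 4, 4))
  v[1, 1, 1] <- 5; v[3, 1, 1] <- 2; v[2, 4, 4] <- 7
  m <- maxIntensityProjection(ReconstructionVolume(v))
  expect_equal(m[1, 1], 5)
  expect_equal(m[4, 4], 7)
})
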