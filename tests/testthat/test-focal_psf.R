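# DOF/resolution trade-off, focal-sweep PSF model, deconvolution.

test_that("conventional resolution limit reproduces the DOF trade-off", {
  expect_equal(conventionalResolutionLimit(7, 550), 38, tolerance = 0.02)
  # square-root scaling: 4x the DOF doubles the resolution value
  expect_equal(conventionalResolutionLimit(28, 550),
               2 * conventionalResolutionLimit(7, 550), tolerance = 1e-9)
  # direct substitution at NA 0.01: dof = 5.5 mm, resolution 33.55 um
  om <- opticsModel(na = 0.01, wavelength = 550)
  expect_equal(om$dof, 5.5, tolerance = 1e-9)
  expect_equal(conventionalResolutionLimit(5.5, 550), 33.55, tolerance = 1e-3)
  # monotone increasing in both arguments
  d <- c(1, 2, 5, 10, 20)
  expect_true(all(diff(vapply(d, conventionalResolutionLimit, numeric(1),
                              wavelengthNm = 550)) > 0))
  w <- c(350, 450, 550, 650, 750)
  expect_true(all(diff(vapply(w, function(x)
    conventionalResolutionLimit(7, x), numeric(1))) > 0))
  expect_error(conventionalResolutionLimit(-1), "positive")
})

test_that("the sweep PSF model widens defocused planes symmetrically", {
  om <- opticsModel(na = 0.05, wavelength = 550, pixelSize = 2,
                    sweepRange = 1)
  z <- seq(-0.6, 0.6, length.out = 25)
  psf <- modelPsf(om, z)
  expect_equal(dim(psf)[1], 25)
  for (i in 1:25) expect_equal(sum(psf[i, , ]), 1, tolerance = 1e-9)
  # symmetric in +/- z
  expect_equal(psf[1, , ], psf[25, , ], tolerance = 1e-12)
  # in-focus plane has sigma ~ sigma0 (by second moment)
  k <- dim(psf)[2]
  x <- seq_len(k) - (k + 1) / 2
  inFocus <- psf[13, , ]
  sigmaMeas <- sqrt(sum(colSums(inFocus) * x^2))
  expect_equal(sigmaMeas, om$sigma0 / om$pixelSize, tolerance = 0.02)
  # sweep-averaged profile is wider than the in-focus one
  zWide <- seq(-5, 5, length.out = 41) * om$zR
  omW <- opticsModel(na = 0.05, wavelength = 550, pixelSize = 2,
                     sweepRange = 10 * om$zR)
  swept <- projectPsf(modelPsf(omW, zWide))
  fw <- function(kern) {                     # interpolated half-max width
    prof <- kern[(nrow(kern) + 1) / 2, ]
    prof <- prof / max(prof)
    fine <- seq(1, length(prof), by = 0.01)
    p <- approx(seq_along(prof), prof, fine)$y
    diff(range(fine[p >= 0.5]))
  }
  expect_gt(fw(swept) / fw(inFocus / sum(inFocus)), 1)
  expect_error(modelPsf(om, c(-0.1, 0.1)), "sweep range")
})

test_that("psf projection renormalizes and keeps separable widths", {
  om <- opticsModel(na = 0.05, wavelength = 550, pixelSize = 2)
  single <- modelPsf(om, 0)
  proj <- projectPsf(single)
  expect_equal(proj, single[1, , ] / sum(single[1, , ]), tolerance = 1e-12)
  expect_equal(sum(proj), 1, tolerance = 1e-9)
  # constant-sigma stack projects to the same Gaussian
  stack <- array(rep(single[1, , ], each = 5), c(5, dim(single)[2:3]))
  expect_equal(projectPsf(aperm(stack, c(1, 2, 3))), proj, tolerance = 1e-9)
  expect_error(projectPsf(array(0, c(3, 5, 5))), "zero")
})

test_that("richardson-lucy sharpens blurred beads and conserves flux", {
  om <- opticsModel(na = 0.05, wavelength = 550, pixelSize = 10,
                    sweepRange = 2)
  kern <- projectPsf(modelPsf(om, seq(-1.1, 1.1, length.out = 21)))
  n <- 64
  truth <- gaussianSpotsImage(n, cbind(c(25, 45), c(40, 22)), sigma = 2)
  blurred <- OPTrecon:::.fftConv2(truth, kern)
  st <- ProjectionStack(array(blurred, c(1, n, n)), angularRange = 360)
  dec <- deconvolveProjections(st, kern, method = "richardson-lucy",
                               iterations = 25L)
  out <- frames(dec)[1, , ]
  expect_equal(sum(out), sum(blurred), tolerance = 1e-3)
  expect_true(min(out) >= 0)
  fwhmOf <- function(img) mean(detectAndFitBeads(img, 3, 4)$fwhm)
  fB <- fwhmOf(blurred); fD <- fwhmOf(out); fT <- fwhmOf(truth)
  expect_lte(fD, fT + (fB - fT) * 0.75)      # >= 25% of the excess removed
  # delta kernel is the identity
  delta <- matrix(0, 5, 5); delta[3, 3] <- 1
  ident <- deconvolveProjections(st, delta, iterations = 5L)
  expect_equal(frames(ident)[1, , ], blurred, tolerance = 1e-9)
  # wiener runs and also sharpens
  wie <- deconvolveProjections(st, kern, method = "wiener",
                               noisePower = 1e-4)
  expect_lt(fwhmOf(pmax(frames(wie)[1, , ], 0)), fB)
  expect_error(deconvolveProjections(st, matrix(1 / 96^2, 96, 96)),
               "kernel larger")
})

test_that("deconvolution before fbp tightens reconstructed beads", {
  om <- opticsModel(na = 0.05, wavelength = 550, pixelSize = 100,
                    sweepRange = 4)
  kern <- projectPsf(modelPsf(om, seq(-2, 2, length.out = 15)))
  # beads sit in the central slice of a stack tall enough for in-plane blur
  sp <- phantomSpec(kind = "beads", beadLayout = "rings", grid = 64L,
                    nSlices = 41L, nBeads = 16L, nProjections = 120L)
  ph <- makePhantom(sp)
  mid <- 21L
  blurred <- simulateProjections(ph$truth, sp, blurKernel = kern)
  recB <- fbpSlice(extractSinogram(blurred, mid))
  dec <- deconvolveProjections(blurred, kern, iterations = 20L)
  recD <- fbpSlice(extractSinogram(dec, mid))
  fB <- mean(detectAndFitBeads(recB, 5, 4)$fwhm)
  fD <- mean(detectAndFitBeads(recD, 5, 4)$fwhm)
  expect_lte(fD, fB)
})
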