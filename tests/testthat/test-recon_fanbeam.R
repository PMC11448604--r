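# Magnification calibration and fan-beam reconstruction.

test_that("magnification calibration fits the line and finds D", {
  g <- calibrateMagnification(data.frame(z_mm = 0:10,
                                         size_px = 100 + 2 * (0:10)))
  expect_equal(g@calibration$slope, 2, tolerance = 1e-9)
  expect_equal(g@calibration$intercept, 100, tolerance = 1e-9)
  expect_equal(g@calibration$residualRms, 0, tolerance = 1e-9)
  expect_equal(fanOrigin(g), 50)
  expect_false(isTelecentric(g))
  # constant size: telecentric limit
  tele <- calibrateMagnification(data.frame(z_mm = 0:10, size_px = 100))
  expect_true(isTelecentric(tele))
  expect_identical(fanOrigin(tele), Inf)
  # noisy line recovers the slope within 5%
  set.seed(42)
  noisy <- calibrateMagnification(
    data.frame(z_mm = seq(-5, 5, 1),
               size_px = 100 + 2 * seq(-5, 5, 1) + rnorm(11, 0, 0.5)))
  expect_equal(noisy@calibration$slope, 2, tolerance = 0.05)
  expect_error(calibrateMagnification(data.frame(z_mm = c(1, 1),
                                                 size_px = c(2, 3))),
               "distinct")
})

# Shared fan-geometry fixture: bead rings in a 14 mm field, D = 50 mm.
fanFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantomSpec(kind = "beads", beadLayout = "rings", grid = 96L,
                        nSlices = 1L, nBeads = 31L, nProjections = 240L,
                        geometry = "fan", fanDMm = 50)
      ph <- makePhantom(sp)
      cache <<- list(spec = sp, phantom = ph,
                     stack = simulateProjections(ph$truth, sp))
    }
    cache
  }
})

test_that("fan-beam reconstruction reduces to fbp in the telecentric limit", {
  fx <- fanFixture()
  sino <- extractSinogram(fx$stack, 1L)
  par <- fbpSlice(sino)
  farD <- fanbeamReconstruct(sino, FanBeamGeometry(D = 1e6 * 14))
  dyn <- diff(range(par))
  expect_lt(rmse(farD, par) / dyn, 0.01)
  expect_identical(fanbeamReconstruct(sino, FanBeamGeometry(D = Inf)), par)
  expect_error(fanbeamReconstruct(sino, FanBeamGeometry(D = 0.1)),
               "exceed")
})

test_that("reconstructing fan data with the true D fixes off-axis beads", {
  fx <- fanFixture()
  sino <- extractSinogram(fx$stack, 1L)
  truth <- fx$phantom$beads
  ctr <- (96 + 1) / 2
  measure <- function(rec) {
    det <- detectAndFitBeads(rec, detectionThreshold = 6, expectedFwhmPx = 3)
    j <- vapply(seq_len(nrow(det)), function(i)
      which.min((truth$x_px - det$x[i])^2 + (truth$y_px - det$y[i])^2),
      integer(1))
    dmin <- sqrt((truth$x_px[j] - det$x)^2 + (truth$y_px[j] - det$y)^2)
    out <- data.frame(det, r = sqrt((truth$x_px[j] - ctr)^2 +
                                    (truth$y_px[j] - ctr)^2))
    out[dmin < 3, ]
  }
  par <- measure(fbpSlice(sino))
  fan <- measure(fanbeamReconstruct(sino, FanBeamGeometry(D = 50)))
  onAxisFan <- mean(fan$fwhm[fan$r < 15])
  offAxisFan <- mean(fan$fwhm[fan$r > 0.5 * 48])
  expect_lt(abs(offAxisFan - onAxisFan) / onAxisFan, 0.25)
  offAxisPar <- mean(par$fwhm[par$r > 0.5 * 48])
  expect_gt(offAxisPar, offAxisFan)
  onAxisPar <- mean(par$fwhm[par$r < 15])
  expect_lt(abs(onAxisPar - onAxisFan) / onAxisFan, 0.10)
})

test_that("fan origin estimation minimizes artifacts at the true distance", {
  fx <- fanFixture()
  est <- estimateFanOrigin(fx$stack, 1L,
                           candidateD = c(25, 40, 50, 65, 100, Inf),
                           detectionThreshold = 6)
  expect_equal(est$D, 50)
  m <- est$artifactCurve$metric[1:5]        # finite-D branch of the sweep
  k <- which.min(m)
  expect_true(all(diff(m[seq_len(k)]) < 0))  # unimodal: falls then rises
  expect_true(all(diff(m[k:5]) > 0))
  # telecentric data prefer the parallel geometry
  spT <- phantomSpec(kind = "beads", beadLayout = "rings", grid = 96L,
                     nSlices = 1L, nBeads = 31L, nProjections = 240L)
  phT <- makePhantom(spT)
  stT <- simulateProjections(phT$truth, spT)
  estT <- estimateFanOrigin(stT, 1L, candidateD = c(50, 100, Inf),
                            detectionThreshold = 6)
  expect_identical(estT$D, Inf)
})
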