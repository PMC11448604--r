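# Flat-field, hot pixels, downsampling, bleaching, rotation-axis alignment.

test_that("flat-field correction removes a known radial gain", {
  n <- 32
  xy <- expand.grid(y = 1:n, x = 1:n)
  gain <- matrix(1 - 0.4 * ((xy$x - 16.5)^2 + (xy$y - 16.5)^2) / 16.5^2, n, n)
  scene <- matrix(runif(n * n, 10, 20), n, n)
  offset <- matrix(5, n, n)
  recorded <- scene * gain + offset
  st <- ProjectionStack(array(recorded, c(1, n, n)), angularRange = 360)
  bg <- 100 * gain + offset
  out <- frames(flatFieldCorrect(st, bg, offset))[1, , ]
  expect_equal(out / mean(100 * gain), scene / 100, tolerance = 1e-6)
  # frame == background, zero offset -> uniform mean(background)
  st2 <- ProjectionStack(array(bg, c(1, n, n)), angularRange = 360)
  out2 <- frames(flatFieldCorrect(st2, bg))[1, , ]
  expect_equal(out2, matrix(mean(bg), n, n), tolerance = 1e-12)
  # frame == offset -> all zero
  st3 <- ProjectionStack(array(offset, c(1, n, n)), angularRange = 360)
  expect_true(all(frames(flatFieldCorrect(st3, bg, offset)) == 0))
  expect_error(flatFieldCorrect(st, matrix(1, 8, 8)), "shape")
  expect_error(flatFieldCorrect(st, offset, bg), "background <= offset")
})

test_that("hot-pixel filter replaces only planted defects", {
  n <- 16
  const <- ProjectionStack(array(3, c(1, n, n)), angularRange = 360)
  expect_identical(frames(hotPixelFilter(const)), frames(const))
  # constant frame with one 100x spike: exactly that pixel changes
  fr <- matrix(3, n, n); fr[5, 9] <- 300
  st <- ProjectionStack(array(fr, c(1, n, n)), angularRange = 360)
  out <- frames(hotPixelFilter(st))[1, , ]
  expect_equal(out[5, 9], 3)
  expect_equal(sum(out != fr), 1)
  # Poisson frame with 50 planted 20-sigma hot pixels
  set.seed(6)
  n2 <- 128
  base <- matrix(rpois(n2 * n2, 100), n2, n2)
  idx <- cbind(sample(2:(n2 - 1), 50), sample(2:(n2 - 1), 50))
  planted <- base
  planted[idx] <- 100 + 20 * 10 * 2      # far beyond 20 robust sigmas
  stp <- ProjectionStack(array(planted, c(1, n2, n2)), angularRange = 360)
  outp <- frames(hotPixelFilter(stp, thresholdSigmas = 8))[1, , ]
  expect_gte(sum(outp[idx] != planted[idx]), 48)
  others <- planted; others[idx] <- outp[idx]
  expect_lt(mean(outp != others), 0.001)
  expect_error(hotPixelFilter(st, window = 4), "odd")
  expect_error(hotPixelFilter(st, window = 99), "window larger")
})

test_that("downsampling bins by the mean and conserves mass", {
  st <- ProjectionStack(array(runif(2 * 12 * 12), c(2, 12, 12)),
                        angularRange = 360, pixelSize = 5)
  expect_identical(downsampleStack(st, 1L), st)
  out <- downsampleStack(st, 2L)
  expect_identical(dim(frames(out)), c(2L, 6L, 6L))
  expect_equal(pixelSize(out), 10)
  expect_equal(sum(frames(out)[1, , ]) * 4, sum(frames(st)[1, , ]),
               tolerance = 1e-9)
  # checkerboard averages to one half
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  stc <- ProjectionStack(array(cb, c(1, 4, 4)), angularRange = 360)
  expect_true(all(frames(downsampleStack(stc, 2L)) == 0.5))
  # non-divisible sizes crop with a message
  st13 <- ProjectionStack(array(1, c(1, 13, 13)), angularRange = 360)
  expect_message(out13 <- downsampleStack(st13, 2L), "cropping")
  expect_identical(dim(frames(out13))[2:3], c(6L, 6L))
  expect_error(downsampleStack(st, 0), "integer")
})

test_that("bleach rate is recovered and correction flattens totals", {
  const <- ProjectionStack(array(2, c(10, 4, 4)), angularRange = 360)
  m0 <- estimateBleach(const)
  expect_equal(bleachRate(m0), 0, tolerance = 1e-12)
  expect_equal(bleachScale(m0), rep(1, 10), tolerance = 1e-12)
  sp <- phantomSpec(kind = "beads", grid = 64L, nSlices = 8L, nBeads = 15L,
                    nProjections = 100L, seed = 5L, bleachRate = 0.002)
  ph <- makePhantom(sp)
  st <- simulateProjections(ph$truth, sp)
  m <- estimateBleach(st)
  expect_equal(bleachRate(m), 0.002, tolerance = 0.05 * 0.002)
  corrected <- applyBleach(st, m)
  totals <- vapply(1:100, function(p) sum(frames(corrected)[p, , ]),
                   numeric(1))
  slope <- unname(coef(lm(log(totals) ~ I(0:99)))[2])
  expect_lt(abs(slope), 1e-4)
  expect_equal(max(abs(totals / totals[1] - 1)), 0, tolerance = 0.01)
  # identity and doubling models
  ident <- new("BleachModel", rate = 0, scale = rep(1, 100), r2 = 1)
  expect_equal(frames(applyBleach(st, ident)), frames(st))
  expect_error(applyBleach(st, m0), "length")
})

test_that("simulated frame totals decay at the configured bleach rate", {
  sp <- phantomSpec(kind = "beads", grid = 48L, nSlices = 4L, nBeads = 10L,
                    nProjections = 60L, seed = 9L, bleachRate = 0.002)
  ph <- makePhantom(sp)
  st <- simulateProjections(ph$truth, sp)
  totals <- vapply(1:60, function(p) sum(frames(st)[p, , ]), numeric(1))
  rate <- -unname(coef(lm(log(totals) ~ I(0:59)))[2])
  expect_equal(rate, 0.002, tolerance = 1e-5 / 0.002)
})

test_that("axis offset and tilt are recovered from opposed projections", {
  aligned <- misalignedBeadStack(0, 0)
  ap0 <- estimateAlignment(aligned)
  expect_lt(abs(axisOffset(ap0)), 0.1)
  expect_lt(abs(axisTilt(ap0)), 0.05)
  shifted <- misalignedBeadStack(3.5, 0)
  ap1 <- estimateAlignment(shifted)
  expect_equal(axisOffset(ap1), 3.5, tolerance = 0.25 / 3.5)
  rotated <- misalignedBeadStack(0, 1.0)
  ap2 <- estimateAlignment(rotated)
  expect_equal(axisTilt(ap2), 1.0, tolerance = 0.1)
  # 180-degree data cannot be auto-aligned
  st180 <- ProjectionStack(frames(aligned), angularRange = 180)
  expect_error(estimateAlignment(st180), "manual")
})

test_that("estimate/apply alignment is a recovery loop over the stated range", {
  for (d in c(-10, 4)) for (t in c(-3, 1)) {
    st <- misalignedBeadStack(d, t)
    ap <- estimateAlignment(st)
    expect_equal(axisOffset(ap), d, tolerance = 0.3, ignore_attr = TRUE)
    expect_equal(axisTilt(ap), t, tolerance = 0.1, ignore_attr = TRUE)
    resid <- estimateAlignment(applyAlignment(st, ap))
    expect_lt(abs(axisOffset(resid)), 0.15)
    expect_lt(abs(axisTilt(resid)), 0.08)
  }
})

test_that("applying alignment is invertible within interpolation tolerance", {
  st <- misalignedBeadStack(0, 0)
  expect_identical(applyAlignment(st, AlignmentParams(0, 0)), st)
  fwd <- applyAlignment(st, AlignmentParams(3, 0))
  back <- applyAlignment(fwd, AlignmentParams(-3, 0))
  dyn <- diff(range(frames(st)))
  # compare away from the zero-filled border
  err <- rmse(frames(back)[, , 10:86], frames(st)[, , 10:86])
  expect_lt(err, 0.01 * dyn)
})
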