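# Phantom generation and the forward imaging simulator.

test_that("phantoms are deterministic, contained and honestly tabulated", {
  expect_error(phantomSpec(kind = "beads", seed = NULL), "seed")
  spEmpty <- phantomSpec(kind = "beads", nBeads = 0L, grid = 32L,
                         nProjections = 8L)
  phE <- makePhantom(spEmpty)
  expect_true(all(voxels(phE$truth) == 0))
  expect_identical(nrow(phE$beads), 0L)
  sp <- phantomSpec(kind = "beads", grid = 64L, nSlices = 6L, nBeads = 100L,
                    nProjections = 16L, seed = 7L)
  a <- makePhantom(sp); b <- makePhantom(sp)
  expect_identical(voxels(a$truth), voxels(b$truth))
  expect_identical(a$beads, b$beads)
  expect_identical(nrow(a$beads), 100L)
  ctr <- (64 + 1) / 2
  r <- sqrt((a$beads$x_px - ctr)^2 + (a$beads$y_px - ctr)^2)
  expect_true(all(r <= 32))
  expect_true(all(a$beads$z_slice >= 1 & a$beads$z_slice <= 6))
  # voxel size bookkeeping: 14 mm over 64 voxels
  expect_equal(voxelSize(a$truth), 14000 / 64)
})

test_that("clean parallel simulation equals the direct radon transform", {
  sp <- phantomSpec(kind = "beads", grid = 48L, nSlices = 3L, nBeads = 8L,
                    nProjections = 30L, seed = 2L)
  ph <- makePhantom(sp)
  st <- simulateProjections(ph$truth, sp)
  ang <- (0:29) * 12
  for (z in c(1L, 3L)) {
    direct <- sinogramValues(forwardProject(voxels(ph$truth)[z, , ], ang))
    viaStack <- sinogramValues(extractSinogram(st, z))
    expect_equal(viaStack, direct, tolerance = 1e-6)
  }
})

test_that("fan simulation converges to the parallel stack as D grows", {
  spP <- phantomSpec(kind = "beads", grid = 48L, nSlices = 1L, nBeads = 10L,
                     nProjections = 24L, seed = 8L)
  ph <- makePhantom(spP)
  spF <- phantomSpec(kind = "beads", grid = 48L, nSlices = 1L, nBeads = 10L,
                     nProjections = 24L, seed = 8L,
                     geometry = "fan", fanDMm = 1e6 * 14)
  parallel <- frames(simulateProjections(ph$truth, spP))
  fan <- frames(simulateProjections(ph$truth, spF))
  expect_lt(max(abs(fan - parallel)) / max(parallel), 0.001)
  expect_error(phantomSpec(kind = "beads", geometry = "fan", fanDMm = 3,
                           fieldSizeMm = 14, seed = 1), "field radius")
})

test_that("two noisy simulations from one seed are bit-identical", {
  sp <- phantomSpec(kind = "beads", grid = 32L, nSlices = 2L, nBeads = 6L,
                    nProjections = 12L, seed = 21L,
                    noise = list(type = "poisson", scale = 5))
  ph <- makePhantom(sp)
  s1 <- simulateProjections(ph$truth, sp)
  s2 <- simulateProjections(ph$truth, sp)
  expect_identical(frames(s1), frames(s2))
  spg <- phantomSpec(kind = "beads", grid = 32L, nSlices = 2L, nBeads = 6L,
                     nProjections = 12L, seed = 21L,
                     noise = list(type = "gaussian", sigma = 0.1))
  g1 <- simulateProjections(ph$truth, spg)
  expect_false(identical(frames(g1), frames(s1)))
  expect_identical(frames(g1), frames(simulateProjections(ph$truth, spg)))
})

test_that("full loop: simulate then reconstruct recovers the phantom", {
  sp <- phantomSpec(kind = "beads", grid = 128L, nSlices = 3L, nBeads = 25L,
                    nProjections = 400L, seed = 17L)
  ph <- makePhantom(sp)
  st <- simulateProjections(ph$truth, sp)
  vol <- fbpVolume(st, fbpConfig())
  # every isolated bead centre within 1 voxel of the truth on the MIP
  # (beads closer than ~3 FWHM merge in detection, as in a real image)
  nnDist <- vapply(seq_len(nrow(ph$beads)), function(i)
    min(sqrt((ph$beads$x_px[-i] - ph$beads$x_px[i])^2 +
             (ph$beads$y_px[-i] - ph$beads$y_px[i])^2)), numeric(1))
  tb <- ph$beads[nnDist > 8, ]
  expect_gte(nrow(tb), 12)
  det <- detectAndFitBeads(maxIntensityProjection(vol),
                           detectionThreshold = 6, expectedFwhmPx = 3)
  j <- vapply(seq_len(nrow(tb)), function(i)
    min(sqrt((det$x - tb$x_px[i])^2 + (det$y - tb$y_px[i])^2)), numeric(1))
  expect_true(all(j < 1))
  mipR <- maxIntensityProjection(vol)
  mipT <- maxIntensityProjection(ph$truth)
  expect_gte(ssim(mipR, mipT, dataRange = max(mipT)), 0.9)
})
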