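# Discrete Radon transform and filtered back projection.

test_that("forward projection conserves mass and centres the axis point", {
  n <- 33                                   # odd: integer centre pixel
  ang <- (0:59) * 6
  img <- matrix(0, n, n); img[17, 17] <- 1
  v <- sinogramValues(forwardProject(img, ang))
  expect_equal(unname(apply(v, 2, which.max)), rep(17L, 60))
  cent <- colSums(v * seq_len(n)) / colSums(v)
  expect_lt(max(abs(cent - 17)), 0.05)
  # mass conservation for an arbitrary interior image
  set.seed(7)
  img2 <- matrix(0, n, n)
  img2[9:25, 9:25] <- runif(17 * 17)
  v2 <- sinogramValues(forwardProject(img2, ang))
  expect_lt(max(abs(colSums(v2) - sum(img2))) / sum(img2), 0.001)
  expect_error(forwardProject(matrix(0, 4, 5), ang), "square")
  expect_error(forwardProject(img, c(0, 10, 30)), "equally spaced")
})

test_that("an off-axis point traces the closed-form sinusoid", {
  n <- 64
  ang <- (0:119) * 3
  r <- 10.5                                 # point at (centre + r, centre)
  img <- matrix(0, n, n); img[33, 43] <- 1  # y = 32.5 + 0.5, x = 32.5 + 10.5
  v <- sinogramValues(forwardProject(img, ang))
  cent <- colSums(v * seq_len(n)) / colSums(v)
  th <- ang * pi / 180
  pred <- 32.5 + 10.5 * cos(th) + 0.5 * sin(th)
  expect_lt(max(abs(cent - pred)), 0.2)
})

test_that("fbp reconstructs the analytic disc and degrades gracefully", {
  n <- 128
  disc <- discImage(n)
  masks <- discMasks(n)
  sino400 <- forwardProject(disc, (0:399) * 0.9)
  rec <- fbpSlice(sino400, fbpConfig(filter = "ram-lak"))
  expect_equal(mean(rec[masks$inside]), 1.0, tolerance = 0.05)
  expect_lt(mean(abs(rec[masks$outside])), 0.02)
  # all-zero sinogram reconstructs to zero
  z <- Sinogram(matrix(0, n, 40), angularRange = 360)
  expect_true(all(fbpSlice(z) == 0))
  # sparse-view streaks: RMSE monotone non-increasing in P
  errs <- vapply(c(20, 40, 80, 200, 400), function(P) {
    sub <- subsetProjections(sino400, P)
    rmse(fbpSlice(sub), disc)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_error(fbpSlice(Sinogram(matrix(0, n, 1), angularRange = 360)),
               "at least 2")
})

test_that("fbp is linear and equivariant to rotation-centre shifts", {
  n <- 64
  set.seed(8)
  s1 <- forwardProject(discImage(n), (0:89) * 4)
  img2 <- matrix(0, n, n); img2[20:30, 35:45] <- 1
  s2 <- forwardProject(img2, (0:89) * 4)
  cfg <- fbpConfig()
  lin <- fbpSlice(Sinogram(2 * sinogramValues(s1) - 3 * sinogramValues(s2),
                           angularRange = 360), cfg)
  ref <- 2 * fbpSlice(s1, cfg) - 3 * fbpSlice(s2, cfg)
  expect_lt(max(abs(lin - ref)) / max(abs(ref)), 1e-6)
  # integer detector shift + matching centre leaves the slice unchanged
  delta <- 4L
  v <- sinogramValues(s1)
  shifted <- rbind(matrix(0, delta, ncol(v)), v[1:(n - delta), ])
  recA <- fbpSlice(s1, fbpConfig())
  recB <- fbpSlice(Sinogram(shifted, angularRange = 360),
                   fbpConfig(rotationCenter = (n + 1) / 2 + delta))
  core <- 10:(n - 10)
  expect_lt(rmse(recA[core, core], recB[core, core]), 0.01)
})

test_that("apodized filters and angular folding stay close to ram-lak", {
  n <- 64
  disc <- discImage(n)
  masks <- discMasks(n)
  sino <- forwardProject(disc, (0:199) * 1.8)
  for (f in c("shepp-logan", "cosine", "hamming", "hann")) {
    rec <- fbpSlice(sino, fbpConfig(filter = f))
    expect_equal(mean(rec[masks$inside]), 1.0, tolerance = 0.05)
  }
  recNone <- fbpSlice(sino, fbpConfig(filter = "none"))
  expect_gt(mean(recNone[masks$inside]), 1)    # unfiltered laminogram blurs up
  fold <- fbpSlice(sino, fbpConfig(angularUsage = "fold360to180"))
  full <- fbpSlice(sino, fbpConfig())
  expect_lt(rmse(fold, full), 0.02)
  expect_error(fbpConfig(frequencyCutoff = 0), "frequencyCutoff")
  lowcut <- fbpSlice(sino, fbpConfig(frequencyCutoff = 0.4))
  expect_equal(mean(lowcut[masks$inside]), 1.0, tolerance = 0.05)
})

test_that("chunked volume reconstruction is bit-identical and recovers beads", {
  sp <- phantomSpec(kind = "beads", beadLayout = "rings", grid = 96L,
                    nSlices = 5L, nBeads = 12L, nProjections = 120L,
                    seed = 12L)
  ph <- makePhantom(sp)
  st <- simulateProjections(ph$truth, sp)
  perSlice <- OPTrecon:::.sliceWorkBytes(96L, 120L, 96L)
  vAll <- fbpVolume(st, fbpConfig(), maxRamBytes = 100 * 5 * perSlice)
  v1 <- fbpVolume(st, fbpConfig(), maxRamBytes = perSlice)          # 1 row
  v2 <- fbpVolume(st, fbpConfig(), maxRamBytes = 2 * perSlice)      # 2 rows
  expect_identical(voxels(v1), voxels(vAll))
  expect_identical(voxels(v2), voxels(vAll))
  expect_error(fbpVolume(st, fbpConfig(), maxRamBytes = 100),
               "working set")
  expect_identical(dim(voxels(vAll))[1], 5L)
  # bead centres land within a voxel of the truth
  mip <- maxIntensityProjection(vAll)
  det <- detectAndFitBeads(mip, detectionThreshold = 6, expectedFwhmPx = 3)
  expect_gte(nrow(det), 10)
  expect_lt(max(beadMatchDistances(det, ph$beads)), 1)
})
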