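# Shared fixture builders; everything is generated in code at test time.

# Uniform unit disc of radius n/4 centred in an n x n image.
discImage <- function(n) {
  ctr <- (n + 1) / 2
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix(as.numeric((xy$x - ctr)^2 + (xy$y - ctr)^2 <= (n / 4)^2), n, n)
}

# Radial masks used when scoring disc reconstructions.
discMasks <- function(n, radius = n / 4) {
  ctr <- (n + 1) / 2
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  r2 <- (xy$x - ctr)^2 + (xy$y - ctr)^2
  list(inside = matrix(r2 <= (0.9 * radius)^2, n, n),
       outside = matrix(r2 > (1.2 * radius)^2 & r2 <= (n / 2 - 2)^2, n, n))
}

# Isolated 2-D Gaussian spots of width sigma at given centres.
gaussianSpotsImage <- function(n, centers, sigma, amplitude = 1) {
  xy <- expand.grid(y = seq_len(n), x = seq_len(n))
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(centers)))
    img <- img + amplitude *
      exp(-((xy$x - centers[i, 1])^2 + (xy$y - centers[i, 2])^2) /
            (2 * sigma^2))
  img
}

# Small misaligned bead-stack fixture shared by the alignment tests.
misalignedBeadStack <- function(offset, tilt, grid = 96L, seed = 11L) {
  sp <- phantomSpec(kind = "beads", grid = grid, nSlices = 48L, nBeads = 30L,
                    nProjections = 64L, seed = seed,
                    misalignment = c(offset, tilt))
  ph <- makePhantom(sp)
  simulateProjections(ph$truth, sp)
}

# Nearest-truth matching distance for each detected bead.
beadMatchDistances <- function(detected, truthBeads) {
  vapply(seq_len(nrow(detected)), function(i)
    min(sqrt((truthBeads$x_px - detected$x[i])^2 +
             (truthBeads$y_px - detected$y[i])^2)), numeric(1))
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
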