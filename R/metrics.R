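# Quantitative evaluation: structural similarity, bead detection with
# Gaussian FWHM fitting, and resolution maps.

#' Structural similarity index (SSIM)
#'
#' Canonical SSIM with Gaussian local statistics (default sigma 1.5,
#' 11 x 11 window) and stabilization constants `C1 = (K1 R)^2`,
#' `C2 = (K2 R)^2` with `K1 = 0.01`, `K2 = 0.03` and R the data range.
#' The mean is taken over the fully windowed interior; the measure is
#' symmetric in its arguments and equals 1 for identical images.
#'
#' @param imageA,imageB equal-shape numeric matrices.
#' @param dataRange dynamic range R (> 0); defaults to the joint range of
#'   both images.
#' @param windowSigma Gaussian window sigma in pixels.
#' @param K1,K2 stabilization constants.
#' @return SSIM value in [-1, 1].
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' ssim(x, x)   # exactly 1
#' @export
ssim <- function(imageA, imageB, dataRange = NULL, windowSigma = 1.5,
                 K1 = 0.01, K2 = 0.03) {
  imageA <- as.matrix(imageA); imageB <- as.matrix(imageB)
  if (!identical(dim(imageA), dim(imageB))) stop("shape mismatch")
  if (is.null(dataRange))
    dataRange <- max(imageA, imageB) - min(imageA, imageB)
  if (dataRange <= 0) stop("dataRange must be > 0")
  radius <- min(floor(3.5 * windowSigma + 0.5),
                (min(dim(imageA)) - 1L) %/% 2L)
  k <- .gaussKernel1d(windowSigma, radius = radius)
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  muA <- .sepConvValid(imageA, k)
  muB <- .sepConvValid(imageB, k)
  eAA <- .sepConvValid(imageA^2, k)
  eBB <- .sepConvValid(imageB^2, k)
  eAB <- .sepConvValid(imageA * imageB, k)
  vA <- eAA - muA^2
  vB <- eBB - muB^2
  covAB <- eAB - muA * muB
  s <- ((2 * muA * muB + C1) * (2 * covAB + C2)) /
       ((muA^2 + muB^2 + C1) * (vA + vB + C2))
  mean(s)
}

# 8-neighbour local maxima of a matrix, as an index matrix.
.localMaxima <- function(img) {
  n <- nrow(img); m <- ncol(img)
  pad <- matrix(-Inf, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- img
  ok <- matrix(TRUE, n, m)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & img >= pad[(2 + dy):(n + 1 + dy), (2 + dx):(m + 1 + dx)]
  }
  which(ok, arr.ind = TRUE)
}

#' Detect point-like features and fit Gaussian widths
#'
#' Finds local maxima above a robust threshold (median background plus
#' `detectionThreshold` robust sigmas), merges overlapping detection
#' windows to the brighter peak, and fits each with a symmetric 2-D
#' Gaussian plus constant offset by Levenberg-Marquardt least squares in a
#' window of four expected FWHM. `FWHM = 2 sqrt(2 ln 2) sigma` (2.3548
#' sigma).
#'
#' @param image numeric matrix containing isolated point-like maxima.
#' @param detectionThreshold threshold in robust sigmas above background.
#' @param expectedFwhmPx expected feature FWHM in pixels (sets the fit
#'   window).
#' @param minRelAmplitude peaks must additionally rise above this fraction
#'   of the brightest peak's excursion over background; suppresses
#'   reconstruction-noise maxima when the background is almost flat.
#' @param voxelSizeUm optional scale to add a `fwhm_um` column.
#' @return Data frame of bead measurements: `x`, `y` (fitted centre, px),
#'   `sigma`, `fwhm` (px), `amplitude`, `offset`, `residual` (RMS); empty
#'   when nothing is detected.
#' @export
detectAndFitBeads <- function(image, detectionThreshold = 5,
                              expectedFwhmPx = 4, minRelAmplitude = 0.1,
                              voxelSizeUm = NULL) {
  image <- as.matrix(image)
  empty <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      fwhm = numeric(0), amplitude = numeric(0),
                      offset = numeric(0), residual = numeric(0))
  bg <- median(image)
  sig <- .robustSigma(as.vector(image) - bg)
  if (sig == 0) sig <- sd(image)
  if (is.na(sig) || sig == 0) return(empty)
  thr <- bg + max(detectionThreshold * sig,
                  minRelAmplitude * (max(image) - bg))
  lm0 <- .localMaxima(image)
  vals <- image[lm0]
  keep <- vals > thr
  if (!any(keep)) return(empty)
  lm0 <- lm0[keep, , drop = FALSE]
  vals <- vals[keep]
  o <- order(vals, decreasing = TRUE)
  lm0 <- lm0[o, , drop = FALSE]; vals <- vals[o]
  half <- max(3L, ceiling(2 * expectedFwhmPx))
  # merge overlapping windows toward the brighter peak
  sel <- logical(nrow(lm0))
  for (i in seq_len(nrow(lm0))) {
    if (i == 1L) { sel[1] <- TRUE; next }
    prev <- lm0[sel, , drop = FALSE]
    d <- pmax(abs(prev[, 1] - lm0[i, 1]), abs(prev[, 2] - lm0[i, 2]))
    sel[i] <- all(d > half)
  }
  lm0 <- lm0[sel, , drop = FALSE]
  fits <- lapply(seq_len(nrow(lm0)), function(i) {
    r0 <- unname(lm0[i, 1]); c0 <- unname(lm0[i, 2])
    ry <- max(1L, r0 - half):min(nrow(image), r0 + half)
    rx <- max(1L, c0 - half):min(ncol(image), c0 + half)
    win <- image[ry, rx, drop = FALSE]
    df <- data.frame(z = as.vector(win),
                     y = rep(ry, times = length(rx)),
                     x = rep(rx, each = length(ry)))
    amp <- max(win) - bg
    start <- list(A = amp, x0 = as.numeric(c0), y0 = as.numeric(r0),
                  s = max(expectedFwhmPx / 2.3548, 0.8),
                  c0 = if (abs(bg) < 1e-6 * amp) 0 else bg)
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + c0,
                        data = df, start = start,
                        lower = c(A = 0, x0 = min(rx) - 1, y0 = min(ry) - 1,
                                  s = 0.3, c0 = -Inf),
                        upper = c(A = Inf, x0 = max(rx) + 1, y0 = max(ry) + 1,
                                  s = 4 * expectedFwhmPx, c0 = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- coef(fit)
    data.frame(x = unname(cf["x0"]), y = unname(cf["y0"]),
               sigma = unname(cf["s"]), fwhm = 2.3548200450309493 * unname(cf["s"]),
               amplitude = unname(cf["A"]), offset = unname(cf["c0"]),
               residual = sqrt(mean(fit$m$resid()^2)))
  })
  out <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(out)) return(empty)
  if (!is.null(voxelSizeUm)) out$fwhm_um <- out$fwhm * voxelSizeUm
  rownames(out) <- NULL
  out
}

#' Bin bead measurements into a resolution map
#'
#' Bins bead FWHM measurements by radial distance from the field centre
#' and reports per-bin mean and spread, the standard summary of effective
#' resolution across a reconstructed field of view.
#'
#' @param measurements data frame from [detectAndFitBeads()].
#' @param center field centre `c(x, y)` in px (default from `fieldSize`).
#' @param fieldSize image side in px (sets default centre and bin limits).
#' @param nBins number of radial bins.
#' @param voxelSizeUm optional scale; adds `meanFwhmUm`.
#' @return A `resolutionMap` data frame: bin radius range and centre (px),
#'   bead count, mean and sd FWHM (px, optionally um).
#' @export
resolutionMap <- function(measurements, fieldSize, center = NULL, nBins = 5,
                          voxelSizeUm = NULL) {
  if (nrow(measurements) < 1L) stop("need at least one measurement")
  if (is.null(center)) center <- rep((fieldSize + 1) / 2, 2)
  r <- sqrt((measurements$x - center[1])^2 + (measurements$y - center[2])^2)
  edges <- seq(0, fieldSize / 2, length.out = nBins + 1)
  bin <- pmin(findInterval(r, edges, rightmost.closed = TRUE), nBins)
  out <- data.frame(rLo = edges[-length(edges)], rHi = edges[-1],
                    rMid = (edges[-1] + edges[-length(edges)]) / 2,
                    n = tabulate(bin, nBins),
                    meanFwhm = vapply(seq_len(nBins), function(b)
                      if (any(bin == b)) mean(measurements$fwhm[bin == b])
                      else NA_real_, numeric(1)),
                    sdFwhm = vapply(seq_len(nBins), function(b)
                      if (sum(bin == b) > 1) sd(measurements$fwhm[bin == b])
                      else NA_real_, numeric(1)))
  if (!is.null(voxelSizeUm)) out$meanFwhmUm <- out$meanFwhm * voxelSizeUm
  class(out) <- c("resolutionMap", "data.frame")
  out
}

#' Plot a resolution map
#'
#' Colour-coded radial resolution summary for documentation figures.
#'
#' @param x a [resolutionMap()] result.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plotResolutionMap <- function(x, ...) {
  filled <- !is.na(x$meanFwhm)
  graphics::image(x = c(x$rLo[1], x$rHi)[c(TRUE, filled)],
                  z = matrix(x$meanFwhm[filled], ncol = 1),
                  col = grDevices::gray.colors(32), xlab = "radius (px)",
                  ylab = "", yaxt = "n", ...)
  invisible(x)
}

#' Maximum intensity projection of a volume
#'
#' Per-(y, x) maximum across slices; the standard rendering on which bead
#' measurements of reconstructed volumes are taken.
#'
#' @param volume a [ReconstructionVolume-class].
#' @return Square matrix.
#' @export
maxIntensityProjection <- function(volume) {
  stopifnot(is(volume, "ReconstructionVolume"))
  apply(voxels(volume), c(2, 3), max)
}
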