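# Parallel-beam forward projection (discrete Radon transform) and filtered
# back projection.
#
# Conventions (fixed package-wide): angles are degrees, counter-clockwise
# viewed down the rotation axis, first projection at 0 deg; a slice image is
# a square matrix img[row = y, col = x]; the detector column grid coincides
# with the image x grid; the rotation axis projects to detector column
# `rotationCenter` (1-based, fractional, default the geometric centre
# (U+1)/2). A unit point at (centre + r, centre) traces the sinusoid
# u(theta) = rotationCenter + r cos(theta).

#' FBP configuration
#'
#' Parameters of the filtered back projection reconstruction.
#'
#' @param filter apodization of the frequency-domain ramp filter: one of
#'   `"ram-lak"`, `"shepp-logan"`, `"cosine"`, `"hamming"`, `"hann"`,
#'   `"none"` (`"none"` backprojects without filtering).
#' @param frequencyCutoff cutoff as a fraction of the Nyquist frequency, in
#'   (0, 1].
#' @param outputSize side of the reconstructed square slice in pixels
#'   (default: detector width U).
#' @param rotationCenter detector column of the rotation axis (1-based,
#'   fractional; default (U+1)/2).
#' @param angularUsage `"full360"` back-projects every projection of a 360
#'   degree acquisition (conjugate rays average), `"fold360to180"` averages
#'   opposed projections into a 180 degree set first, `"native180"` uses a
#'   180 degree acquisition as-is.
#' @return A validated `fbpConfig` list.
#' @examples
#' cfg <- fbpConfig(filter = "hamming", frequencyCutoff = 0.8)
#' @export
fbpConfig <- function(filter = c("ram-lak", "shepp-logan", "cosine",
                                 "hamming", "hann", "none"),
                      frequencyCutoff = 1, outputSize = NULL,
                      rotationCenter = NULL,
                      angularUsage = c("full360", "fold360to180", "native180")) {
  filter <- match.arg(filter)
  angularUsage <- match.arg(angularUsage)
  if (!.scalarNum(frequencyCutoff) || frequencyCutoff <= 0 || frequencyCutoff > 1)
    stop("frequencyCutoff must be in (0, 1]")
  structure(list(filter = filter, frequencyCutoff = frequencyCutoff,
                 outputSize = outputSize, rotationCenter = rotationCenter,
                 angularUsage = angularUsage),
            class = "fbpConfig")
}

# Equally spaced angle vector of a Sinogram, radians.
.sinoAnglesRad <- function(sino) .deg2rad(angles(sino))

.checkEqualSpacing <- function(anglesDeg) {
  if (length(anglesDeg) >= 2L) {
    d <- diff(anglesDeg)
    if (max(abs(d - d[1])) > 1e-9 * max(1, abs(d[1])))
      stop("projection angles must be equally spaced")
  }
  invisible(TRUE)
}

#' Parallel-beam forward projection of a slice
#'
#' Computes line integrals of a square slice image along parallel rays at
#' each requested angle (the discrete Radon transform), with bilinear
#' interpolation and a detector column grid identical to the image x grid.
#'
#' @param slice square numeric matrix (row = y, column = x).
#' @param angles projection angles in degrees; must be equally spaced,
#'   start at 0 and span 180 or 360 degrees (i.e. (p-1) * range/P).
#' @param rotationCenter detector/image column of the rotation axis
#'   (default (N+1)/2).
#' @param pixelSize um/pixel recorded in the returned object.
#' @return A [Sinogram-class] (N detector columns x P angles).
#' @examples
#' img <- matrix(0, 32, 32); img[16, 16] <- 1
#' s <- forwardProject(img, angles = (0:35) * 10)
#' dim(sinogramValues(s))
#' @export
forwardProject <- function(slice, angles, rotationCenter = NULL, pixelSize = 1) {
  slice <- as.matrix(slice)
  if (nrow(slice) != ncol(slice)) stop("slice must be square")
  .checkEqualSpacing(angles)
  if (abs(angles[1]) > 1e-9) stop("first angle must be 0")
  P <- length(angles)
  span <- if (P >= 2L) P * (angles[2] - angles[1]) else 360
  range <- if (abs(span - 180) < 1e-6) 180 else if (abs(span - 360) < 1e-6) 360 else
    stop("angles must span 180 or 360 degrees")
  if (is.null(rotationCenter)) rotationCenter <- (nrow(slice) + 1) / 2
  vals <- cpp_forward_project(slice, .deg2rad(angles), rotationCenter)
  Sinogram(vals, rowIndex = 1L, angularRange = range, pixelSize = pixelSize)
}

# Frequency response of the (apodized) ramp filter, length nPad.
# The base response is the DFT of the band-limited spatial-domain ramp
# (Kak & Slaney discretization), which avoids the DC bias of sampling |f|.
.rampResponse <- function(nPad, filter, cutoff) {
  h <- numeric(nPad)
  h[1] <- 0.25
  kOdd <- seq(1L, nPad / 2, by = 2L)
  h[1 + kOdd] <- -1 / (pi^2 * kOdd^2)
  h[nPad + 1 - kOdd] <- -1 / (pi^2 * kOdd^2)
  H <- Re(fft(h))
  f <- abs(.fftfreq(nPad))          # cycles/pixel, Nyquist = 0.5
  fc <- 0.5 * cutoff
  w <- switch(filter,
    "ram-lak" = rep(1, nPad),
    "shepp-logan" = { x <- f / (2 * fc); ifelse(x == 0, 1, sin(pi * x) / (pi * x)) },
    "cosine" = cos(pi * f / (2 * fc)),
    "hamming" = 0.54 + 0.46 * cos(pi * f / fc),
    "hann" = 0.5 * (1 + cos(pi * f / fc)),
    stop("unknown filter"))
  H <- H * w
  H[f > fc] <- 0
  H
}

# Ramp-filter each projection (column of a U x P matrix) in the frequency
# domain, zero-padded to the next power of two >= 2U.
.filterProjections <- function(values, filter, cutoff) {
  if (filter == "none") return(values)
  U <- nrow(values)
  nPad <- max(64L, .nextPow2(2L * U))
  H <- .rampResponse(nPad, filter, cutoff)
  padded <- matrix(0, nPad, ncol(values))
  padded[seq_len(U), ] <- values
  filtered <- Re(mvfft(mvfft(padded) * H, inverse = TRUE)) / nPad
  filtered[seq_len(U), , drop = FALSE]
}

# Mirror a sinogram's detector axis about the rotation centre (linear
# interpolation for fractional centres).
.mirrorDetector <- function(values, center) {
  U <- nrow(values)
  u <- seq_len(U)
  um <- 2 * center - u
  u0 <- floor(um); du <- um - u0
  lo <- pmin(pmax(u0, 1L), U); hi <- pmin(pmax(u0 + 1L, 1L), U)
  inb <- u0 >= 1 & u0 + 1 <= U
  out <- values[lo, , drop = FALSE] * (1 - du) + values[hi, , drop = FALSE] * du
  out[!inb & !(um >= 1 & um <= U), ] <- 0
  out
}

# Resolve angular usage: returns list(values, anglesRad, scale).
.resolveAngularUsage <- function(values, rangeDeg, usage, center) {
  P <- ncol(values)
  if (rangeDeg == 180) {
    anglesRad <- .deg2rad((seq_len(P) - 1) * 180 / P)
    return(list(values = values, anglesRad = anglesRad, scale = pi / P))
  }
  if (usage == "fold360to180") {
    if (P %% 2L != 0L) stop("fold360to180 requires an even projection count")
    half <- P / 2L
    mirrored <- .mirrorDetector(values[, (half + 1L):P, drop = FALSE], center)
    folded <- 0.5 * (values[, seq_len(half), drop = FALSE] + mirrored)
    anglesRad <- .deg2rad((seq_len(half) - 1) * 180 / half)
    return(list(values = folded, anglesRad = anglesRad, scale = pi / half))
  }
  # full360: back-project everything; conjugate rays contribute redundantly,
  # the halved angular weight averages them.
  anglesRad <- .deg2rad((seq_len(P) - 1) * 360 / P)
  list(values = values, anglesRad = anglesRad, scale = pi / P)
}

#' Filtered back projection of one sinogram
#'
#' Ramp-filters the projections in the frequency domain (apodized according
#' to the configuration, zero-padded to at least twice the detector width)
#' and back-projects them with bilinear interpolation. The normalization is
#' the Riemann sum of the inverse Radon integral, so a calibrated phantom
#' reconstructs to its true absolute values; voxels outside the inscribed
#' circle are set to 0.
#'
#' @param sinogram a [Sinogram-class] with equally spaced angles.
#' @param config an [fbpConfig()].
#' @return Square numeric matrix of side `outputSize`.
#' @examples
#' img <- matrix(0, 64, 64); img[24:40, 24:40] <- 1
#' s <- forwardProject(img, angles = (0:89) * 4)
#' rec <- fbpSlice(s, fbpConfig())
#' @export
fbpSlice <- function(sinogram, config = fbpConfig()) {
  stopifnot(is(sinogram, "Sinogram"))
  values <- sinogramValues(sinogram)
  U <- nrow(values); P <- ncol(values)
  if (P < 2L) stop("need at least 2 projections")
  center <- if (is.null(config$rotationCenter)) (U + 1) / 2 else config$rotationCenter
  outN <- if (is.null(config$outputSize)) U else config$outputSize
  if (outN > U) stop("outputSize must be <= detector width")
  usage <- .resolveAngularUsage(values, angularRange(sinogram),
                                config$angularUsage, center)
  filtered <- .filterProjections(usage$values, config$filter,
                                 config$frequencyCutoff)
  rec <- cpp_back_project(filtered, usage$anglesRad, center, outN, TRUE)
  rec * usage$scale
}

# Working-set estimate for one slice reconstruction, bytes.
.sliceWorkBytes <- function(U, P, outN) {
  nPad <- max(64L, .nextPow2(2L * U))
  8 * (3 * nPad * P + U * P + 2 * outN^2)
}

#' Filtered back projection of a full projection stack
#'
#' Reconstructs every detector row of the stack with [fbpSlice()] into a
#' [ReconstructionVolume-class]. Rows are processed in chunks sized to a
#' memory budget; the result is bit-identical whatever the chunk size, the
#' budget only bounds the working set so volumes larger than RAM can be
#' reconstructed.
#'
#' @param stack a preprocessed [ProjectionStack-class].
#' @param config an [fbpConfig()].
#' @param maxRamBytes memory budget for the per-chunk working set.
#' @return A [ReconstructionVolume-class] with one slice per detector row.
#' @export
fbpVolume <- function(stack, config = fbpConfig(), maxRamBytes = 2^31) {
  stopifnot(is(stack, "ProjectionStack"))
  fr <- frames(stack)
  P <- dim(fr)[1]; V <- dim(fr)[2]; U <- dim(fr)[3]
  outN <- if (is.null(config$outputSize)) U else config$outputSize
  perSlice <- .sliceWorkBytes(U, P, outN)
  chunk <- floor(maxRamBytes / perSlice)
  if (chunk < 1L)
    stop(sprintf("maxRamBytes (%g) smaller than one slice's working set (%g)",
                 maxRamBytes, perSlice))
  vol <- array(0, c(V, outN, outN))
  starts <- seq(1L, V, by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, V)
    for (v in rows) {
      pv <- matrix(fr[, v, ], nrow = P, ncol = U)   # P x U
      sino <- Sinogram(t(pv), rowIndex = v,
                       angularRange = angularRange(stack),
                       pixelSize = pixelSize(stack))
      vol[v, , ] <- fbpSlice(sino, config)
    }
  }
  ReconstructionVolume(vol, voxelSize = pixelSize(stack),
                       provenance = list(method = "fbp",
                                         filter = config$filter,
                                         frequencyCutoff = config$frequencyCutoff,
                                         angularUsage = config$angularUsage,
                                         nProjections = P))
}
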