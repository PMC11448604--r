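# Focal-sweep PSF modelling, its axial projection, projection
# deconvolution, and the DOF/resolution trade-off of conventional OPT.
#
# In conventional OPT the numerical aperture is restricted so the depth of
# field covers the sample radius, which ties the achievable resolution to
# the sample size. Focal scanning breaks that trade-off by sweeping a
# shallow high-NA focal plane through the sample during each exposure; the
# recorded projections are then deconvolved with the axial projection of
# the sweep-averaged 3-D PSF before reconstruction.

#' Optics model for focal-sweep imaging
#'
#' @param na numerical aperture (0 < na < refractiveIndex).
#' @param wavelength emission wavelength, nm (300--900).
#' @param refractiveIndex immersion refractive index.
#' @param pixelSize um/pixel at the sample plane.
#' @param sweepRange focal-sweep peak-to-peak range, mm.
#' @return An `opticsModel` list; `dof` (mm) is derived as
#'   `wavelength / na^2`.
#' @export
opticsModel <- function(na, wavelength = 550, refractiveIndex = 1.0,
                        pixelSize = 1, sweepRange = 0) {
  if (!(na > 0 && na < refractiveIndex))
    stop("need 0 < na < refractiveIndex")
  if (wavelength < 300 || wavelength > 900)
    stop("wavelength must be in [300, 900] nm")
  lambdaMm <- wavelength * 1e-6
  structure(list(na = na, wavelength = wavelength,
                 refractiveIndex = refractiveIndex, pixelSize = pixelSize,
                 sweepRange = sweepRange,
                 dof = lambdaMm / na^2,
                 sigma0 = 0.21 * wavelength * 1e-3 / na,          # um
                 zR = refractiveIndex * lambdaMm / (pi * na^2)),  # mm
            class = "opticsModel")
}

#' Resolution limit of conventional fixed-focus OPT
#'
#' For a telecentric system whose depth of field is set to the sample
#' radius, `dof = lambda / NA^2` fixes the numerical aperture at
#' `NA = sqrt(lambda / dof)` and the Rayleigh resolution follows as
#' `0.61 lambda / NA`. This quantifies the resolution/sample-size
#' trade-off that focal scanning is designed to beat.
#'
#' @param dofMm required depth of field (sample radius), mm.
#' @param wavelengthNm wavelength, nm.
#' @return Resolution in micrometres.
#' @examples
#' conventionalResolutionLimit(7, 550)   # ~38 um
#' @export
conventionalResolutionLimit <- function(dofMm, wavelengthNm = 550) {
  if (dofMm <= 0 || wavelengthNm <= 0) stop("inputs must be positive")
  lambdaMm <- wavelengthNm * 1e-6
  na <- sqrt(lambdaMm / dofMm)
  0.61 * lambdaMm / na * 1000
}

#' Model the focal-sweep 3-D PSF
#'
#' Gaussian-beam approximation of the defocus series: the lateral profile
#' at depth z is a Gaussian with `sigma(z) = sigma0 sqrt(1 + (z/zR)^2)`,
#' `sigma0 = 0.21 lambda / NA` and Rayleigh range
#' `zR = n lambda / (pi NA^2)`. Each z plane is normalized to unit
#' integral and weighted by the focal-sweep dwell time, which is uniform
#' for a triangle-wave sweep cycling many times per exposure. This is a
#' parametric approximation to a full diffraction PSF model, adequate for
#' the deconvolution role.
#'
#' @param optics an [opticsModel()].
#' @param zPlanes axial sample positions in mm; must span at least the
#'   sweep range and at least one depth of focus.
#' @return 3-D array (z, y, x) with attributes `zPlanes` and `pixelSize`.
#' @export
modelPsf <- function(optics, zPlanes) {
  stopifnot(inherits(optics, "opticsModel"))
  span <- diff(range(zPlanes))
  if (span < optics$sweepRange)
    stop("zPlanes must span the sweep range")
  if (length(zPlanes) > 1L && span < optics$dof)
    stop("z range smaller than one depth of focus")
  sigmaUm <- optics$sigma0 * sqrt(1 + (zPlanes / optics$zR)^2)
  sigmaPx <- sigmaUm / optics$pixelSize
  r <- ceiling(3.5 * max(sigmaPx))
  x <- (-r):r
  psf <- array(0, c(length(zPlanes), 2 * r + 1, 2 * r + 1))
  for (i in seq_along(zPlanes)) {
    k <- exp(-x^2 / (2 * sigmaPx[i]^2))
    plane <- outer(k, k)
    psf[i, , ] <- plane / sum(plane)      # unit integral, uniform dwell
  }
  attr(psf, "zPlanes") <- zPlanes
  attr(psf, "pixelSize") <- optics$pixelSize
  psf
}

#' Project a 3-D PSF along the optical axis
#'
#' Sums the z planes and renormalizes to unit sum, giving the 2-D kernel
#' with which focal-sweep projection images are deconvolved.
#'
#' @param psf3d array from [modelPsf()] (or any (z, y, x) nonnegative
#'   array).
#' @return 2-D kernel matrix, nonnegative, sums to 1, centred.
#' @export
projectPsf <- function(psf3d) {
  if (length(dim(psf3d)) == 2L) psf3d <- array(psf3d, c(1L, dim(psf3d)))
  k <- apply(psf3d, c(2, 3), sum)
  s <- sum(k)
  if (s <= 0) stop("all-zero PSF")
  k / s
}

# Richardson-Lucy with a flux-normalization term for the zero-padded
# boundary, preserving nonnegativity and per-frame total intensity.
.richardsonLucy <- function(y, kern, iterations) {
  eps <- .Machine$double.eps
  y <- pmax(y, 0)
  norm <- .fftConv2(matrix(1, nrow(y), ncol(y)), kern, conj = TRUE)
  norm[norm < 1e-6] <- 1
  x <- y
  for (i in seq_len(iterations)) {
    est <- .fftConv2(x, kern)
    ratio <- y / pmax(est, eps)
    x <- x * .fftConv2(ratio, kern, conj = TRUE) / norm
  }
  x
}

.wienerDeconv <- function(y, kern, noisePower) {
  n <- nrow(y); m <- ncol(y)
  pn <- nextn(n + nrow(kern) - 1L, 2L); pm <- nextn(m + ncol(kern) - 1L, 2L)
  A <- matrix(0, pn, pm); A[1:n, 1:m] <- y
  K <- matrix(0, pn, pm)
  cr <- (nrow(kern) + 1L) %/% 2L; cc <- (ncol(kern) + 1L) %/% 2L
  ri <- ((seq_len(nrow(kern)) - cr) %% pn) + 1L
  ci <- ((seq_len(ncol(kern)) - cc) %% pm) + 1L
  K[ri, ci] <- kern
  H <- fft(K)
  X <- fft(A) * Conj(H) / (Mod(H)^2 + noisePower)
  out <- Re(fft(X, inverse = TRUE)) / (pn * pm)
  out[1:n, 1:m]
}

#' Deconvolve projection images with a PSF kernel
#'
#' Per-frame deconvolution of a projection stack before reconstruction.
#' Richardson-Lucy preserves nonnegativity and per-frame total intensity
#' (within 0.1%); Wiener applies the standard frequency-domain filter with
#' a noise-power parameter. Negative input values are clamped to zero for
#' Richardson-Lucy (with a warning).
#'
#' @param stack a [ProjectionStack-class].
#' @param kernel 2-D PSF kernel (unit sum), smaller than the frames; see
#'   [projectPsf()].
#' @param method `"richardson-lucy"` or `"wiener"`.
#' @param iterations Richardson-Lucy iteration count.
#' @param noisePower Wiener noise-to-signal power parameter.
#' @return The deconvolved [ProjectionStack-class].
#' @export
deconvolveProjections <- function(stack, kernel,
                                  method = c("richardson-lucy", "wiener"),
                                  iterations = 25L, noisePower = 0.01) {
  stopifnot(is(stack, "ProjectionStack"))
  method <- match.arg(method)
  kernel <- as.matrix(kernel)
  d <- dim(frames(stack))
  if (nrow(kernel) > d[2] || ncol(kernel) > d[3])
    stop("kernel larger than frame")
  if (method == "richardson-lucy" &&
      min(frames(stack)) < -1e-9 * max(abs(frames(stack))))
    warning("negative input clamped to 0 for Richardson-Lucy")
  .stackApply(stack, function(fr, p)
    if (method == "richardson-lucy") .richardsonLucy(fr, kernel, iterations)
    else .wienerDeconv(fr, kernel, noisePower))
}
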