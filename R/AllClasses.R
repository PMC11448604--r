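#' @include utils.R
NULL

# ---------------------------------------------------------------- classes --

#' ProjectionStack: an ordered set of 2-D projection images
#'
#' The raw OPT acquisition object: a 3-D intensity array indexed
#' (projection p, detector row v, detector column u) together with the
#' angular and spatial metadata needed for reconstruction. Projection p
#' (1-based) was acquired at angle \eqn{\theta_p = (p-1)\cdot
#' \mathrm{angularRange}/P} degrees, counter-clockwise when viewed down the
#' rotation axis, with the first frame at 0 degrees. The rotation axis is
#' assumed vertical in the frame, so detector rows index the axial (z)
#' direction and each row yields one independently reconstructable sinogram.
#'
#' @slot frames numeric 3-D array, dim (P, V, U); photon-count-like
#'   arbitrary units.
#' @slot angularRange numeric(1), total angular coverage in degrees
#'   (180 or 360).
#' @slot pixelSize numeric(1), micrometres per pixel at the sample plane.
#' @slot exposure numeric(1), exposure time in seconds (NA when unknown).
#' @slot wavelength numeric(1), emission wavelength in nm (NA when unknown).
#'
#' @seealso [readProjectionStack()], [extractSinogram()], [simulateProjections()]
#' @export
setClass("ProjectionStack",
  representation(frames = "array", angularRange = "numeric",
                 pixelSize = "numeric", exposure = "numeric",
                 wavelength = "numeric"),
  prototype(angularRange = 360, pixelSize = 1,
            exposure = NA_real_, wavelength = NA_real_))

setValidity("ProjectionStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-D array (P, V, U)")
  if (d[1] < 1L) return("need at least one projection")
  if (!object@angularRange %in% c(180, 360))
    return("angularRange must be 180 or 360 degrees")
  if (!.scalarNum(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar (um/pixel)")
  if (anyNA(object@frames)) return("frames contain NA")
  TRUE
})

#' Sinogram: a single detector row across all projection angles
#'
#' The x--theta dataset extracted from one detector row of a
#' [ProjectionStack-class]; the unit of 2-D slice reconstruction. Values are
#' stored as a (detector column u) x (projection p) matrix.
#'
#' @slot values numeric U x P matrix.
#' @slot rowIndex integer(1), the detector row (1-based) this sinogram came
#'   from.
#' @slot angularRange,pixelSize inherited acquisition metadata.
#' @seealso [extractSinogram()], [fbpSlice()], [twistReconstruct()]
#' @export
setClass("Sinogram",
  representation(values = "matrix", rowIndex = "integer",
                 angularRange = "numeric", pixelSize = "numeric"),
  prototype(rowIndex = 1L, angularRange = 360, pixelSize = 1))

setValidity("Sinogram", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (!object@angularRange %in% c(180, 360))
    return("angularRange must be 180 or 360 degrees")
  if (object@rowIndex < 1L) return("rowIndex must be >= 1")
  TRUE
})

#' ReconstructionVolume: a stack of reconstructed slices
#'
#' Reconstructed voxels indexed (slice z, row y, column x) with isotropic
#' in-plane voxel size and a provenance record (reconstruction method and
#' parameters).
#'
#' @slot voxels numeric 3-D array, dim (Z, N, N).
#' @slot voxelSize numeric(1), micrometres per voxel.
#' @slot provenance list; at least `method`, plus method parameters.
#' @seealso [fbpVolume()], [writeVolume()], [makePhantom()]
#' @export
setClass("ReconstructionVolume",
  representation(voxels = "array", voxelSize = "numeric", provenance = "list"),
  prototype(voxelSize = 1, provenance = list(method = "unknown")))

setValidity("ReconstructionVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3-D array (Z, Y, X)")
  if (d[2] != d[3]) return("slices must be square")
  if (!.scalarNum(object@voxelSize) || object@voxelSize <= 0)
    return("voxelSize must be positive")
  TRUE
})

#' AlignmentParams: rotation-axis offset and tilt
#'
#' Rigid description of where the rotation axis sits in the projection
#' frames: `offset` is the axis column minus the detector centre column in
#' pixels (fractional, signed), `tilt` the in-plane rotation of the axis
#' relative to the image columns in degrees.
#'
#' @slot offset numeric(1), pixels.
#' @slot tilt numeric(1), degrees.
#' @seealso [estimateAlignment()], [applyAlignment()]
#' @export
setClass("AlignmentParams",
  representation(offset = "numeric", tilt = "numeric"),
  prototype(offset = 0, tilt = 0))

setValidity("AlignmentParams", function(object) {
  if (!.scalarNum(object@offset) || !.scalarNum(object@tilt))
    return("offset and tilt must be finite scalars")
  if (abs(object@tilt) >= 10) return("|tilt| must be < 10 degrees")
  TRUE
})

#' BleachModel: per-projection photobleaching correction
#'
#' Monoexponential bleaching model in projection index (a proxy for
#' cumulative light exposure): frame p is multiplied by
#' \eqn{s_p = \exp(k\,(p-1))} to restore its pre-bleach intensity, where k
#' is the fitted per-frame decay rate. `scale` caches s_p for all frames;
#' `r2` records the goodness of the log-linear fit.
#'
#' @slot rate numeric(1), fitted decay rate k per projection index.
#' @slot scale numeric(P), multiplicative corrections, scale[1] == 1.
#' @slot r2 numeric(1), R^2 of the log-total-intensity fit.
#' @seealso [estimateBleach()], [applyBleach()]
#' @export
setClass("BleachModel",
  representation(rate = "numeric", scale = "numeric", r2 = "numeric"),
  prototype(rate = 0, scale = 1, r2 = NA_real_))

setValidity("BleachModel", function(object) {
  if (any(object@scale <= 0)) return("all scale factors must be positive")
  if (abs(object@scale[1] - 1) > 1e-12) return("scale[1] must be 1")
  TRUE
})

#' FanBeamGeometry: magnification model for non-telecentric acquisition
#'
#' Under focal scanning the magnification varies approximately linearly
#' with axial position, m(z) = m0 (1 + g z). That linear trend is the
#' first-order expansion of a fan-beam geometry whose vertex (the "source")
#' sits on the optical axis at distance D = 1/g from the rotation axis (in
#' object units). g = 0 (D = Inf) is the telecentric, parallel-beam limit.
#'
#' @slot m0 numeric(1), magnification at the rotation axis (1 when only
#'   relative calibration data are available).
#' @slot g numeric(1), relative magnification gradient per mm of depth.
#' @slot D numeric(1), fan-origin (source-to-axis) distance in mm; Inf for
#'   telecentric.
#' @slot detectorSpacing numeric(1), detector pixel spacing in um.
#' @slot calibration list; the fitted (z, size) line when produced by
#'   [calibrateMagnification()].
#' @seealso [calibrateMagnification()], [fanbeamReconstruct()],
#'   [estimateFanOrigin()]
#' @export
setClass("FanBeamGeometry",
  representation(m0 = "numeric", g = "numeric", D = "numeric",
                 detectorSpacing = "numeric", calibration = "list"),
  prototype(m0 = 1, g = 0, D = Inf, detectorSpacing = 1, calibration = list()))

setValidity("FanBeamGeometry", function(object) {
  if (object@m0 <= 0) return("m0 must be positive")
  if (is.finite(object@D) && object@D <= 0) return("D must be positive or Inf")
  if (object@g == 0 && is.finite(object@D))
    return("g = 0 requires D = Inf (telecentric)")
  TRUE
})

# ----------------------------------------------------------- constructors --

#' Construct a ProjectionStack
#'
#' @param frames numeric 3-D array (P, V, U) or a list of equally shaped
#'   V x U matrices ordered by acquisition angle.
#' @param angularRange total angular coverage in degrees (180 or 360).
#' @param pixelSize pixel size at the sample plane, um/pixel.
#' @param exposure optional exposure time, s.
#' @param wavelength optional emission wavelength, nm.
#' @return A [ProjectionStack-class] object.
#' @examples
#' st <- ProjectionStack(array(0, c(4, 8, 8)), angularRange = 360)
#' nProjections(st)
#' @export
ProjectionStack <- function(frames, angularRange, pixelSize = 1,
                            exposure = NA_real_, wavelength = NA_real_) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L)
      stop("all frames must share one (rows x columns) shape")
    arr <- array(0, c(length(frames), shapes[[1]][1], shapes[[1]][2]))
    for (p in seq_along(frames)) arr[p, , ] <- frames[[p]]
    frames <- arr
  }
  if (missing(angularRange))
    stop("angularRange is required (180 or 360 degrees); it is never defaulted")
  new("ProjectionStack", frames = frames, angularRange = angularRange,
      pixelSize = pixelSize, exposure = as.numeric(exposure),
      wavelength = as.numeric(wavelength))
}

#' Construct a Sinogram
#'
#' @param values U x P numeric matrix (detector column x projection).
#' @param rowIndex source detector row, 1-based.
#' @param angularRange angular coverage in degrees.
#' @param pixelSize um/pixel.
#' @return A [Sinogram-class] object.
#' @export
Sinogram <- function(values, rowIndex = 1L, angularRange = 360, pixelSize = 1) {
  new("Sinogram", values = as.matrix(values), rowIndex = as.integer(rowIndex),
      angularRange = angularRange, pixelSize = pixelSize)
}

#' Construct a ReconstructionVolume
#'
#' @param voxels numeric 3-D array (Z, Y, X) with square slices.
#' @param voxelSize um/voxel.
#' @param provenance list recording method and parameters.
#' @return A [ReconstructionVolume-class] object.
#' @export
ReconstructionVolume <- function(voxels, voxelSize = 1,
                                 provenance = list(method = "unknown")) {
  if (length(dim(voxels)) == 2L)
    voxels <- array(voxels, c(1L, dim(voxels)))
  new("ReconstructionVolume", voxels = voxels, voxelSize = voxelSize,
      provenance = provenance)
}

#' Construct AlignmentParams
#' @param offset axis offset in pixels (axis column minus detector centre).
#' @param tilt in-plane axis tilt in degrees.
#' @return An [AlignmentParams-class] object.
#' @export
AlignmentParams <- function(offset = 0, tilt = 0)
  new("AlignmentParams", offset = offset, tilt = tilt)

#' Construct FanBeamGeometry
#' @param D fan-origin distance in mm (Inf for telecentric).
#' @param m0 magnification at the rotation axis.
#' @param g relative magnification gradient per mm (defaults to 1/D).
#' @param detectorSpacing detector pixel spacing, um.
#' @param calibration optional calibration record.
#' @return A [FanBeamGeometry-class] object.
#' @export
FanBeamGeometry <- function(D = Inf, m0 = 1, g = if (is.finite(D)) 1 / D else 0,
                            detectorSpacing = 1, calibration = list()) {
  new("FanBeamGeometry", m0 = m0, g = g, D = D,
      detectorSpacing = detectorSpacing, calibration = calibration)
}
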