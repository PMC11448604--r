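# Generics, accessors and show methods for the core classes.

#' @name accessors
#' @title Accessors for OPTrecon data objects
#' @description Slot accessors for [ProjectionStack-class],
#'   [Sinogram-class] and [ReconstructionVolume-class]. Bioconductor-style:
#'   user code should use these rather than `@`.
#' @param object an OPTrecon data object.
#' @return The corresponding slot value; `angles()` returns the acquisition
#'   angles in degrees, derived from the frame order and angular range.
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nProjections", function(object) standardGeneric("nProjections"))
#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("angularRange", function(object) standardGeneric("angularRange"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("sinogramValues", function(object) standardGeneric("sinogramValues"))
#' @rdname accessors
#' @export
setGeneric("rowIndex", function(object) standardGeneric("rowIndex"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("frames", "ProjectionStack", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("nProjections", "ProjectionStack",
          function(object) dim(object@frames)[1])
#' @rdname accessors
#' @export
setMethod("angularRange", "ProjectionStack", function(object) object@angularRange)
#' @rdname accessors
#' @export
setMethod("angularRange", "Sinogram", function(object) object@angularRange)
#' @rdname accessors
#' @export
setMethod("angles", "ProjectionStack", function(object) {
  P <- dim(object@frames)[1]
  (seq_len(P) - 1) * object@angularRange / P
})
#' @rdname accessors
#' @export
setMethod("angles", "Sinogram", function(object) {
  P <- ncol(object@values)
  (seq_len(P) - 1) * object@angularRange / P
})
#' @rdname accessors
#' @export
setMethod("pixelSize", "ProjectionStack", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "Sinogram", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("sinogramValues", "Sinogram", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("rowIndex", "Sinogram", function(object) object@rowIndex)
#' @rdname accessors
#' @export
setMethod("voxels", "ReconstructionVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ReconstructionVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("provenance", "ReconstructionVolume", function(object) object@provenance)

#' @rdname accessors
#' @param value replacement value.
#' @export
setGeneric("pixelSize<-", function(object, value) standardGeneric("pixelSize<-"))
#' @rdname accessors
#' @export
setMethod("pixelSize<-", "ProjectionStack", function(object, value) {
  object@pixelSize <- value
  validObject(object)
  object
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ProjectionStack: %d projections of %d x %d px over %g deg\n",
              d[1], d[2], d[3], object@angularRange))
  cat(sprintf("  pixel size %g um, intensity range [%.4g, %.4g]\n",
              object@pixelSize, min(object@frames), max(object@frames)))
  if (!is.na(object@exposure))
    cat(sprintf("  exposure %g s\n", object@exposure))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: row %d, %d detector px x %d projections over %g deg\n",
              object@rowIndex, nrow(object@values), ncol(object@values),
              object@angularRange))
})

setMethod("show", "ReconstructionVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ReconstructionVolume: %d slices of %d x %d, voxel %g um\n",
              d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  method: %s\n",
              if (is.null(object@provenance$method)) "unknown"
              else object@provenance$method))
})

setMethod("show", "AlignmentParams", function(object)
  cat(sprintf("AlignmentParams: offset %.3f px, tilt %.3f deg\n",
              object@offset, object@tilt)))

setMethod("show", "BleachModel", function(object)
  cat(sprintf("BleachModel: k = %.5g per frame over %d frames (R2 = %.3f)\n",
              object@rate, length(object@scale), object@r2)))

setMethod("show", "FanBeamGeometry", function(object) {
  if (is.finite(object@D))
    cat(sprintf("FanBeamGeometry: fan origin D = %.3g mm (m0 = %.3g, g = %.3g /mm)\n",
                object@D, object@m0, object@g))
  else cat("FanBeamGeometry: telecentric (parallel-beam limit, D = Inf)\n")
})

#' Bleach-model accessors
#' @param object a [BleachModel-class].
#' @return `bleachRate`: the fitted per-frame decay rate k;
#'   `bleachScale`: the per-frame correction factors s_p.
#' @export
bleachRate <- function(object) object@rate

#' @rdname bleachRate
#' @export
bleachScale <- function(object) object@scale

#' Fan-geometry accessors
#' @param object a [FanBeamGeometry-class].
#' @return `fanOrigin`: source-to-axis distance D in mm (Inf when
#'   telecentric); `isTelecentric`: TRUE for the parallel-beam limit.
#' @export
fanOrigin <- function(object) object@D

#' @rdname fanOrigin
#' @export
isTelecentric <- function(object) !is.finite(object@D)

#' Alignment accessors
#' @param object an [AlignmentParams-class].
#' @return `axisOffset`: offset in px; `axisTilt`: tilt in degrees.
#' @export
axisOffset <- function(object) object@offset

#' @rdname axisOffset
#' @export
axisTilt <- function(object) object@tilt
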