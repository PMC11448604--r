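# Projection-stack / volume I/O and headless sinogram quality control.
#
# Formats: plain multi-page TIFF, OME-TIFF and directories of per-angle
# TIFFs for stacks; OME-TIFF and TIFF directories for volumes. OME metadata
# (PhysicalSizeX/Y/Z plus an annotation carrying the angular range and
# value scaling) is written as a companion OME-XML file next to the TIFF
# and read back from either the embedded ImageDescription (for externally
# produced OME-TIFFs) or the companion file.

.OME_NS <- "http://www.openmicroscopy.org/Schemas/OME/2016-06"

.companionPath <- function(path)
  paste0(sub("\\.ome\\.tiff?$|\\.tiff?$", "", path), ".companion.ome.xml")

# Build minimal OME-XML; extra is a named list folded into an annotation.
.omeXml <- function(sizeX, sizeY, sizeT, physicalSize, type = "float",
                    extra = list()) {
  doc <- xml2::xml_new_root("OME", xmlns = .OME_NS)
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0")
  px <- xml2::xml_add_child(img, "Pixels", ID = "Pixels:0",
    DimensionOrder = "XYZCT", Type = type,
    SizeX = as.character(sizeX), SizeY = as.character(sizeY),
    SizeZ = "1", SizeC = "1", SizeT = as.character(sizeT),
    PhysicalSizeX = format(physicalSize, digits = 17),
    PhysicalSizeY = format(physicalSize, digits = 17),
    PhysicalSizeXUnit = "µm", PhysicalSizeYUnit = "µm")
  xml2::xml_add_child(px, "TiffData")
  if (length(extra)) {
    sa <- xml2::xml_add_child(doc, "StructuredAnnotations")
    xa <- xml2::xml_add_child(sa, "XMLAnnotation", ID = "Annotation:0")
    val <- xml2::xml_add_child(xa, "Value")
    node <- xml2::xml_add_child(val, "OPTrecon")
    for (nm in names(extra))
      if (!is.na(extra[[nm]]))
        xml2::xml_set_attr(node, nm, format(extra[[nm]], digits = 17))
  }
  doc
}

# Parse OME-XML text into a metadata list (NULL fields when absent).
.parseOmeXml <- function(txt) {
  doc <- tryCatch(xml2::read_xml(txt), error = function(e) NULL)
  if (is.null(doc)) return(list())
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  out <- list()
  if (!inherits(px, "xml_missing")) {
    psx <- xml2::xml_attr(px, "PhysicalSizeX")
    if (!is.na(psx)) out$pixelSize <- as.numeric(psx)
  }
  ann <- xml2::xml_find_first(doc, ".//OPTrecon")
  if (!inherits(ann, "xml_missing")) {
    for (nm in c("angular_range", "exposure", "wavelength", "voxel_size_um",
                 "value_offset", "value_scale", "method")) {
      v <- xml2::xml_attr(ann, nm)
      if (!is.na(v))
        out[[nm]] <- if (nm == "method") v else as.numeric(v)
    }
  }
  out
}

# Read every page of a TIFF as numeric matrices holding the raw stored
# values: integer pages are un-normalized back to their 2^bits - 1 range
# (exactly), float pages are returned as stored.
.readTiffPages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (!is.null(bits) && bits <= 16L) p <- round(p * (2^bits - 1))
    p <- unclass(p)
    attributes(p) <- list(dim = dim(p))
    storage.mode(p) <- "double"
    p
  })
}

.tiffDescription <- function(path) {
  info <- tryCatch(tiff::readTIFF(path, info = TRUE, payload = FALSE),
                   error = function(e) NULL)
  if (is.null(info)) return(NULL)
  d <- attr(info, "description")
  if (is.null(d)) d <- info$description
  d
}

#' Read a projection stack
#'
#' Reads an acquisition saved as a single multi-page (OME-)TIFF or as a
#' directory of per-angle TIFFs (sorted by the last integer group in each
#' filename, matching per-frame acquisition naming). Metadata are taken
#' from OME-XML when present (embedded ImageDescription or a
#' `*.companion.ome.xml` file), with `metadataOverrides` taking precedence.
#' The angular range has no safe default and must be available from one of
#' those sources.
#'
#' @param path TIFF file or directory of TIFFs.
#' @param dialect `"auto"` (default), `"tiff"`, `"ome-tiff"` or `"dir"`.
#' @param metadataOverrides named list; recognised names: `angularRange`,
#'   `pixelSize`, `exposure`, `wavelength`.
#' @return A [ProjectionStack-class].
#' @seealso [writeProjectionStack()]
#' @export
readProjectionStack <- function(path, dialect = c("auto", "ome-tiff", "tiff", "dir"),
                                metadataOverrides = list()) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (dir.exists(path)) "dir" else "tiff"
  if (dialect == "dir") {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no TIFF files found in ", path)
    key <- .lastIntegerKey(basename(files))
    if (anyNA(key)) stop("per-angle filenames must contain an integer index")
    files <- files[order(key)]
    pages <- unlist(lapply(files, .readTiffPages), recursive = FALSE)
    desc <- NULL
    companion <- list.files(path, pattern = "\\.companion\\.ome\\.xml$",
                            full.names = TRUE)
    meta <- if (length(companion)) .parseOmeXml(paste(readLines(companion[1],
                                                                warn = FALSE),
                                                      collapse = "\n")) else list()
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    pages <- .readTiffPages(path)
    desc <- .tiffDescription(path)
    meta <- if (!is.null(desc) && nzchar(desc) && grepl("<", desc, fixed = TRUE))
      .parseOmeXml(desc) else list()
    cp <- .companionPath(path)
    if (!length(meta) && file.exists(cp))
      meta <- .parseOmeXml(paste(readLines(cp, warn = FALSE), collapse = "\n"))
  }
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L) stop("inconsistent frame shapes across projections")
  angularRange <- metadataOverrides$angularRange
  if (is.null(angularRange)) angularRange <- meta$angular_range
  if (is.null(angularRange))
    stop("angular range not present in metadata and not overridden; ",
         "pass metadataOverrides = list(angularRange = 180 or 360)")
  pixelSize <- metadataOverrides$pixelSize %||% meta$pixelSize %||% 1
  exposure <- metadataOverrides$exposure %||% meta$exposure %||% NA_real_
  wavelength <- metadataOverrides$wavelength %||% meta$wavelength %||% NA_real_
  off <- meta$value_offset %||% 0
  sc <- meta$value_scale %||% 1
  if (off != 0 || sc != 1) pages <- lapply(pages, function(p) p * sc + off)
  ProjectionStack(pages, angularRange = angularRange, pixelSize = pixelSize,
                  exposure = exposure, wavelength = wavelength)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write numeric pages; float32 TIFF requires [0,1], so affine-rescale and
# record offset/scale in the OME annotation for lossless-to-float32 reads.
.writeTiffFloat <- function(pages, path) {
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  sc <- if (hi > lo) hi - lo else 1
  scaled <- lapply(pages, function(p) (p - lo) / sc)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  list(value_offset = lo, value_scale = sc)
}

#' Write a projection stack as an OME-TIFF
#'
#' Frames are stored as 32-bit float TIFF pages (affinely rescaled to the
#' writable range; the scaling is recorded in, and undone from, the OME
#' metadata) with a companion OME-XML file carrying pixel size, angular
#' range and optional acquisition metadata, so a read-back reproduces the
#' stack to 32-bit float precision.
#'
#' @param stack a [ProjectionStack-class].
#' @param path output path (conventionally `*.ome.tiff`).
#' @return `path`, invisibly.
#' @export
writeProjectionStack <- function(stack, path) {
  stopifnot(is(stack, "ProjectionStack"))
  fr <- frames(stack)
  P <- dim(fr)[1]
  pages <- lapply(seq_len(P), function(p) matrix(fr[p, , ], dim(fr)[2], dim(fr)[3]))
  scaling <- .writeTiffFloat(pages, path)
  doc <- .omeXml(dim(fr)[3], dim(fr)[2], P, pixelSize(stack),
                 extra = c(list(angular_range = angularRange(stack),
                                exposure = stack@exposure,
                                wavelength = stack@wavelength), scaling))
  xml2::write_xml(doc, .companionPath(path))
  invisible(path)
}

#' Write a reconstruction volume
#'
#' Supported formats: `"ome-tiff"` (single multi-page float TIFF plus
#' companion OME-XML storing the voxel size, method and value scaling) and
#' `"tiff-stack"` (a directory of per-slice TIFFs with the same companion
#' metadata). Integer-valued volumes within the 16-bit range are stored as
#' uint16 and round-trip bit-exactly; other data round-trip to 32-bit float
#' precision.
#'
#' @param volume a [ReconstructionVolume-class].
#' @param path output file (ome-tiff) or directory (tiff-stack).
#' @param format `"ome-tiff"` or `"tiff-stack"`.
#' @return `path`, invisibly.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(volume, path, format = c("ome-tiff", "tiff-stack")) {
  stopifnot(is(volume, "ReconstructionVolume"))
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unsupported format token: ", format[1]))
  vx <- voxels(volume)
  if (dim(vx)[1] < 1L) stop("cannot write an empty volume (0 slices)")
  slices <- lapply(seq_len(dim(vx)[1]),
                   function(z) matrix(vx[z, , ], dim(vx)[2], dim(vx)[3]))
  isInt <- all(vx == round(vx)) && min(vx) >= 0 && max(vx) <= 65535
  writeOne <- function(pages, fpath) {
    if (isInt) {
      # stored as uint16; .readTiffPages recovers the integers exactly
      tiff::writeTIFF(lapply(pages, function(p) p / 65535), fpath,
                      bits.per.sample = 16L, compression = "none")
      list(value_offset = 0, value_scale = 1)
    } else .writeTiffFloat(pages, fpath)
  }
  meta <- list(voxel_size_um = voxelSize(volume),
               method = provenance(volume)$method %||% "unknown")
  if (format == "ome-tiff") {
    scaling <- writeOne(slices, path)
    doc <- .omeXml(dim(vx)[3], dim(vx)[2], dim(vx)[1], voxelSize(volume),
                   type = if (isInt) "uint16" else "float",
                   extra = c(meta, scaling))
    xml2::write_xml(doc, .companionPath(path))
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    width <- max(4L, nchar(length(slices)))
    scaling <- NULL
    for (z in seq_along(slices)) {
      fpath <- file.path(path, sprintf(paste0("slice_%0", width, "d.tif"), z - 1L))
      scaling <- writeOne(slices[z], fpath)
    }
    doc <- .omeXml(dim(vx)[3], dim(vx)[2], dim(vx)[1], voxelSize(volume),
                   type = if (isInt) "uint16" else "float",
                   extra = c(meta, scaling))
    xml2::write_xml(doc, file.path(path, "volume.companion.ome.xml"))
  }
  invisible(path)
}

#' Read back a reconstruction volume written by [writeVolume()]
#'
#' @param path file or directory produced by [writeVolume()].
#' @return A [ReconstructionVolume-class].
#' @export
readVolume <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(.lastIntegerKey(basename(files)))]
    pages <- unlist(lapply(files, .readTiffPages), recursive = FALSE)
    metaFile <- file.path(path, "volume.companion.ome.xml")
  } else {
    pages <- .readTiffPages(path)
    metaFile <- .companionPath(path)
  }
  meta <- if (file.exists(metaFile))
    .parseOmeXml(paste(readLines(metaFile, warn = FALSE), collapse = "\n"))
  else list()
  off <- meta$value_offset %||% 0
  sc <- meta$value_scale %||% 1
  vx <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) vx[z, , ] <- pages[[z]] * sc + off
  ReconstructionVolume(vx, voxelSize = meta$voxel_size_um %||% 1,
                       provenance = list(method = meta$method %||% "unknown"))
}

# Note on the 16-bit path: values are written as v/65535 and read back with
# as.is = TRUE, which recovers the original integers exactly.

#' Extract the sinogram of one detector row
#'
#' @param stack a [ProjectionStack-class].
#' @param rowIndex detector row, 1-based, in `[1, V]`.
#' @return A [Sinogram-class] with `values[u, p] = frames[p, rowIndex, u]`.
#' @export
extractSinogram <- function(stack, rowIndex) {
  stopifnot(is(stack, "ProjectionStack"))
  d <- dim(frames(stack))
  if (!.isCount(rowIndex) || rowIndex > d[2])
    stop("rowIndex out of range [1, ", d[2], "]")
  vals <- t(matrix(frames(stack)[, rowIndex, ], d[1], d[3]))
  Sinogram(vals, rowIndex = as.integer(rowIndex),
           angularRange = angularRange(stack), pixelSize = pixelSize(stack))
}

# Intensity centroid column of each projection in a U x P sinogram; NA for
# empty projections.
.sinoCentroids <- function(values) {
  u <- seq_len(nrow(values))
  tot <- colSums(values)
  cent <- colSums(values * u) / tot
  cent[tot <= 0] <- NA_real_
  cent
}

#' Headless sinogram quality check
#'
#' Screens an acquisition for the defects visible in sinograms right after
#' acquisition: saturated detector rows, dead rows and discontinuities in
#' the sinogram trace (e.g. skipped or shuffled frames, sample movement).
#' The continuity score of a row is the mean absolute shift of the
#' intensity centroid between adjacent projections, in pixels; it is a
#' package-defined surrogate for visual sinogram inspection, not a
#' published criterion.
#'
#' @param stack a [ProjectionStack-class].
#' @param saturationValue detector saturation level in frame units.
#' @param thresholds list with `saturationFraction` (max tolerated fraction
#'   of saturated pixels per row) and `continuity` (max tolerated mean
#'   centroid shift, px).
#' @return A `qcReport` list: per-row data frame (`saturationFraction`,
#'   `deadRow`, `continuityScore`, `rowPass`), per-frame saturation
#'   fractions, and a global `pass` flag. Deterministic in its inputs.
#' @export
qcCheck <- function(stack, saturationValue = 65535,
                    thresholds = list(saturationFraction = 0.01, continuity = 2)) {
  stopifnot(is(stack, "ProjectionStack"))
  fr <- frames(stack)
  P <- dim(fr)[1]; V <- dim(fr)[2]; U <- dim(fr)[3]
  satRow <- numeric(V); dead <- logical(V); cont <- numeric(V)
  for (v in seq_len(V)) {
    m <- t(matrix(fr[, v, ], P, U))           # U x P
    satRow[v] <- mean(m >= saturationValue)
    dead[v] <- all(m == 0)
    cent <- .sinoCentroids(m)
    dif <- abs(diff(cent))
    cont[v] <- if (all(is.na(dif))) 0 else mean(dif, na.rm = TRUE)
  }
  satFrame <- vapply(seq_len(P), function(p) mean(fr[p, , ] >= saturationValue),
                     numeric(1))
  rowPass <- satRow <= thresholds$saturationFraction &
    cont <= thresholds$continuity
  flagged <- which(satFrame > thresholds$saturationFraction)
  structure(list(
    rows = data.frame(row = seq_len(V), saturationFraction = satRow,
                      deadRow = dead, continuityScore = cont,
                      rowPass = rowPass),
    frameSaturation = satFrame,
    flaggedFrames = flagged,
    pass = all(rowPass) && length(flagged) == 0L), class = "qcReport")
}

#' @export
print.qcReport <- function(x, ...) {
  cat(sprintf("Sinogram QC: %s (%d/%d rows pass)\n",
              if (x$pass) "PASS" else "FAIL",
              sum(x$rows$rowPass), nrow(x$rows)))
  cat(sprintf("  max row saturation %.3g, max continuity score %.3g px\n",
              max(x$rows$saturationFraction), max(x$rows$continuityScore)))
  if (length(x$flaggedFrames))
    cat("  saturated frames:", paste(head(x$flaggedFrames, 10), collapse = ", "),
        "\n")
  invisible(x)
}
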