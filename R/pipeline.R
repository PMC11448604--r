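# Config-driven pipeline: simulate -> preprocess -> reconstruct (fbp |
# twist | fanbeam) -> evaluate, with a reproducibility manifest. This is
# the programmatic core behind the `optrecon` command-line script shipped
# in inst/scripts/.

.pipelineSeed <- function(globalSeed, stepIndex)
  (as.integer(globalSeed) * 1000L + stepIndex) %% .Machine$integer.max

.manifestEntry <- function(name, params, outputs) {
  sums <- if (length(outputs)) {
    files <- unlist(lapply(outputs, function(o)
      if (dir.exists(o)) list.files(o, full.names = TRUE, recursive = TRUE) else o))
    as.list(tools::md5sum(sort(files[file.exists(files)])))
  } else list()
  list(step = name, params = params, checksums = sums)
}

#' Run a reconstruction pipeline from a configuration
#'
#' Executes an ordered list of steps, each writing its outputs under the
#' configured output directory, and records a manifest (step parameters
#' and MD5 checksums of every output file). Identical configuration and
#' inputs give identical manifest checksums; every stochastic step derives
#' its seed deterministically from the global seed.
#'
#' Recognised steps and their parameters:
#' \describe{
#'   \item{simulate}{phantom parameters (see [phantomSpec()]); writes
#'     `truth.ome.tiff`, `beads.csv`, `stack.ome.tiff`.}
#'   \item{preprocess}{`input` stack; optional `flatField`, `hotPixel`,
#'     `bleach`, `align`, `downsample` blocks; writes
#'     `preprocessed.ome.tiff`.}
#'   \item{fbp}{`input` stack, [fbpConfig()] fields, `maxRamBytes`; writes
#'     `fbp.ome.tiff`.}
#'   \item{twist}{`input` stack, `row`, [twistConfig()] fields, optional
#'     `subset`; writes `twist_row<row>.ome.tiff`.}
#'   \item{fanbeam}{`input` stack, `row`, `D` (mm) or `calib` CSV of
#'     `z_mm,size_px`; writes `fanbeam_row<row>.ome.tiff`.}
#'   \item{deconv}{`input` stack, optics fields, `method`, `iterations`;
#'     writes `deconvolved.ome.tiff`.}
#'   \item{evaluate}{`input` volume, optional `truth` volume and `beads`
#'     CSV; writes `report.json` with SSIM and bead statistics.}
#' }
#'
#' @param config path to a YAML file or an equivalent list with fields
#'   `seed`, `outDir` and `steps` (a list of named step blocks, each with
#'   a `step` field).
#' @return List with `status` (0 on success), `manifest`, and the manifest
#'   file path. The manifest is also written as `manifest.json`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  outDir <- config$outDir %||% "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  steps <- config$steps %||% list()
  manifest <- list()
  loadStack <- function(params) {
    ov <- list(angularRange = params$angularRange)
    ov <- ov[!vapply(ov, is.null, logical(1))]
    readProjectionStack(params$input, metadataOverrides = ov)
  }
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    name <- st$step
    if (is.null(name)) stop("step ", i, ": missing 'step' field")
    outputs <- character(0)
    res <- tryCatch(switch(name,
      simulate = {
        sp <- do.call(phantomSpec, c(
          st[setdiff(names(st), c("step"))],
          if (is.null(st$seed)) list(seed = .pipelineSeed(seed, i))))
        ph <- makePhantom(sp)
        tPath <- file.path(outDir, "truth.ome.tiff")
        writeVolume(ph$truth, tPath)
        bPath <- file.path(outDir, "beads.csv")
        utils::write.csv(ph$beads, bPath, row.names = FALSE)
        sPath <- file.path(outDir, "stack.ome.tiff")
        writeProjectionStack(simulateProjections(ph$truth, sp), sPath)
        outputs <- c(tPath, .companionPath(tPath), bPath, sPath,
                     .companionPath(sPath))
        NULL
      },
      preprocess = {
        stk <- loadStack(st)
        if (!is.null(st$flatField))
          stk <- flatFieldCorrect(stk,
            .readTiffPages(st$flatField$background)[[1]],
            if (!is.null(st$flatField$offset))
              .readTiffPages(st$flatField$offset)[[1]] else NULL)
        if (isTRUE(st$hotPixel$enabled) || !is.null(st$hotPixel))
          stk <- hotPixelFilter(stk,
            window = st$hotPixel$window %||% 3L,
            thresholdSigmas = st$hotPixel$thresholdSigmas %||% 5)
        if (isTRUE(st$bleach)) stk <- applyBleach(stk, estimateBleach(stk))
        if (isTRUE(st$align)) stk <- applyAlignment(stk, estimateAlignment(stk))
        if (!is.null(st$downsample) && st$downsample > 1L)
          stk <- downsampleStack(stk, st$downsample)
        oPath <- file.path(outDir, "preprocessed.ome.tiff")
        writeProjectionStack(stk, oPath)
        outputs <- c(oPath, .companionPath(oPath))
        NULL
      },
      fbp = {
        stk <- loadStack(st)
        cfg <- fbpConfig(filter = st$filter %||% "ram-lak",
                         frequencyCutoff = st$frequencyCutoff %||% 1,
                         rotationCenter = st$rotationCenter)
        vol <- fbpVolume(stk, cfg, maxRamBytes = st$maxRamBytes %||% 2^31)
        oPath <- file.path(outDir, "fbp.ome.tiff")
        writeVolume(vol, oPath)
        outputs <- c(oPath, .companionPath(oPath))
        NULL
      },
      twist = {
        stk <- loadStack(st)
        if (!is.null(st$subset)) stk <- subsetProjections(stk, st$subset)
        row <- st$row %||% 1L
        cfg <- twistConfig(lambda = st$lambda,
                           maxIters = st$maxIters %||% 200L,
                           tol = st$tol %||% 1e-4)
        rec <- twistReconstruct(extractSinogram(stk, row), cfg)
        vol <- ReconstructionVolume(array(rec, c(1L, dim(rec))),
                                    voxelSize = pixelSize(stk),
                                    provenance = list(method = "twist"))
        oPath <- file.path(outDir, sprintf("twist_row%d.ome.tiff", row))
        writeVolume(vol, oPath)
        outputs <- c(oPath, .companionPath(oPath))
        NULL
      },
      fanbeam = {
        stk <- loadStack(st)
        row <- st$row %||% 1L
        geom <- if (!is.null(st$calib))
          calibrateMagnification(utils::read.csv(st$calib))
        else FanBeamGeometry(D = st$D %||% Inf)
        rec <- fanbeamReconstruct(extractSinogram(stk, row), geom,
                                  fbpConfig(filter = st$filter %||% "ram-lak"))
        vol <- ReconstructionVolume(array(rec, c(1L, dim(rec))),
                                    voxelSize = pixelSize(stk),
                                    provenance = list(method = "fanbeam"))
        oPath <- file.path(outDir, sprintf("fanbeam_row%d.ome.tiff", row))
        writeVolume(vol, oPath)
        outputs <- c(oPath, .companionPath(oPath))
        NULL
      },
      deconv = {
        stk <- loadStack(st)
        om <- opticsModel(na = st$na %||% 0.02,
                          wavelength = st$wavelength %||% 550,
                          pixelSize = pixelSize(stk),
                          sweepRange = st$sweep %||% 0)
        zr <- max(om$sweepRange, om$dof) / 2
        kern <- projectPsf(modelPsf(om, seq(-zr, zr, length.out = 21)))
        stk <- deconvolveProjections(stk, kern,
                                     method = st$method %||% "richardson-lucy",
                                     iterations = st$iterations %||% 25L)
        oPath <- file.path(outDir, "deconvolved.ome.tiff")
        writeProjectionStack(stk, oPath)
        outputs <- c(oPath, .companionPath(oPath))
        NULL
      },
      evaluate = {
        vol <- readVolume(st$input)
        report <- list(nSlices = dim(voxels(vol))[1])
        mip <- maxIntensityProjection(vol)
        if (!is.null(st$truth)) {
          tr <- readVolume(st$truth)
          report$ssim <- ssim(mip, maxIntensityProjection(tr))
        }
        beads <- detectAndFitBeads(mip,
          detectionThreshold = st$detectionThreshold %||% 5)
        report$nBeadsDetected <- nrow(beads)
        if (nrow(beads)) report$meanFwhmPx <- mean(beads$fwhm)
        oPath <- file.path(outDir, "report.json")
        jsonlite::write_json(report, oPath, auto_unbox = TRUE, digits = NA)
        outputs <- oPath
        NULL
      },
      stop("unknown step: ", name)
    ), error = function(e)
      stop("step ", i, " (", name, "): ", conditionMessage(e), call. = FALSE))
    manifest[[i]] <- .manifestEntry(name, st[setdiff(names(st), "step")],
                                    outputs)
  }
  mPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, digits = NA)
  list(status = 0L, manifest = manifest, manifestPath = mPath)
}
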