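Package: OPTrecon
Title: Optical Projection Tomography Reconstruction and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstruction stack for fluorescence optical projection
    tomography (OPT). Reads and writes projection stacks and volumes
    (OME-TIFF, TIFF), provides the standard pre-reconstruction pipeline
    (flat-field and offset correction, hot-pixel median filtering,
    downsampling, photobleaching compensation, automatic rotation-axis
    alignment), parallel-beam filtered back projection with selectable
    frequency filters and RAM-bounded chunking, compressive-sensing
    reconstruction of undersampled sinograms by two-step iterative
    shrinkage/thresholding (TwIST) with total-variation regularization,
    fan-beam filtered back projection for non-telecentric focal-scanning
    acquisitions with magnification calibration and empirical fan-origin
    estimation, focal-sweep PSF modelling and projection deconvolution,
    ground-truthed bead/vessel/disc phantom simulation, and quantitative
    evaluation (SSIM, bead detection and FWHM fitting, resolution maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    xml2,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'OPTrecon-package.R'
    'RcppExports.R'
    'focal_psf.R'
    'io_stack.R'
    'metrics.R'
    'phantom.R'
    'pipeline.R'
    'preprocess.R'
    'recon_fanbeam.R'
    'recon_parallel.R'
    'recon_twist.R'
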