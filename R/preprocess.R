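# Pre-reconstruction pipeline: illumination/offset correction, hot-pixel
# removal, downsampling, photobleaching compensation and rotation-axis
# alignment. Every operation is pure and preserves stack shape/metadata,
# except downsampling which changes the documented fields only. The
# documented default order is flat-field -> hot-pixel -> bleach -> align ->
# downsample.

.stackApply <- function(stack, f) {
  fr <- frames(stack)
  out <- fr
  for (p in seq_len(dim(fr)[1]))
    out[p, , ] <- f(matrix(fr[p, , ], dim(fr)[2], dim(fr)[3]), p)
  initialize(stack, frames = out)
}

#' Flat-field and offset correction
#'
#' Corrects uneven illumination and detector offset using user-supplied
#' background (illumination) and offset (dark) images:
#' `frame' = (frame - offset) / (background - offset) * mean(background -
#' offset)`, with negative results clamped to 0. The mean-gain factor keeps
#' the corrected frames on the original intensity scale.
#'
#' @param stack a [ProjectionStack-class].
#' @param backgroundFrame V x U illumination image.
#' @param offsetFrame V x U dark image (default all zeros).
#' @return The corrected [ProjectionStack-class].
#' @export
flatFieldCorrect <- function(stack, backgroundFrame, offsetFrame = NULL) {
  stopifnot(is(stack, "ProjectionStack"))
  d <- dim(frames(stack))[2:3]
  backgroundFrame <- as.matrix(backgroundFrame)
  if (is.null(offsetFrame)) offsetFrame <- matrix(0, d[1], d[2])
  offsetFrame <- as.matrix(offsetFrame)
  if (!identical(dim(backgroundFrame), d) || !identical(dim(offsetFrame), d))
    stop("background/offset frame shape does not match the stack frames")
  gain <- backgroundFrame - offsetFrame
  bad <- mean(gain <= 0)
  if (bad > 0.01)
    stop(sprintf("background <= offset over %.1f%% of pixels", 100 * bad))
  gain[gain <= 0] <- min(gain[gain > 0])
  norm <- mean(gain)
  .stackApply(stack, function(fr, p) {
    out <- (fr - offsetFrame) / gain * norm
    out[out < 0] <- 0
    out
  })
}

# Window median of a matrix with edge replication.
.windowMedian <- function(m, window) {
  r <- (window - 1L) %/% 2L
  n <- nrow(m); mm <- ncol(m)
  if (window > n || window > mm) stop("window larger than frame")
  pad <- m[c(rep(1L, r), seq_len(n), rep(n, r)),
           c(rep(1L, r), seq_len(mm), rep(mm, r)), drop = FALSE]
  shifts <- expand.grid(dy = 0:(window - 1L), dx = 0:(window - 1L))
  cols <- lapply(seq_len(nrow(shifts)), function(s)
    as.vector(pad[shifts$dy[s] + seq_len(n), shifts$dx[s] + seq_len(mm),
                  drop = FALSE]))
  med <- if (length(cols) == 9L) .median9(cols)
         else .rowMedians(do.call(cbind, cols))
  matrix(med, n, mm)
}

#' Hot/stuck pixel removal by thresholded median filtering
#'
#' Replaces only defective pixels: a pixel deviating from its window median
#' by more than `thresholdSigmas` robust standard deviations (per-frame MAD
#' of the median residuals, scaled by 1.4826) is set to that median; all
#' other pixels are untouched.
#'
#' @param stack a [ProjectionStack-class].
#' @param window odd window side, >= 3.
#' @param thresholdSigmas detection threshold in robust sigmas.
#' @return The filtered [ProjectionStack-class].
#' @export
hotPixelFilter <- function(stack, window = 3L, thresholdSigmas = 5) {
  stopifnot(is(stack, "ProjectionStack"))
  if (!.isCount(window) || window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  .stackApply(stack, function(fr, p) {
    med <- .windowMedian(fr, window)
    res <- fr - med
    sig <- .robustSigma(as.vector(res))
    hot <- abs(res) > thresholdSigmas * sig
    fr[hot] <- med[hot]
    fr
  })
}

#' Downsample a projection stack by mean binning
#'
#' Bins each frame by `factor` x `factor` averaging (after cropping to the
#' largest region divisible by the factor, reported via a message) and
#' scales the pixel size accordingly.
#'
#' @param stack a [ProjectionStack-class].
#' @param factor integer binning factor >= 1.
#' @return The downsampled [ProjectionStack-class] with
#'   `pixelSize * factor`.
#' @export
downsampleStack <- function(stack, factor) {
  stopifnot(is(stack, "ProjectionStack"))
  if (!.isCount(factor)) stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(stack)
  fr <- frames(stack)
  P <- dim(fr)[1]; V <- dim(fr)[2]; U <- dim(fr)[3]
  V2 <- (V %/% factor) * factor; U2 <- (U %/% factor) * factor
  if (V2 < V || U2 < U)
    message(sprintf("cropping frames from %dx%d to %dx%d for factor %d",
                    V, U, V2, U2, factor))
  out <- array(0, c(P, V2 %/% factor, U2 %/% factor))
  for (p in seq_len(P)) {
    m <- matrix(fr[p, seq_len(V2), seq_len(U2)], V2, U2)
    binned <- rowsum(m, rep(seq_len(V2 %/% factor), each = factor))
    binned <- t(rowsum(t(binned), rep(seq_len(U2 %/% factor), each = factor)))
    out[p, , ] <- binned / factor^2
  }
  st <- initialize(stack, frames = out)
  st@pixelSize <- pixelSize(stack) * factor
  validObject(st)
  st
}

#' Estimate a photobleaching model from frame totals
#'
#' Fits the log of the per-frame total intensity (of pixels above a
#' background percentile) to a line in projection index by least squares,
#' giving the monoexponential decay rate k and the per-frame multiplicative
#' corrections `s_p = exp(k (p-1))`.
#'
#' @param stack a [ProjectionStack-class] with P >= 3.
#' @param backgroundPercentile pixels at or below this per-frame quantile
#'   are excluded from the totals (default 0.1).
#' @return A [BleachModel-class] with fitted rate and R^2 diagnostic.
#' @export
estimateBleach <- function(stack, backgroundPercentile = 0.1) {
  stopifnot(is(stack, "ProjectionStack"))
  fr <- frames(stack)
  P <- dim(fr)[1]
  if (P < 3L) stop("need at least 3 projections to fit a bleaching trend")
  totals <- vapply(seq_len(P), function(p) {
    f <- fr[p, , ]
    thr <- quantile(f, backgroundPercentile)
    sum(f[f >= thr])
  }, numeric(1))
  if (any(totals <= 0)) stop("nonpositive frame totals; cannot fit bleaching")
  idx <- seq_len(P) - 1
  fit <- lm(log(totals) ~ idx)
  b <- unname(coef(fit)[2])
  k <- -b
  # R^2 computed directly; summary.lm warns on numerically perfect fits
  ss <- sum((log(totals) - mean(log(totals)))^2)
  r2 <- if (ss > 0) 1 - sum(fit$residuals^2) / ss else 1
  new("BleachModel", rate = k, scale = exp(k * idx), r2 = r2)
}

#' Apply a photobleaching correction
#'
#' Multiplies frame p by the model's correction factor `s_p`.
#'
#' @param stack a [ProjectionStack-class].
#' @param model a [BleachModel-class] with one factor per projection.
#' @return The corrected [ProjectionStack-class].
#' @export
applyBleach <- function(stack, model) {
  stopifnot(is(stack, "ProjectionStack"), is(model, "BleachModel"))
  P <- dim(frames(stack))[1]
  if (length(model@scale) != P)
    stop("model length (", length(model@scale), ") != projection count (", P, ")")
  .stackApply(stack, function(fr, p) fr * model@scale[p])
}

# Cross-spectrum of two (mean-subtracted, zero-padded) profiles; lags are
# recovered from an accumulated spectrum so correlations average cleanly
# over projection pairs.
.xspec <- function(a, b, nPad) {
  A <- fft(c(a - mean(a), numeric(nPad - length(a))))
  B <- fft(c(b - mean(b), numeric(nPad - length(b))))
  A * Conj(B)
}

# Sub-pixel correlation lag from an accumulated cross-spectrum, by
# frequency-domain zero-padding (x`up` correlation upsampling) plus a final
# parabolic refinement; unbiased for broad correlation peaks where a plain
# 3-point parabola is not.
.profileLag <- function(spec, maxLag, up = 16L) {
  n <- length(spec)
  N <- n * up
  S <- complex(N)
  half <- n %/% 2L
  S[1:half] <- spec[1:half]
  S[(N - half + 2L):N] <- spec[(half + 2L):n]
  S[half + 1L] <- 0.5 * spec[half + 1L]
  S[N - half + 1L] <- 0.5 * Conj(spec[half + 1L])
  cc <- Re(fft(S, inverse = TRUE)) / n
  lags <- .fftfreq(N) * N / up
  keep <- abs(lags) <= maxLag
  cc <- cc[keep]; lg <- lags[keep]
  o <- order(lg)
  cc <- cc[o]; lg <- lg[o]
  i <- which.max(cc)
  lg[1] + (.parabolicPeak(cc, i) - 1) / up
}

#' Automatic rotation-axis alignment from opposed projections
#'
#' For a 360-degree acquisition, the projection at theta and the
#' column-mirrored projection at theta + 180 are identical images shifted
#' by twice the axis offset. The offset is estimated from the peak of their
#' cross-correlation (averaged over opposed pairs, sub-pixel by parabolic
#' interpolation) and the axis tilt from the linear trend of per-row-band
#' offsets down the frame.
#'
#' @param stack a [ProjectionStack-class] with `angularRange == 360` and an
#'   even number of projections. 180-degree data carry no opposed pairs;
#'   an error asks for manual alignment in that case.
#' @param nPairs number of opposed pairs to average (>= 8 recommended).
#' @param nBands number of row bands for the tilt fit.
#' @param maxRefine refinement passes: because an axis tilt mixes detector
#'   rows between the opposed frames, a single correlation pass carries a
#'   small multiplicative bias; re-estimating on the corrected stack and
#'   accumulating removes it.
#' @return An [AlignmentParams-class].
#' @seealso [applyAlignment()]
#' @export
estimateAlignment <- function(stack, nPairs = 8L, nBands = 8L, maxRefine = 3L) {
  stopifnot(is(stack, "ProjectionStack"))
  if (angularRange(stack) != 360)
    stop("automatic alignment needs 360-degree data (opposed projections); ",
         "supply AlignmentParams manually for 180-degree acquisitions")
  total <- c(0, 0)
  for (pass in seq_len(max(1L, maxRefine))) {
    est <- .alignmentPass(stack, nPairs, nBands)
    total <- total + est
    if (abs(est[1]) < 0.05 && abs(est[2]) < 0.02) break
    if (pass < maxRefine)
      stack <- applyAlignment(stack, AlignmentParams(est[1], est[2]))
  }
  AlignmentParams(offset = total[1], tilt = total[2])
}

# One opposed-pair correlation pass; returns c(offset, tilt).
.alignmentPass <- function(stack, nPairs, nBands) {
  fr <- frames(stack)
  P <- dim(fr)[1]; V <- dim(fr)[2]; U <- dim(fr)[3]
  if (P %% 2L != 0L) stop("projection count must be even")
  half <- P %/% 2L
  pairIdx <- unique(round(seq(1L, half, length.out = min(nPairs, half))))
  nPad <- .nextPow2(2L * U)
  maxLag <- floor(U / 2) - 1L
  bandBreaks <- floor(seq(0L, V, length.out = nBands + 1L))
  bandRows <- lapply(seq_len(nBands), function(b)
    (bandBreaks[b] + 1L):bandBreaks[b + 1L])
  bandCC <- vector("list", nBands)
  globalCC <- complex(nPad)
  for (p in pairIdx) {
    A <- matrix(fr[p, , ], V, U)
    B <- matrix(fr[p + half, , ], V, U)
    Bm <- B[, U:1, drop = FALSE]            # mirror about (U+1)/2
    globalCC <- globalCC + .xspec(colMeans(A), colMeans(Bm), nPad)
    for (b in seq_len(nBands)) {
      rows <- bandRows[[b]]
      bandCC[[b]] <- (if (is.null(bandCC[[b]])) 0 else bandCC[[b]]) +
        .xspec(colMeans(A[rows, , drop = FALSE]),
               colMeans(Bm[rows, , drop = FALSE]), nPad)
    }
  }
  lag <- .profileLag(globalCC, maxLag)
  offset <- lag / 2
  bandLag <- vapply(bandCC, .profileLag, numeric(1), maxLag = maxLag)
  bandMid <- vapply(bandRows, function(r) mean(r), numeric(1))
  bandW <- vapply(bandRows, function(r) sum(abs(fr[pairIdx[1], r, ])), numeric(1))
  keep <- bandW > 0.01 * max(bandW)
  tilt <- 0
  if (sum(keep) >= 3L) {
    fit <- lm(I(bandLag[keep] / 2) ~ bandMid[keep], weights = bandW[keep])
    slope <- unname(coef(fit)[2])           # d(offset)/d(row)
    tilt <- -atan(slope) * 180 / pi
  }
  c(offset, tilt)
}

#' Apply rotation-axis alignment to a stack
#'
#' Translates each frame by `-offset` pixels along the detector axis and
#' rotates it by `-tilt` degrees about the frame centre (bilinear
#' interpolation, zero fill), undoing the misalignment described by the
#' parameters.
#'
#' @param stack a [ProjectionStack-class].
#' @param params an [AlignmentParams-class].
#' @return The aligned [ProjectionStack-class].
#' @export
applyAlignment <- function(stack, params) {
  stopifnot(is(stack, "ProjectionStack"), is(params, "AlignmentParams"))
  if (abs(params@offset) >= dim(frames(stack))[3] / 2)
    stop("|offset| must be < U/2")
  if (params@offset == 0 && params@tilt == 0) return(stack)
  phi <- .deg2rad(params@tilt)
  .stackApply(stack, function(fr, p)
    cpp_warp_rigid(fr, params@offset, 0, phi))
}
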