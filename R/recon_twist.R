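# Compressive-sensing reconstruction of undersampled sinograms by two-step
# iterative shrinkage/thresholding (TwIST) with isotropic total-variation
# regularization. The objective is
#     1/2 ||y - A x||^2 + lambda TV(x)
# with A the parallel-beam forward projector and A^T its exact adjoint
# (unfiltered backprojection transpose). A is normalized by its largest
# singular value (seeded power iteration) so the two-step relaxation
# parameters can be derived from an assumed spectrum of A^T A.

#' TwIST configuration
#'
#' @param lambda regularization weight (>= 0), or `NULL` for the
#'   scale-invariant per-slice default `0.01 * max|A^T y|` (computed after
#'   operator normalization).
#' @param alpha,beta two-step relaxation parameters; defaults derived from
#'   an assumed spectral interval `[xi1, 1]` of the normalized `A^T A`:
#'   `rho = (1 - sqrt(xi1)) / (1 + sqrt(xi1))`, `alpha = rho^2 + 1`,
#'   `beta = 2 alpha / (1 + xi1)`.
#' @param xi1 assumed smallest eigenvalue of the normalized `A^T A`.
#' @param maxIters iteration cap.
#' @param tol stop when the relative objective decrease falls below this.
#' @param tvInnerIters iterations of the dual (Chambolle) TV denoiser.
#' @param nonnegativity clamp iterates to >= 0 (fluorescence is
#'   nonnegative).
#' @param warmStart `"fbp"` (Hamming-filtered FBP, deterministic) or
#'   `"zero"`.
#' @param powerIters seeded power iterations for the operator norm.
#' @return A validated `twistConfig` list.
#' @export
twistConfig <- function(lambda = NULL, alpha = NULL, beta = NULL, xi1 = 1e-3,
                        maxIters = 200L, tol = 1e-4, tvInnerIters = 10L,
                        nonnegativity = TRUE,
                        warmStart = c("fbp", "zero"), powerIters = 20L) {
  warmStart <- match.arg(warmStart)
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0")
  if (tol <= 0) stop("tol must be > 0")
  rho <- (1 - sqrt(xi1)) / (1 + sqrt(xi1))
  if (is.null(alpha)) alpha <- rho^2 + 1
  if (is.null(beta)) beta <- 2 * alpha / (1 + xi1)
  if (beta <= 0) stop("beta must be > 0")
  structure(list(lambda = lambda, alpha = alpha, beta = beta, xi1 = xi1,
                 maxIters = as.integer(maxIters), tol = tol,
                 tvInnerIters = as.integer(tvInnerIters),
                 nonnegativity = isTRUE(nonnegativity),
                 warmStart = warmStart, powerIters = as.integer(powerIters)),
            class = "twistConfig")
}

# Isotropic total variation of an image (forward differences, edge
# replication).
.tvNorm <- function(x) {
  dx <- cbind(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE], 0)
  dy <- rbind(x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE], 0)
  sum(sqrt(dx^2 + dy^2))
}

# Proximal operator of lambda*TV via Chambolle's (2004) dual projection
# algorithm with a fixed iteration count; solves
# argmin_u 1/2 ||u - x||^2 + lambda TV(u).
.tvDenoise <- function(x, lambda, iters, tau = 0.248) {
  if (lambda <= 0 || iters < 1L) return(x)
  n <- nrow(x); m <- ncol(x)
  p1 <- matrix(0, n, m); p2 <- matrix(0, n, m)
  for (it in seq_len(iters)) {
    # divergence of p
    div <- p1 - rbind(0, p1[-n, , drop = FALSE]) +
           p2 - cbind(0, p2[, -m, drop = FALSE])
    u <- x - lambda * div
    # dual ascent on u/lambda keeps the step stable for any lambda
    gx <- rbind(u[-1, , drop = FALSE] - u[-n, , drop = FALSE], 0) / lambda
    gy <- cbind(u[, -1, drop = FALSE] - u[, -m, drop = FALSE], 0) / lambda
    p1n <- p1 - tau * gx
    p2n <- p2 - tau * gy
    den <- 1 + tau * sqrt(gx^2 + gy^2)
    p1 <- p1n / den
    p2 <- p2n / den
  }
  div <- p1 - rbind(0, p1[-n, , drop = FALSE]) +
         p2 - cbind(0, p2[, -m, drop = FALSE])
  x - lambda * div
}

# Largest singular value of the projector by power iteration (seeded).
.operatorNorm <- function(n, anglesRad, center, iters, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * n), n, n)
  x <- x / sqrt(sum(x^2))
  s <- 1
  for (i in seq_len(iters)) {
    Ax <- cpp_forward_project(x, anglesRad, center)
    x <- cpp_back_project_adjoint(Ax, anglesRad, center, n)
    nx <- sqrt(sum(x^2))
    s <- sqrt(nx)                     # ||A||^2 ~ eigenvalue of A^T A
    x <- x / nx
  }
  s
}

#' TwIST reconstruction of a sinogram
#'
#' Minimizes `1/2 ||y - A x||^2 + lambda TV(x)` by the two-step iterative
#' shrinkage/thresholding scheme
#' `x_{t+1} = (1 - alpha) x_{t-1} + (alpha - beta) x_t +
#'  beta Psi_lambda(x_t + A^T (y - A x_t))`,
#' where `Psi_lambda` is an isotropic TV proximal denoiser followed by an
#' optional nonnegativity clamp. A monotone variant is used: a step whose
#' objective increases is retried as a plain IST step; if the objective
#' still increases for 10 consecutive accepted steps the reconstruction
#' aborts with a diagnostic. Intended for sparse (undersampled) angular
#' sets where filtered back projection shows streak artifacts.
#'
#' @param sinogram a [Sinogram-class] with equally spaced angles.
#' @param config a [twistConfig()].
#' @param init optional initial image (square matrix); overrides the
#'   configured warm start.
#' @return The reconstructed slice (square matrix) with attributes
#'   `objective` (the recorded objective trace), `iterations`, and
#'   `lambda` (the value actually used, after operator normalization).
#' @export
twistReconstruct <- function(sinogram, config = twistConfig(), init = NULL) {
  stopifnot(is(sinogram, "Sinogram"))
  y0 <- sinogramValues(sinogram)
  U <- nrow(y0)
  anglesRad <- .sinoAnglesRad(sinogram)
  center <- (U + 1) / 2
  sNorm <- .operatorNorm(U, anglesRad, center, config$powerIters)
  A <- function(x) cpp_forward_project(x, anglesRad, center) / sNorm
  At <- function(r) cpp_back_project_adjoint(r, anglesRad, center, U) / sNorm
  y <- y0 / sNorm
  Aty <- At(y)
  lambda <- config$lambda %||% (0.01 * max(abs(Aty)))
  psi <- function(x) {
    x <- .tvDenoise(x, lambda, config$tvInnerIters)
    if (config$nonnegativity) x[x < 0] <- 0
    x
  }
  objective <- function(x, Ax) 0.5 * sum((y - Ax)^2) + lambda * .tvNorm(x)
  x <- if (!is.null(init)) as.matrix(init)
       else if (config$warmStart == "fbp")
         fbpSlice(sinogram, fbpConfig(filter = "hamming"))
       else matrix(0, U, U)
  if (config$nonnegativity) x[x < 0] <- 0
  xPrev <- x
  Ax <- A(x)
  obj <- objective(x, Ax)
  trace <- obj
  badRun <- 0L
  iters <- 0L
  for (t in seq_len(config$maxIters)) {
    iters <- t
    grad <- At(y - Ax)
    xDen <- psi(x + grad)
    xNew <- (1 - config$alpha) * xPrev + (config$alpha - config$beta) * x +
      config$beta * xDen
    if (config$nonnegativity) xNew[xNew < 0] <- 0
    AxNew <- A(xNew)
    objNew <- objective(xNew, AxNew)
    if (!is.finite(objNew))
      stop("TwIST diverged: non-finite objective (check alpha/beta/lambda)")
    if (objNew > obj && t > 1L) {
      # monotone fallback: retry as a plain IST step
      xNew <- xDen
      AxNew <- A(xNew)
      objNew <- objective(xNew, AxNew)
      if (objNew > obj * (1 + 1e-9)) {
        badRun <- badRun + 1L
        if (badRun >= 10L)
          stop("TwIST diverged: objective increased for 10 consecutive steps ",
               sprintf("(last objective %.6g)", objNew))
        # no descent within the accuracy of the inexact TV prox: keep the
        # previous iterate (monotone trace) and stop
        break
      }
    }
    badRun <- 0L
    relDec <- (obj - objNew) / max(obj, .Machine$double.eps)
    xPrev <- x; x <- xNew; Ax <- AxNew; obj <- objNew
    trace <- c(trace, obj)
    if (t > 2L && relDec >= 0 && relDec < config$tol) break
  }
  structure(x, objective = trace, iterations = iters, lambda = lambda)
}

#' Forward/adjoint consistency check
#'
#' Verifies that the backprojection used as the TwIST gradient is the true
#' adjoint of the forward projector by the dot-product test
#' `<A x, y> == <x, A^T y>` over random pairs.
#'
#' @param shape image side (<= 64 recommended).
#' @param angles projection angles in degrees.
#' @param seed RNG seed for the random pairs.
#' @param nPairs number of random pairs.
#' @return Maximum relative error `|<Ax,y> - <x,A^T y>| / (||Ax|| ||y||)`
#'   over the pairs.
#' @export
adjointConsistencyCheck <- function(shape = 32L, angles = (0:15) * 22.5,
                                    seed = 0L, nPairs = 10L) {
  set.seed(seed)
  anglesRad <- .deg2rad(angles)
  center <- (shape + 1) / 2
  errs <- vapply(seq_len(nPairs), function(i) {
    x <- matrix(rnorm(shape^2), shape, shape)
    y <- matrix(rnorm(shape * length(angles)), shape, length(angles))
    Ax <- cpp_forward_project(x, anglesRad, center)
    Aty <- cpp_back_project_adjoint(y, anglesRad, center, as.integer(shape))
    abs(sum(Ax * y) - sum(x * Aty)) /
      (sqrt(sum(Ax^2)) * sqrt(sum(y^2)))
  }, numeric(1))
  max(errs)
}

#' Keep an equally spaced angular subset of a stack or sinogram
#'
#' Emulates sparse acquisition by keeping `keep` equally spaced projections
#' out of P (P must be divisible by `keep`).
#'
#' @param x a [ProjectionStack-class] or [Sinogram-class].
#' @param keep number of projections to keep.
#' @return Object of the same class with `keep` projections.
#' @export
subsetProjections <- function(x, keep) {
  if (is(x, "Sinogram")) {
    P <- ncol(sinogramValues(x))
    if (P %% keep != 0L) stop("keep must divide the projection count")
    idx <- seq(1L, P, by = P %/% keep)
    return(Sinogram(sinogramValues(x)[, idx, drop = FALSE],
                    rowIndex = rowIndex(x), angularRange = angularRange(x),
                    pixelSize = pixelSize(x)))
  }
  stopifnot(is(x, "ProjectionStack"))
  P <- dim(frames(x))[1]
  if (P %% keep != 0L) stop("keep must divide the projection count")
  idx <- seq(1L, P, by = P %/% keep)
  initialize(x, frames = frames(x)[idx, , , drop = FALSE])
}
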