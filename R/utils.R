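# Internal numerical helpers shared across modules.

.deg2rad <- function(x) x * pi / 180

.nextPow2 <- function(n) 2^ceiling(log2(n))

# FFT sample frequencies in cycles/sample, numpy fftfreq layout.
.fftfreq <- function(n) {
  if (n %% 2 == 0) c(0:(n / 2 - 1), -(n / 2):-1) / n
  else c(0:((n - 1) / 2), -((n - 1) / 2):-1) / n
}

# Sub-sample peak position from three samples around an interior maximum.
.parabolicPeak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(i)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(i)
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

# Median of nine equal-length vectors by a minimax exchange network;
# vectorised replacement for apply(..., median) in the 3x3 hot-pixel filter.
.median9 <- function(v) {
  stopifnot(length(v) == 9L)
  ex <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  ex(2, 3); ex(5, 6); ex(8, 9)
  ex(1, 2); ex(4, 5); ex(7, 8)
  ex(2, 3); ex(5, 6); ex(8, 9)
  ex(1, 4); ex(6, 9); ex(5, 8)
  ex(4, 7); ex(2, 5); ex(3, 6)
  ex(5, 8); ex(3, 5); ex(5, 7); ex(3, 5)
  v[[5]]
}

# Row-wise median of a numeric matrix with an odd number of columns.
.rowMedians <- function(M) {
  m <- ncol(M)
  if (m == 9L) return(.median9(lapply(seq_len(9L), function(j) M[, j])))
  apply(M, 1L, median)
}

.robustSigma <- function(residuals) 1.4826 * median(abs(residuals))

# 1-D Gaussian kernel, unit sum.
.gaussKernel1d <- function(sigma, radius = ceiling(3.5 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution keeping only the fully supported ("valid")
# interior; used by the SSIM local statistics.
.sepConvValid <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  stopifnot(n > 2 * r, m > 2 * r)
  # rows
  out <- matrix(0, n - 2 * r, m)
  for (s in seq_along(k)) out <- out + k[s] * img[s:(n - 2 * r + s - 1L), , drop = FALSE]
  # columns
  out2 <- matrix(0, n - 2 * r, m - 2 * r)
  for (s in seq_along(k)) out2 <- out2 + k[s] * out[, s:(m - 2 * r + s - 1L), drop = FALSE]
  out2
}

# Linear (non-circular) 2-D convolution of an image with a centred odd-sized
# kernel, same-size output, zero boundary; FFT-based.
.fftConv2 <- function(img, kern, conj = FALSE) {
  n <- nrow(img); m <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  pn <- nextn(n + kr - 1L, 2L); pm <- nextn(m + kc - 1L, 2L)
  A <- matrix(0, pn, pm); A[1:n, 1:m] <- img
  # embed kernel with its centre at (1,1), wrapped
  K <- matrix(0, pn, pm)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  ri <- ((seq_len(kr) - cr) %% pn) + 1L
  ci <- ((seq_len(kc) - cc) %% pm) + 1L
  K[ri, ci] <- kern
  FK <- fft(K)
  if (conj) FK <- Conj(FK)
  out <- Re(fft(fft(A) * FK, inverse = TRUE)) / (pn * pm)
  out[1:n, 1:m]
}

# Last integer group in a string; filename sort key for per-angle TIFFs.
.lastIntegerKey <- function(x) {
  m <- regmatches(x, gregexpr("[0-9]+", x))
  vapply(m, function(g) if (length(g)) as.numeric(g[length(g)]) else NA_real_,
         numeric(1))
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
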