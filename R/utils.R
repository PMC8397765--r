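# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("tomoqc_validation_error", "tomoqc_error")))
}

stop_computation <- function(...) {
  stop(errorCondition(paste0(...), class = c("tomoqc_computation_error", "tomoqc_error")))
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (strict && x <= min) stop_validation(name, " must be > ", min, " (got ", x, ")")
  if (!strict && x < min) stop_validation(name, " must be >= ", min, " (got ", x, ")")
  invisible(x)
}

# Mirror (symmetric) index reflection: 1..n extended as  2 1 | 1 2 .. n | n n-1
reflect_index <- function(i, n) {
  i <- i - 1L
  p <- 2L * n
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - 1L - i, i) + 1L
}

# Dense band matrix applying a discrete Gaussian of sd `sigma` (in samples)
# along a dimension of length n, with symmetric boundary reflection.
# Kernel is symmetric and reflection is measure-preserving, so both row and
# column sums are 1: the blur is an exact mean-preserving averaging operator.
gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (m in -r:r) {
    j <- reflect_index(idx + m, n)
    K[cbind(idx, j)] <- K[cbind(idx, j)] + w[m + r + 1L]
  }
  K
}

# Separable Gaussian blur of a 2D matrix or 3D array; sigma in voxels
# (scalar, applied isotropically). Symmetric boundary condition.
gauss_blur <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  if (is.null(d)) stop_validation("gauss_blur expects a matrix or 3D array")
  if (length(d) == 2L) {
    K1 <- gauss_kernel_matrix(d[1L], sigma)
    K2 <- gauss_kernel_matrix(d[2L], sigma)
    return(K1 %*% a %*% t(K2))
  }
  if (length(d) != 3L) stop_validation("gauss_blur expects a matrix or 3D array")
  # dim 1
  K <- gauss_kernel_matrix(d[1L], sigma)
  a <- array(K %*% matrix(a, d[1L], d[2L] * d[3L]), d)
  # dim 2
  K <- gauss_kernel_matrix(d[2L], sigma)
  a <- aperm(a, c(2L, 1L, 3L))
  a <- array(K %*% matrix(a, d[2L], d[1L] * d[3L]), c(d[2L], d[1L], d[3L]))
  a <- aperm(a, c(2L, 1L, 3L))
  # dim 3
  K <- gauss_kernel_matrix(d[3L], sigma)
  a <- aperm(a, c(3L, 1L, 2L))
  a <- array(K %*% matrix(a, d[3L], d[1L] * d[2L]), c(d[3L], d[1L], d[2L]))
  aperm(a, c(2L, 3L, 1L))
}

# FFT sample frequencies (cycles per physical unit), numpy fftfreq layout.
fft_freq <- function(n, d = 1) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k / (n * d)
}

# Histogram with `bins` equal-width bins spanning [lo, hi]; returns counts,
# bin upper edges and midpoints. Values at lo fall in bin 1, at hi in bin `bins`.
hist_fixed <- function(x, bins = 256L, lo = min(x), hi = max(x)) {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop_computation("degenerate histogram: data range is empty or constant")
  }
  b <- pmin(pmax(floor((x - lo) / (hi - lo) * bins) + 1L, 1L), bins)
  counts <- tabulate(b, nbins = bins)
  edges <- lo + (hi - lo) * seq_len(bins) / bins
  mids <- edges - (hi - lo) / (2 * bins)
  list(counts = counts, upper = edges, mids = mids, lo = lo, hi = hi,
       width = (hi - lo) / bins, bin = b)
}

# Multi-class Otsu on a fixed histogram: maximizes between-class variance
# over all threshold placements. k = 2 gives the classic single threshold,
# k = 3 a (t_low, t_high) pair. Thresholds are reported as bin upper edges;
# ties resolved toward the smallest thresholds (deterministic).
otsu_from_hist <- function(counts, mids, k = 2L) {
  n <- length(counts)
  tot <- sum(counts)
  if (tot == 0) stop_computation("degenerate histogram: no counts")
  p <- counts / tot
  if (sum(p > 0) < k) {
    stop_computation("degenerate histogram: fewer than ", k, " occupied gray levels")
  }
  W <- cumsum(p)
  M <- cumsum(p * mids)
  if (k == 2L) {
    w1 <- W[-n]
    m1 <- M[-n]
    valid <- w1 > 0 & w1 < 1
    # between-class variance: w1*w2*(mu1-mu2)^2 = (M_T*w1 - m1)^2/(w1*(1-w1))
    bcv <- rep(-Inf, n - 1L)
    bcv[valid] <- (M[n] * w1[valid] - m1[valid])^2 / (w1[valid] * (1 - w1[valid]))
    t1 <- which.max(bcv)
    return(t1)
  }
  if (k == 3L) {
    # vectorized over threshold pairs (t1 < t2), t in 1..n-1
    w1 <- W
    m1 <- M
    res <- -Inf
    best <- c(NA_integer_, NA_integer_)
    muT <- M[n]
    for (t1 in 1:(n - 2L)) {
      if (W[t1] <= 0) next
      t2 <- (t1 + 1L):(n - 1L)
      wA <- W[t1]
      wB <- W[t2] - W[t1]
      wC <- 1 - W[t2]
      ok <- wB > 0 & wC > 0
      if (!any(ok)) next
      mA <- M[t1] / wA
      mB <- (M[t2] - M[t1]) / wB
      mC <- (muT - M[t2]) / wC
      bcv <- wA * (mA - muT)^2 + wB * (mB - muT)^2 + wC * (mC - muT)^2
      bcv[!ok] <- -Inf
      j <- which.max(bcv)
      if (bcv[j] > res) {
        res <- bcv[j]
        best <- c(t1, t2[j])
      }
    }
    if (!is.finite(res)) stop_computation("degenerate histogram: no valid 3-class split")
    return(best)
  }
  stop_validation("k must be 2 or 3")
}

#' Otsu thresholds on a fixed 256-bin histogram
#'
#' Computes the threshold (`k = 2`) or threshold pair (`k = 3`) maximizing
#' the between-class variance of the gray-value histogram, binned into
#' `bins` equal-width bins spanning the data range. A fixed binning makes
#' the result deterministic and directly comparable with exhaustive
#' threshold searches on the same histogram.
#'
#' @param x numeric vector or array of gray values.
#' @param k number of classes, 2 or 3.
#' @param bins number of histogram bins (default 256).
#' @return numeric vector of `k - 1` thresholds in gray units (bin upper
#'   edges), increasing.
#' @examples
#' x <- c(rnorm(500, 0, 0.1), rnorm(500, 1, 0.1))
#' otsu_thresholds(x, k = 2)
#' @export
otsu_thresholds <- function(x, k = 2L, bins = 256L) {
  h <- hist_fixed(as.numeric(x), bins = bins)
  idx <- otsu_from_hist(h$counts, h$mids, k = as.integer(k))
  h$upper[idx]
}

# Evaluate an expression with a temporarily fixed RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
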