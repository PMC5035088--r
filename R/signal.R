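#' @title 1D signal primitives for profile-based image analysis
#' @description
#' All structure, channel and cell detection in the pipeline operates on 1D
#' mean-intensity profiles rather than on full 2D images. This file collects
#' the shared primitives: profile extraction, Hamming-window smoothing,
#' cross-correlation lag estimation, dominant-frequency (period) estimation
#' and Otsu thresholding.
#'
#' Images are stored as plain numeric matrices indexed `I[y, x]`, i.e. rows
#' are image rows (y), columns are image columns (x). Pixel coordinates
#' reported by the pipeline are 0-based, half-open `[top, bottom)`.
#' @name signal-core
NULL

#' Mean intensity profile of an image
#'
#' The horizontal profile `h(x)` is the mean over all rows of each column;
#' the vertical profile `v(y)` is the mean over all columns of each row.
#' These profiles carry the full structural information needed for
#' registration and channel detection of a comb-like device layout.
#'
#' @param image numeric matrix `I[y, x]`.
#' @param axis `"horizontal"` (length `W`) or `"vertical"` (length `H`).
#' @return numeric vector with attributes `axis` and `origin` (0-based pixel
#'   offset of the first element in the source image).
#' @export
mean_profile <- function(image, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (!is.matrix(image) || any(dim(image) == 0L))
    stop("`image` must be a non-empty matrix")
  v <- if (axis == "horizontal") colMeans(image) else rowMeans(image)
  structure(as.numeric(v), axis = axis, origin = 0L)
}

#' Normalised Hamming window
#'
#' Coefficients `0.54 - 0.46 * cos(2*pi*k/(M-1))`, `k = 0..M-1`, scaled to
#' unit sum so that convolution preserves constant signals.
#'
#' @param m window length (positive integer).
#' @return numeric vector of length `m` summing to 1.
#' @keywords internal
hamming_window <- function(m) {
  m <- as.integer(m)
  if (m < 1L) stop("window length must be >= 1")
  if (m == 1L) return(1)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(m - 1L)) / (m - 1L))
  w / sum(w)
}

#' Smooth a profile with a normalised Hamming window
#'
#' Convolution with a unit-sum Hamming window; boundaries are handled by
#' reflection (mirroring without repeating the edge sample) so that the
#' output has the same length as the input and no edge droop is introduced
#' that could fake extrema in cell detection.
#'
#' @param x numeric vector.
#' @param window_len window length, `1 <= window_len <= length(x)`.
#' @return smoothed numeric vector, same length as `x`.
#' @export
smooth_profile <- function(x, window_len) {
  x <- as.numeric(x)
  n <- length(x)
  window_len <- as.integer(window_len)
  if (window_len < 1L || window_len > n)
    stop("`window_len` must be in [1, length(x)]")
  if (window_len == 1L) return(x)
  w <- hamming_window(window_len)
  pl <- (window_len - 1L) %/% 2L
  pr <- window_len - 1L - pl
  left <- if (pl > 0L) x[(pl + 1L):2L] else numeric(0)
  right <- if (pr > 0L) x[(n - 1L):(n - pr)] else numeric(0)
  xp <- c(left, x, right)
  # full linear convolution, then take the n central samples
  z <- stats::convolve(xp, rev(w), type = "open")
  z[(window_len):(window_len + n - 1L)]
}

#' Lag of maximal cross-correlation between two equal-length signals
#'
#' Computes the linear (zero-padded, mean-subtracted) cross-correlation of
#' `a` against `b` via FFT and returns the lag at which it peaks. The sign
#' convention is that a positive shift means `b` is displaced in the +x
#' direction relative to `a`, i.e. `b[x] ~ a[x - shift]`.
#'
#' Ties are broken towards the smallest-magnitude lag (then towards the
#' positive lag). Flat (zero-variance) inputs are degenerate: the function
#' returns 0 with attribute `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param lag_range optional integer vector `c(lo, hi)` restricting the
#'   search to lags in `[lo, hi]`.
#' @return integer lag, with attribute `degenerate` (logical).
#' @export
xcorr_argmax <- function(a, b, lag_range = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (n != length(b)) stop("`a` and `b` must have equal length")
  if (n < 2L) stop("signals must have length >= 2")
  a0 <- a - mean(a); b0 <- b - mean(b)
  if (all(a0 == 0) || all(b0 == 0)) {
    return(structure(0L, degenerate = TRUE))
  }
  nfft <- 2L^ceiling(log2(2L * n - 1L))
  A <- stats::fft(c(a0, numeric(nfft - n)))
  B <- stats::fft(c(b0, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / nfft
  lags <- c(0L:(n - 1L), (-(n - 1L)):(-1L))
  vals <- cc[c(1L:n, (nfft - n + 2L):nfft)]
  if (!is.null(lag_range)) {
    keep <- lags >= lag_range[1] & lags <= lag_range[2]
    if (!any(keep)) stop("empty lag range")
    lags <- lags[keep]; vals <- vals[keep]
  }
  o <- order(abs(lags), -sign(lags))
  lags <- lags[o]; vals <- vals[o]
  structure(lags[which.max(vals)], degenerate = FALSE)
}

# Cross-correlation lag with parabolic sub-sample refinement of the peak.
# Integer lags are fine for registration, but the rotation angle divides a
# lag by the strip width, so quantisation of +/-0.5 px would limit angular
# resolution; fitting a parabola through the peak and its neighbours
# recovers the fractional peak position.
xcorr_lag_refined <- function(a, b, max_lag = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  if (all(a0 == 0) || all(b0 == 0)) return(structure(0, degenerate = TRUE))
  nfft <- 2L^ceiling(log2(2L * n - 1L))
  A <- stats::fft(c(a0, numeric(nfft - n)))
  B <- stats::fft(c(b0, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(A) * B, inverse = TRUE)) / nfft
  lags <- c(0L:(n - 1L), (-(n - 1L)):(-1L))
  vals <- cc[c(1L:n, (nfft - n + 2L):nfft)]
  o <- order(lags)
  lags <- lags[o]; vals <- vals[o]
  if (!is.null(max_lag)) {
    keep <- abs(lags) <= max_lag
    lags <- lags[keep]; vals <- vals[keep]
  }
  i <- which.max(vals)
  if (i > 1L && i < length(vals)) {
    y1 <- vals[i - 1L]; y2 <- vals[i]; y3 <- vals[i + 1L]
    den <- y1 - 2 * y2 + y3
    delta <- if (den != 0) max(-0.5, min(0.5, 0.5 * (y1 - y3) / den)) else 0
    structure(lags[i] + delta, degenerate = FALSE)
  } else structure(as.numeric(lags[i]), degenerate = FALSE)
}

#' Dominant period of a profile
#'
#' Power spectrum of the mean-subtracted profile; the strongest non-DC peak
#' with period at most `length/2` is located and refined to sub-bin
#' precision by parabolic interpolation over three bins. Used to measure the
#' channel interval of the periodic device structure; periodicity detection
#' in the frequency domain is insensitive to smooth illumination gradients.
#'
#' @param x numeric vector, length >= 8.
#' @return list with `period_px` (pixels) and `power` (peak spectral power).
#' @export
dominant_frequency <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("profile too short for spectral estimation")
  x0 <- x - mean(x)
  p <- Mod(stats::fft(x0))^2
  # frequency index k (0-based); restrict to period <= n/2 i.e. k >= 2
  ks <- 2L:(n %/% 2L)
  pk <- p[ks + 1L]
  i <- which.max(pk)
  k <- ks[i]
  # parabolic refinement over (k-1, k, k+1)
  y1 <- p[k]; y2 <- p[k + 1L]; y3 <- p[k + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  list(period_px = n / (k + delta), power = as.numeric(y2))
}

#' Otsu threshold of an intensity collection
#'
#' Maximises the inter-class variance over a 256-bin histogram spanning the
#' observed intensity range. Returns the boundary intensity separating the
#' two classes (values strictly below the threshold are the dark class).
#'
#' @param values numeric vector or matrix with at least two distinct values.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2]) stop("constant input: Otsu threshold undefined")
  nbins <- 256L
  h <- tabulate(pmin(nbins, 1L + floor((v - r[1]) / (r[2] - r[1]) * nbins)),
                nbins = nbins)
  w <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * (r[2] - r[1])
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  # inter-class variance for split after bin t (classes 1..t | t+1..n)
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[-nbins]
  # ties (an empty intensity gap admits many optimal splits): take the
  # middle so the threshold keeps the largest margin to both classes
  t_ties <- which(sb >= max(sb) - 1e-10 * abs(max(sb)))
  t_star <- t_ties[ceiling(length(t_ties) / 2)]
  r[1] + t_star / nbins * (r[2] - r[1])
}
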