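# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#'
#' @param x angles in degrees.
#' @return angles mapped into `[0, 360)`.
#' @export
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Wrap into (-180, 180]; used by the peak/trough categorizer.
wrap180 <- function(x) {
  w <- wrap360(x)
  ifelse(w > 180, w - 360, w)
}

# Linear convolution via FFT, full length (length(x) + length(h) - 1).
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                       stats::fft(c(h, rep(0, nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Centered ("same") convolution with an odd-length symmetric kernel: the
# output sample k lines up with input sample k, so a linear-phase FIR kernel
# applied this way introduces no delay.
conv_same <- function(x, h) {
  gd <- (length(h) - 1L) %/% 2L
  full <- fft_conv(x, h)
  full[(gd + 1L):(gd + length(x))]
}

# Reflect-pad a signal at both ends by `l` samples (edge mirror).
reflect_pad <- function(x, l) {
  n <- length(x)
  l <- min(l, n - 1L)
  c(x[(l + 1L):2L], x, x[(n - 1L):(n - l)])
}

# Centered moving average over an odd window of k samples.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  h <- rep(1 / k, k)
  l <- (k - 1L) %/% 2L
  xp <- reflect_pad(x, l)
  conv_same(xp, h)[(l + 1L):(l + length(x))]
}

# Analytic signal via the frequency-domain Hilbert transformer.
analytic_signal <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(f * h, inverse = TRUE) / n
}

# Runs of TRUE in a logical vector as (start, end) sample indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Vectorized membership of points in a union of closed intervals: merge
# overlapping intervals, then a point is inside iff it has passed more
# starts than ends.
in_intervals <- function(x, lo, hi) {
  if (!length(lo)) return(rep(FALSE, length(x)))
  o <- order(lo)
  lo <- lo[o]; hi <- cummax(hi[o])
  keep <- c(TRUE, lo[-1] > hi[-length(hi)])
  ends <- c(which(keep)[-1] - 1L, length(hi))  # last member of each group
  lo <- lo[keep]
  hi <- hi[ends]
  findInterval(x, lo) > findInterval(x, hi, left.open = TRUE)
}
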