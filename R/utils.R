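`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal computed through the FFT (Hilbert
#' transform). Used as the instantaneous-amplitude stage before the
#' Savitzky-Golay / moving-mean smoothing chain.
#'
#' @param x numeric vector.
#' @return envelope vector, same length as `x`, non-negative.
#' @keywords internal
hilbert_envelope <- function(x) {
  n0 <- length(x)
  # reflect-pad to a 2-3-5-smooth length: mixed-radix FFTs degrade to
  # O(n^2) when the length has a large prime factor
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, rev(x)[seq_len(n - n0)])
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)[seq_len(n0)]
}

# centered moving average with edge shrinkage
movmean <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2 == 0) w <- w + 1L
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  # fill edges with partial-window means
  half <- (w - 1L) / 2L
  n <- length(x)
  for (i in seq_len(min(half, n))) {
    y[i] <- mean(x[1:min(n, i + half)])
    y[n - i + 1] <- mean(x[max(1, n - i + 1 - half):n])
  }
  as.numeric(y)
}

# band power of a trace by periodogram integration, f in Hz
# (zero-padded to a 2-3-5-smooth length; see hilbert_envelope)
band_power <- function(x, rate, band) {
  x <- x - mean(x)
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  sp <- Mod(stats::fft(x))[1:floor(n / 2)]^2 / n0
  f <- (seq_len(floor(n / 2)) - 1) * rate / n
  sum(sp[f >= band[1] & f <= band[2]])
}

# Rational resampling by p/q with exact group-delay compensation:
# upsample (zero insertion), symmetric FIR low-pass, downsample. The
# symmetric filter's delay is (ntaps-1)/2 samples and is removed exactly,
# so output sample k sits at input time (k-1)*q/p + 1 with no residual
# fractional shift (peak-centering depends on this alignment).
resample_trace <- function(x, p, q) {
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  if (p == 1 && q == 1) return(x)
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1, length(up), by = p)] <- x
  ntaps <- 20 * max(p, q) + 1
  h <- p * signal::fir1(ntaps - 1, 1 / max(p, q))
  pad <- numeric(ntaps)
  y <- stats::filter(c(pad, up, pad), as.numeric(h), sides = 1)
  delay <- (ntaps - 1) / 2
  y <- as.numeric(y[(ntaps + delay + 1):(ntaps + delay + length(up))])
  y[seq(1, length(y), by = q)]
}

# farthest-point (maxmin) subsample indices
maxmin_subsample <- function(X, m, start = 1L) {
  n <- nrow(X)
  if (m >= n) return(seq_len(n))
  sel <- integer(m)
  sel[1] <- start
  dmin <- colSums((t(X) - X[start, ])^2)
  for (i in 2:m) {
    sel[i] <- which.max(dmin)
    dmin <- pmin(dmin, colSums((t(X) - X[sel[i], ])^2))
  }
  sel
}

# extract the event x sample matrix from a ripple_cloud or plain matrix
cloud_matrix <- function(cloud) {
  if (inherits(cloud, "ripple_cloud")) cloud$X else as.matrix(cloud)
}
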