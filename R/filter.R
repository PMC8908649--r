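# Zero-phase Butterworth band-pass filtering.
#
# Implemented from first principles (analog Butterworth prototype,
# lowpass-to-bandpass transform, bilinear transform with frequency
# pre-warping) because no DSP library is assumed.  Coefficients agree
# with the standard scipy/Matlab `butter` design to machine precision.

# polynomial coefficients (descending powers) from complex roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Butterworth band-pass coefficients
#'
#' Designs a digital Butterworth band-pass filter of prototype order
#' `order` (so `2 * order` poles) via the bilinear transform with
#' frequency pre-warping.
#'
#' @param low_hz,high_hz pass-band edges in Hz.
#' @param fs sampling frequency in Hz.
#' @param order lowpass prototype order (default 4; the band-pass filter
#'   then has 8 poles).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low_hz, high_hz, fs, order = 4L) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop_wmhnet(sprintf(
      "band edges must satisfy 0 < low < high < Nyquist = %.4g Hz (TR = %.4g s)",
      nyq, 1 / fs))
  fs2 <- 2 * fs
  W1 <- fs2 * tan(pi * low_hz / fs)
  W2 <- fs2 * tan(pi * high_hz / fs)
  Bw <- W2 - W1
  W0 <- sqrt(W1 * W2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles <- unlist(lapply(proto, function(p) {
    disc <- sqrt((Bw * p)^2 - 4 * W0^2)
    c((Bw * p + disc) / 2, (Bw * p - disc) / 2)
  }))
  zeros <- rep(0 + 0i, order)
  gain <- Bw^order
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- (fs2 + zeros) / (fs2 - zeros)
  gain_d <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zz <- c(zz, rep(-1 + 0i, length(poles) - length(zeros)))
  list(b = Re(poly_from_roots(zz)) * gain_d,
       a = Re(poly_from_roots(zp)))
}

# steady-state initial filter delays for a unit step (suppresses the
# start-up transient in forward-backward filtering)
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  m <- n - 1
  comp <- matrix(0, m, m)          # companion matrix of a, transposed
  comp[, 1] <- -a[-1]
  if (m > 1) comp[cbind(seq_len(m - 1), seq(2, m))] <- 1
  rhs <- b[-1] - b[1] * a[-1]
  solve(diag(m) - comp, rhs)
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the IIR filter `b`, `a` forward and backward with odd-symmetric
#' edge padding, giving zero phase distortion and squared magnitude
#' response.  Phase preservation matters here because the downstream
#' statistic is the inter-regional Pearson correlation.
#'
#' @param b,a filter coefficients as from [butter_bandpass()].
#' @param x numeric vector to filter.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  drop(filtfilt_mat(b, a, matrix(x, ncol = 1)))
}

# column-parallel transposed-II filter: X is T x N, zi (n-1) x N
iir_filter_mat <- function(b, a, X, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  Y <- X * 0
  z <- zi
  for (t in seq_len(nrow(X))) {
    xt <- X[t, ]
    yt <- b[1] * xt + z[1, ]
    for (j in seq_len(n - 2))
      z[j, ] <- b[j + 1] * xt + z[j + 1, ] - a[j + 1] * yt
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# zero-phase forward-backward filtering of every column of a T x N matrix
filtfilt_mat <- function(b, a, X) {
  nt <- nrow(X)
  padlen <- min(nt - 1L, max(3L * (max(length(a), length(b)) - 1L), 48L))
  if (padlen < 1L) stop_wmhnet("series too short to filter")
  front <- sweep(-X[seq(padlen + 1, 2), , drop = FALSE], 2,
                 2 * X[1, ], "+")
  back <- sweep(-X[seq(nt - 1, nt - padlen), , drop = FALSE], 2,
                2 * X[nt, ], "+")
  ext <- rbind(front, X, back)
  zi <- iir_steady_state(b, a)
  Y <- iir_filter_mat(b, a, ext, outer(zi, ext[1, ]))
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y <- iir_filter_mat(b, a, Y, outer(zi, Y[1, ]))
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[seq(padlen + 1, padlen + nt), , drop = FALSE]
}
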