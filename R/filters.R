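#' Butterworth low-pass filter coefficients
#'
#' Designs a digital Butterworth low-pass filter by the standard bilinear
#' transform of the analog prototype (the same construction used by the
#' common scientific signal-processing libraries).
#'
#' @param order Filter order (default 4).
#' @param cutoff Cut-off frequency, Hz.
#' @param rate Sampling rate, Hz; must exceed `2 * cutoff`.
#' @return List with numerator `b` and denominator `a` polynomial
#'   coefficients (length `order + 1`).
#' @export
butter_lowpass <- function(cutoff, rate, order = 4L) {
  if (rate <= 2 * cutoff)
    stop("sampling rate must exceed twice the cut-off frequency")
  if (cutoff <= 0) stop("cutoff must be positive")
  K <- tan(pi * cutoff / rate)            # prewarped analog cutoff
  k <- seq_len(order)
  p_analog <- K * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_digital <- (1 + p_analog) / (1 - p_analog)
  # gain: H(z=1) must be 1; zeros all at z = -1
  a <- Re(.poly_from_roots(p_digital))
  b <- Re(.poly_from_roots(rep(-1 + 0i, order)))
  gain <- sum(a) / sum(b)
  list(b = b * gain, a = a)
}

.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

.iir_filter <- function(b, a, x) {
  # MA part by causal convolution (zero initial state), AR part recursively
  nb <- length(b)
  v <- drop(stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution",
                          sides = 1))[-seq_len(nb - 1L)]
  drop(stats::filter(v, -a[-1], method = "recursive"))
}

#' Zero-phase low-pass filtering
#'
#' Forward-backward application of a Butterworth low-pass filter
#' (`filtfilt`), with odd-reflection end padding to suppress edge
#' transients. Zero phase means the output has no time lag relative to the
#' input, at the cost of squaring the magnitude response (the effective
#' attenuation at the cut-off is -6 dB).
#'
#' @param x Numeric vector, or T x k matrix filtered column-wise.
#' @param cutoff Cut-off frequency, Hz.
#' @param rate Sampling rate, Hz.
#' @param order Filter order before the forward-backward pass (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
lowpass <- function(x, cutoff, rate, order = 4L) {
  if (is.matrix(x)) return(apply(x, 2, lowpass, cutoff = cutoff, rate = rate,
                                 order = order))
  ba <- butter_lowpass(cutoff, rate, order)
  n <- length(x)
  min_pad <- 3L * (order + 1L)
  if (n <= min_pad + 1L)
    stop("signal too short (", n, " samples) for the filter warm-up (needs > ",
         min_pad + 1L, ")")
  # pad generously (a few filter time constants) so the zero-state transient
  # dies out inside the reflected region
  pad <- min(n - 1L, max(min_pad, as.integer(ceiling(3 * rate / cutoff))))
  # odd reflection about the end points
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(pre, x, post)
  # constant warm-up block long enough for the slowest pole's zero-state
  # transient to decay below ~1e-9, so DC passes exactly
  maxmod <- max(Mod(polyroot(rev(ba$a))))
  warm <- as.integer(min(20000, ceiling(-21 / log(maxmod))))
  run <- function(z) .iir_filter(ba$b, ba$a,
                                 c(rep(z[1], warm), z))[-seq_len(warm)]
  y <- rev(run(rev(run(xe))))
  y[(pad + 1L):(pad + n)]
}

#' Time derivative by central differences
#'
#' Second-order central differences in the interior, first-order one-sided
#' differences at the ends.
#'
#' @param x Numeric vector or T x k matrix (differentiated column-wise).
#' @param rate Sampling rate, Hz.
#' @return Derivative, same shape as `x`.
#' @export
deriv_central <- function(x, rate) {
  if (is.matrix(x)) return(apply(x, 2, deriv_central, rate = rate))
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}
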