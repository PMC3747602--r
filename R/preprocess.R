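# Full convolution, length(x) + length(h) - 1 samples. Short kernels are
# convolved directly (exact in floating point, e.g. a constant stays exactly
# zero under an antisymmetric kernel); long ones via FFT.
conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  if (length(h) <= 64L) {
    y <- numeric(n)
    for (j in seq_along(h))
      y[j:(j + length(x) - 1L)] <- y[j:(j + length(x) - 1L)] + h[j] * x
    return(y)
  }
  N <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(N - length(x)))) *
                     stats::fft(c(h, numeric(N - length(h)))), inverse = TRUE)) / N
  y[seq_len(n)]
}

# Convolve and keep only fully supported samples. For a symmetric
# (linear-phase) kernel of odd length the result is the delay-compensated
# filter output: sample i of the output corresponds to sample
# i + (length(h) - 1)/2 of the input.
conv_valid <- function(x, h) {
  L <- length(h)
  if (length(x) < L) stop("signal shorter than the filter support")
  conv_full(x, h)[L:length(x)]
}

#' Design a linear-phase FIR filter by the window method
#'
#' Truncated ideal-response (sinc) design weighted by a Hamming window, the
#' construction behind the classic `fir1`-style routines. The order must be
#' even so the group delay `order/2` is an integer sample count. Low-pass
#' designs are scaled to unit gain at DC, high-pass designs (spectral
#' inversion of the complementary low-pass) to unit gain at Nyquist; by
#' construction the magnitude response is approximately 0.5 at the cutoff.
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff Cutoff frequency in Hz (0 < cutoff < fs/2).
#' @param order Filter order (even); the filter has `order + 1` taps.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `order + 1` symmetric coefficients.
#' @export
design_windowed_fir <- function(kind = c("lowpass", "highpass"), cutoff,
                                order, fs) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L) stop("`order` must be even and >= 2")
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    stop("`cutoff` must lie strictly between 0 and fs/2")
  M <- order / 2L
  k <- (-M):M
  fc <- cutoff / fs                       # cycles per sample
  ideal <- 2 * fc * sinc(2 * fc * k)      # ideal low-pass impulse response
  w <- 0.54 + 0.46 * cos(pi * k / M)      # Hamming window, symmetric
  h <- ideal * w
  h <- h / sum(h)                         # unit gain at DC
  if (kind == "highpass") {
    delta <- numeric(order + 1L); delta[M + 1L] <- 1
    h <- delta - h                        # spectral inversion; unit gain at Nyquist
    h <- h / abs(sum(h * (-1)^k))
  }
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Evaluate the magnitude response of an FIR filter
#' @param h Coefficient vector.
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return `|H(f)|`, numeric vector like `f`.
#' @export
fir_magnitude <- function(h, f, fs) {
  k <- seq_along(h) - 1L
  vapply(f, function(fi) Mod(sum(h * exp(-2i * pi * fi / fs * k))), numeric(1L))
}

#' Extract the AC band of a PPG signal
#'
#' Sequential low-pass (noise removal) then high-pass (DC/drift removal)
#' FIR filtering, each compensated by its integer group delay. No padding is
#' used: the `order/2` leading and trailing samples of each stage are
#' discarded, so the output covers only the region of full filter support
#' and `t0` advances accordingly.
#'
#' @param x A `sampled_signal` at the canonical rate `config$fs`.
#' @param config A [run_config()].
#' @return A `sampled_signal` holding the AC component,
#'   `lp_order + hp_order` samples shorter than the input.
#' @export
bandpass_ppg <- function(x, config = run_config()) {
  stopifnot(inherits(x, "sampled_signal"))
  if (!isTRUE(all.equal(x$fs, config$fs)))
    stop(sprintf("signal rate %g Hz differs from the configured %g Hz; resample first",
                 x$fs, config$fs))
  need <- config$lp_order + config$hp_order + 2L
  if (length(x$samples) < need)
    stop(sprintf("signal too short for band separation: %d samples needed (%.1f s at %g Hz), got %d",
                 need, need / config$fs, config$fs, length(x$samples)))
  lp <- design_windowed_fir("lowpass", config$lp_cutoff_hz, config$lp_order, config$fs)
  hp <- design_windowed_fir("highpass", config$hp_cutoff_hz, config$hp_order, config$fs)
  y <- conv_valid(x$samples, lp)
  y <- conv_valid(y, hp)
  t0 <- x$t0 + (config$lp_order / 2 + config$hp_order / 2) / config$fs
  sampled_signal(y, x$fs, label = paste0(x$label, " [AC]"), t0 = t0)
}
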