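#' Herrmann-Rabiner estimate of the minimal equiripple FIR order
#'
#' Classical order estimate for a Parks-McClellan low-pass design,
#' \deqn{N \approx D_\infty(\delta_1, \delta_2)/\Delta F -
#'       f(\delta_1, \delta_2)\,\Delta F,}
#' with the normalized transition width \eqn{\Delta F = } `transition_hz/fs`
#' and the usual polynomial fits for \eqn{D_\infty} and \eqn{f}. The result
#' is truncated (floored) to an integer. For ripples of 0.001 in both bands,
#' a 1 Hz transition and a 1 kHz rate the estimate is 3255. The estimate is
#' a starting point: the realized equiripple deviation at this order is
#' typically a few percent above the target, so [design_pm_lowpass()]
#' verifies the design and increases the order until the ripple
#' specification is met.
#'
#' @param ripple_pass Maximum passband deviation (0 < delta < 1).
#' @param ripple_stop Maximum stopband deviation (0 < delta < 1).
#' @param transition_hz Transition-band width in Hz.
#' @param fs Sampling rate in Hz.
#' @return Integer filter order (taps minus one).
#' @export
estimate_pm_order <- function(ripple_pass, ripple_stop, transition_hz, fs) {
  for (d in c(ripple_pass, ripple_stop))
    if (!is.finite(d) || d <= 0 || d >= 1)
      stop("ripples must lie strictly in (0, 1)")
  if (!is.finite(transition_hz) || transition_hz <= 0 || transition_hz >= fs / 2)
    stop("`transition_hz` must lie strictly between 0 and fs/2")
  l1 <- log10(ripple_pass)
  l2 <- log10(ripple_stop)
  Dinf <- (0.005309 * l1^2 + 0.07114 * l1 - 0.4761) * l2 -
          (0.00266 * l1^2 + 0.5941 * l1 + 0.4278)
  f12 <- 11.01217 + 0.51244 * (l1 - l2)
  dF <- transition_hz / fs
  as.integer(floor(Dinf / dF - f12 * dF))
}

# cache of verified equiripple designs, keyed by the full specification
.pm_cache <- new.env(parent = emptyenv())

#' Design a verified equiripple (Parks-McClellan) low-pass filter
#'
#' Designs the low-pass with passband `[0, edge_hz]` and stopband
#' `[edge_hz + transition_hz, fs/2]` with the Remez exchange algorithm,
#' starting at the Herrmann-Rabiner order estimate and increasing the order
#' until the realized deviation in both bands is at most `ripple` (measured
#' on a dense FFT grid). Orders at which the exchange fails to converge are
#' skipped. Designs are cached per specification.
#'
#' @param edge_hz Passband edge in Hz.
#' @param transition_hz Transition width in Hz.
#' @param ripple Maximum allowed deviation, both bands.
#' @param fs Sampling rate in Hz.
#' @return List with `h` (coefficients), `order`, `estimated_order`,
#'   `ripple_pass`, `ripple_stop`, and the band edges.
#' @export
design_pm_lowpass <- function(edge_hz, transition_hz = 1, ripple = 0.001,
                              fs = 1000) {
  key <- sprintf("%.10g|%.10g|%.10g|%.10g", edge_hz, transition_hz, ripple, fs)
  if (!is.null(.pm_cache[[key]])) return(.pm_cache[[key]])
  if (edge_hz + transition_hz >= fs / 2)
    stop("edge_hz + transition_hz must be below fs/2")
  n_est <- estimate_pm_order(ripple, ripple, transition_hz, fs)
  bands <- c(0, 2 * edge_hz / fs, 2 * (edge_hz + transition_hz) / fs, 1)
  n <- n_est
  best <- NULL
  for (try in 1:80) {
    h <- tryCatch(signal::remez(n, bands, c(1, 1, 0, 0)),
                  error = function(e) NULL)
    if (!is.null(h)) {
      dev <- pm_band_deviation(h, edge_hz, edge_hz + transition_hz, fs)
      if (dev["pass"] <= ripple && dev["stop"] <= ripple) {
        best <- list(h = as.numeric(h), order = n, estimated_order = n_est,
                     ripple_pass = unname(dev["pass"]),
                     ripple_stop = unname(dev["stop"]),
                     edge_hz = edge_hz, transition_hz = transition_hz, fs = fs)
        break
      }
      # scale the order up in proportion to the log-ripple shortfall
      n <- n + max(2L, ceiling(n * 0.004))
    } else {
      n <- n + 1L   # exchange did not converge at this order; try the next
    }
  }
  if (is.null(best))
    stop("equiripple design did not meet the ripple specification")
  .pm_cache[[key]] <- best
  best
}

# max deviation from 1 in [0, f_pass] and from 0 in [f_stop, fs/2]
pm_band_deviation <- function(h, f_pass, f_stop, fs) {
  N <- stats::nextn(max(2^16, 8 * length(h)), 2)
  H <- Mod(stats::fft(c(h, numeric(N - length(h)))))[1:(N / 2 + 1)]
  f <- (0:(N / 2)) / N * fs
  c(pass = max(abs(H[f <= f_pass] - 1)), stop = max(H[f >= f_stop]))
}

# Apply a linear-phase FIR filter with exact group-delay compensation.
# Returns only fully supported samples. For even-length (odd-order) filters
# the group delay is half-integral; the residual half-sample shift is
# removed by cubic-spline interpolation, which is essentially exact for the
# narrow-band signals this stage sees. The first output sample corresponds
# to input sample floor(L/2) + 1.
pm_apply <- function(x, h) {
  L <- length(h)
  y <- conv_valid(x, h)            # y[i] ~ x at i + (L-1)/2
  if (L %% 2L == 1L) return(list(y = y, offset = (L - 1L) / 2L))
  # half-sample advance: value at integer grid i + L/2 from samples at i + (L-1)/2
  n <- length(y)
  if (n < 4L) stop("filtered segment too short for delay compensation")
  ys <- stats::spline(seq_len(n), y, xout = seq_len(n - 1L) + 0.5,
                      method = "fmm")$y
  list(y = ys, offset = L / 2L)
}
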