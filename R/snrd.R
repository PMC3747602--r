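#' Smooth noise-robust differentiator kernel
#'
#' Antisymmetric FIR differentiation kernels that are exact on low-degree
#' polynomials, match the ideal differentiator closely at low frequencies,
#' and have a guaranteed zero of tangency at the Nyquist frequency, so
#' broadband noise is not amplified the way a plain first difference
#' amplifies it. For length 5 (the shortest member, used by default) the
#' rule is
#' \deqn{f'(t_0) \approx \frac{2(f_{1} - f_{-1}) + (f_{2} - f_{-2})}{8\,h}.}
#' General odd lengths `N = 2M + 1` follow the same family with one-sided
#' weights \eqn{c_k = [\binom{2m}{m-k+1} - \binom{2m}{m-k-1}] / 2^{2m+1}},
#' `m = (N - 3)/2`.
#'
#' @param length Odd kernel length, at least 5.
#' @param step Sample interval in seconds (i.e. `1/fs`).
#' @return An object of class `snrd_kernel`: list with `weights` (full
#'   antisymmetric vector, index offsets `-M..M`), `length`, `step`.
#' @export
snrd_kernel <- function(length = 5, step = 1) {
  length <- as.integer(length)
  if (length %% 2L == 0L || length < 5L)
    stop("`length` must be an odd integer >= 5")
  if (!is.finite(step) || step <= 0) stop("`step` must be positive")
  M <- (length - 1L) / 2L
  m <- (length - 3L) / 2L
  ck <- vapply(seq_len(M), function(k)
    (choose(2 * m, m - k + 1) - choose(2 * m, m - k - 1)) / 2^(2 * m + 1),
    numeric(1L))
  w <- c(-rev(ck), 0, ck) / step
  structure(list(weights = w, length = length, step = step),
            class = "snrd_kernel")
}

#' Apply the differentiator at a single (central) point
#' @param kernel An `snrd_kernel`.
#' @param f Numeric vector of `kernel$length` samples centred on the point.
#' @return The derivative estimate at the central sample.
#' @export
snrd_apply_center <- function(kernel, f) {
  stopifnot(inherits(kernel, "snrd_kernel"))
  if (length(f) != kernel$length)
    stop("`f` must have exactly kernel$length samples")
  sum(kernel$weights * f)
}

#' Frequency response of a differentiator kernel
#' @param kernel An `snrd_kernel`.
#' @param f Frequencies in Hz (sampling rate is `1/kernel$step`).
#' @return Complex response `H(f)`; an ideal differentiator has
#'   `H(f) = 2i*pi*f`.
#' @export
snrd_response <- function(kernel, f) {
  M <- (kernel$length - 1L) / 2L
  k <- (-M):M
  vapply(f, function(fi) sum(kernel$weights * exp(2i * pi * fi * kernel$step * k)),
         complex(1L))
}

#' Differentiate a signal by repeated kernel application
#'
#' Convolves the signal with the antisymmetric kernel `times` times. Only
#' fully supported samples are kept: each pass trims `(length - 1)/2`
#' samples from each end, and `t0` advances so that sample times are
#' preserved (the centred kernel introduces no net shift).
#'
#' @param x A `sampled_signal`.
#' @param times Number of derivative orders to take (>= 1).
#' @param kernel An `snrd_kernel`; defaults to the 5-point kernel at the
#'   signal's own sample interval.
#' @return A `sampled_signal` holding the `times`-th derivative (units of
#'   input per second^times).
#' @export
snrd_differentiate <- function(x, times = 1, kernel = NULL) {
  stopifnot(inherits(x, "sampled_signal"))
  times <- as.integer(times)
  if (times < 1L) stop("`times` must be >= 1")
  if (is.null(kernel)) kernel <- snrd_kernel(5, step = 1 / x$fs)
  if (!isTRUE(all.equal(kernel$step, 1 / x$fs)))
    stop("kernel step does not match the signal's sample interval")
  M <- (kernel$length - 1L) / 2L
  if (length(x$samples) < times * (kernel$length - 1L) + 2L)
    stop(sprintf("signal too short to differentiate %d times: need at least %d samples",
                 times, times * (kernel$length - 1L) + 2L))
  # convolution kernel = reversed correlation weights = -weights (antisymmetry)
  h <- rev(kernel$weights)
  y <- x$samples
  for (i in seq_len(times)) y <- conv_valid(y, h)
  sampled_signal(y, x$fs,
                 label = sprintf("%s d%d", x$label, times),
                 t0 = x$t0 + times * M / x$fs)
}

#' Band-limited PPG together with its second and fourth derivatives
#'
#' Computes the 2nd and 4th derivatives of the AC PPG by repeated
#' application of the smooth noise-robust differentiator and crops all
#' three series to their common region of full support, so they share one
#' time grid.
#'
#' @param ac A `sampled_signal` holding the AC PPG (see [bandpass_ppg()]).
#' @param config A [run_config()]; `snrd_length` selects the kernel.
#' @return A list of class `derivative_set` with `ppg`, `sd2`, `d4`
#'   (`sampled_signal`s on a common grid) and the kernel used.
#' @export
derivative_set <- function(ac, config = run_config()) {
  stopifnot(inherits(ac, "sampled_signal"))
  kernel <- snrd_kernel(config$snrd_length, step = 1 / ac$fs)
  M <- (kernel$length - 1L) / 2L
  sd2 <- snrd_differentiate(ac, 2, kernel)
  d4 <- snrd_differentiate(ac, 4, kernel)
  n <- length(ac$samples)
  trim4 <- 4L * M
  ppg <- sampled_signal(ac$samples[(trim4 + 1L):(n - trim4)], ac$fs,
                        label = ac$label, t0 = ac$t0 + trim4 / ac$fs)
  sd2 <- sampled_signal(sd2$samples[(2L * M + 1L):(length(sd2$samples) - 2L * M)],
                        ac$fs, label = sd2$label, t0 = sd2$t0 + 2L * M / ac$fs)
  stopifnot(length(ppg$samples) == length(sd2$samples),
            length(ppg$samples) == length(d4$samples))
  structure(list(ppg = ppg, sd2 = sd2, d4 = d4, kernel = kernel),
            class = "derivative_set")
}
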