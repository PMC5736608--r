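# Spectral front end: zero-phase FIR bandpass, Hilbert instantaneous phase,
# and two-cycle Morlet wavelet power.

# FFT-based "same" convolution with a centered kernel. The kernel must have
# odd length so the output is exactly aligned with the input.
fft_conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  stopifnot(m %% 2L == 1L)
  nfft <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  K <- stats::fft(c(k, rep(0, nfft - m)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  idx <- (m %/% 2L) + seq_len(n)
  out <- full[idx]
  if (is.double(x) && is.double(k)) Re(out) else out
}

# Windowed-sinc bandpass kernel (Hamming). Taps chosen so that the
# transition band fits inside min(low, high - low)/2, and never fewer than
# 3 cycles of the low edge; always odd (type-I linear phase).
design_bandpass <- function(rate, band) {
  low <- band[1]
  high <- band[2]
  if (!(low > 0 && high > low && high < rate / 2)) {
    stop(sprintf(
      "band (%g, %g) Hz must satisfy 0 < low < high < rate/2 = %g",
      low, high, rate / 2
    ), call. = FALSE)
  }
  delta <- min(low, high - low) / 2
  taps <- max(ceiling(3 * rate / low), ceiling(3.3 * rate / delta))
  if (taps %% 2L == 0L) taps <- taps + 1L
  signal::fir1(taps - 1L, c(low, high) * 2 / rate, type = "pass")
}

#' Zero-phase bandpass filter
#'
#' Filters an LFP trace with a linear-phase windowed-sinc (Hamming) FIR
#' kernel applied forward and backward via FFT convolution, so the output
#' has exactly zero group delay: peaks of a bandpassed sinusoid stay where
#' they are. The filter-transient-contaminated edges are not removed but
#' their extent is recorded in the `n_edge` attribute (samples per edge);
#' downstream coupling functions drop them.
#'
#' @param lfp An [lfp_recording()] or a numeric trace (then supply `rate`).
#' @param band Length-2 numeric, passband `(low, high)` in Hz,
#'   `0 < low < high < rate/2`.
#' @param rate Sampling rate in Hz, only for bare numeric traces.
#' @return Numeric vector, same length as the input, with attributes
#'   `n_edge` (edge samples to distrust), `band` and `rate`.
#' @export
#' @examples
#' x <- cos(2 * pi * 8 * seq(0, 5, by = 1 / 500))
#' y <- bandpass_zero_phase(x, band = c(4, 12), rate = 500)
bandpass_zero_phase <- function(lfp, band, rate = NULL) {
  tr <- as_trace(lfp, rate)
  k <- design_bandpass(tr$rate, band)
  if (length(tr$v) <= 3L * length(k)) {
    stop(sprintf(
      "trace too short: %d samples, need more than 3 filter lengths (%d)",
      length(tr$v), 3L * length(k)
    ), call. = FALSE)
  }
  y <- fft_conv_same(fft_conv_same(tr$v, k), k)
  attr(y, "n_edge") <- length(k) - 1L
  attr(y, "band") <- band
  attr(y, "rate") <- tr$rate
  y
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of a bandpassed, zero-mean trace and returns
#' its instantaneous phase, wrapped to (-pi, pi]. The convention is the
#' cosine one: phase 0 at local maxima (oscillation peaks), +/- pi at
#' troughs.
#'
#' @param filtered Numeric vector, a bandpassed zero-mean trace (typically
#'   the output of [bandpass_zero_phase()]).
#' @param rate Sampling rate in Hz; taken from the input's attribute if
#'   present.
#' @return A numeric vector of phases (radians) of class `phase_series`,
#'   with attributes `rate`, `band` and `n_edge` carried over.
#' @export
instantaneous_phase <- function(filtered, rate = NULL) {
  if (is.null(rate)) rate <- attr(filtered, "rate")
  if (is.null(rate)) stop("rate must be supplied", call. = FALSE)
  v <- as.numeric(filtered)
  if (stats::sd(v) < .Machine$double.eps^0.5 * (abs(mean(v)) + 1)) {
    stop("phase is undefined for a (near-)constant trace", call. = FALSE)
  }
  ph <- Arg(analytic_signal(v))
  structure(ph,
    class = "phase_series", rate = rate,
    band = attr(filtered, "band"),
    n_edge = attr(filtered, "n_edge") %||% 0L
  )
}

# Analytic signal by the one-sided spectrum construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Morlet wavelet power
#'
#' Time-frequency power by convolution with complex Morlet wavelets of a
#' fixed number of cycles (default 2): at frequency f the Gaussian envelope
#' has \eqn{\sigma_t = n_{cycles}/(2\pi f)} and the kernel is truncated at
#' \eqn{\pm 5\sigma_t}. Power is the squared magnitude of the convolution.
#' Kernels are L1-normalized so a unit cosine at f yields power 0.25 at f.
#'
#' @param lfp An [lfp_recording()] or numeric trace (then supply `rate`).
#' @param freqs Strictly increasing frequencies in Hz, all `< rate/2`.
#'   Default 1-150 Hz in 1-Hz steps (clipped below Nyquist).
#' @param rate Sampling rate, for bare numeric traces.
#' @param n_cycles Wavelet length in cycles (default 2).
#' @return A `wavelet_power` object: list with `power` (time x frequency
#'   matrix), `freqs`, `rate`, and `coi` (per-frequency count of
#'   edge samples inside the cone of influence).
#' @export
morlet_power <- function(lfp, freqs = NULL, rate = NULL, n_cycles = 2) {
  tr <- as_trace(lfp, rate)
  if (is.null(freqs)) freqs <- seq(1, min(150, floor(tr$rate / 2) - 1), by = 1)
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing", call. = FALSE)
  if (any(freqs <= 0) || any(freqs >= tr$rate / 2)) {
    stop("all freqs must lie in (0, rate/2)", call. = FALSE)
  }
  n <- length(tr$v)
  # one forward FFT of the (padded) signal, reused for every frequency
  max_half <- ceiling(5 * n_cycles / (2 * pi * freqs[1]) * tr$rate)
  nfft <- stats::nextn(n + 2L * max_half, 2)
  X <- stats::fft(c(tr$v, rep(0, nfft - n)))
  pow <- matrix(NA_real_, nrow = n, ncol = length(freqs))
  coi <- integer(length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma <- n_cycles / (2 * pi * f)
    half <- ceiling(5 * sigma * tr$rate)
    tt <- (-half:half) / tr$rate
    k <- exp(1i * 2 * pi * f * tt) * exp(-tt^2 / (2 * sigma^2))
    k <- k / sum(Mod(k))
    m <- length(k)
    K <- stats::fft(c(k, rep(0, nfft - m)))
    full <- stats::fft(X * K, inverse = TRUE) / nfft
    pow[, j] <- Mod(full[(m %/% 2L) + seq_len(n)])^2
    coi[j] <- half
  }
  structure(
    list(power = pow, freqs = freqs, rate = tr$rate, n_cycles = n_cycles, coi = coi),
    class = "wavelet_power"
  )
}

#' @export
print.wavelet_power <- function(x, ...) {
  cat(sprintf(
    "<wavelet_power> %d samples x %d freqs (%g-%g Hz), %g cycles\n",
    nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs), x$n_cycles
  ))
  invisible(x)
}

#' @describeIn morlet_power Long tibble (`time_s`, `freq_hz`, `power`).
#' @param x A `wavelet_power` object.
#' @param ... Unused.
#' @method tidy wavelet_power
#' @export
tidy.wavelet_power <- function(x, ...) {
  tibble::tibble(
    time_s = rep((seq_len(nrow(x$power)) - 1) / x$rate, times = length(x$freqs)),
    freq_hz = rep(x$freqs, each = nrow(x$power)),
    power = as.vector(x$power)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
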