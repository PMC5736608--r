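# Gamma-burst peak detection, peak-triggered LFP averaging, and
# theta-phase histograms of gamma peaks.

#' Detect gamma-burst peaks with a 100-ms exclusion zone
#'
#' Finds local maxima of a gamma-bandpassed voltage trace and greedily
#' retains them in descending amplitude, discarding any maximum within
#' `min_separation` of an already-retained one, so only the highest peak
#' inside each 100-ms neighborhood survives (one peak per theta cycle at
#' most). Amplitude ties are broken in favor of the earlier peak.
#'
#' @param filtered Numeric vector, a gamma-bandpassed trace (e.g. from
#'   [bandpass_zero_phase()]).
#' @param rate Sampling rate in Hz (taken from attributes if present).
#' @param min_separation Minimum separation between retained peaks,
#'   seconds (default 0.1).
#' @return A `gamma_peaks` tibble with columns `time_s`, `amplitude`,
#'   sorted by time; attributes `min_separation` and `rate`.
#' @export
detect_gamma_peaks <- function(filtered, rate = NULL, min_separation = 0.1) {
  if (is.null(rate)) rate <- attr(filtered, "rate")
  if (is.null(rate)) stop("rate must be supplied", call. = FALSE)
  v <- as.numeric(filtered)
  if (length(v) < 0.2 * rate) {
    stop("trace shorter than 200 ms; cannot detect separated peaks", call. = FALSE)
  }
  d <- diff(v)
  is_max <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(is_max) == 0L) {
    stop("no local maxima found in trace", call. = FALSE)
  }
  # greedy highest-first; tie -> earlier sample first (stable order)
  ord <- is_max[order(-v[is_max], is_max)]
  t_all <- (ord - 1) / rate
  kept_t <- numeric(0)
  kept_i <- integer(0)
  for (k in seq_along(ord)) {
    if (all(abs(t_all[k] - kept_t) >= min_separation)) {
      kept_t <- c(kept_t, t_all[k])
      kept_i <- c(kept_i, ord[k])
    }
  }
  o <- order(kept_t)
  out <- tibble::tibble(time_s = kept_t[o], amplitude = v[kept_i[o]])
  attr(out, "min_separation") <- min_separation
  attr(out, "rate") <- rate
  class(out) <- c("gamma_peaks", class(out))
  out
}

#' Gamma-peak-triggered LFP average
#'
#' Averages fixed-length windows (default 200 ms) of a raw LFP trace
#' centered on each gamma peak time. Peaks whose window would extend
#' beyond the trace are dropped and counted.
#'
#' @param peaks A `gamma_peaks` tibble from [detect_gamma_peaks()].
#' @param lfp An [lfp_recording()] (typically the raw vHPC trace).
#' @param half_window Half window length in seconds (default 0.1).
#' @return A tibble with columns `lag_s`, `mean_voltage`; attributes
#'   `n_used` and `n_dropped`.
#' @export
triggered_average <- function(peaks, lfp, half_window = 0.1) {
  rate <- lfp_rate(lfp)
  half <- round(half_window * rate)
  centers <- round((peaks$time_s - lfp_t0(lfp)) * rate) + 1L
  ok <- centers - half >= 1L & centers + half <= nrow(lfp)
  if (!any(ok)) stop("no peak has a full window inside the trace", call. = FALSE)
  offs <- -half:half
  acc <- numeric(length(offs))
  for (ci in centers[ok]) acc <- acc + lfp$voltage[ci + offs]
  out <- tibble::tibble(lag_s = offs / rate, mean_voltage = acc / sum(ok))
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Theta-phase histogram of gamma peaks
#'
#' Looks up the theta phase at each gamma peak time (nearest sample) and
#' returns the normalized count per pi/50 phase bin (sums to 1) together
#' with the circular mean direction of the peak phases.
#'
#' @param peaks A `gamma_peaks` tibble.
#' @param theta_phase A `phase_series` (from [instantaneous_phase()]).
#' @param rate Sampling rate of the phase series (from attributes if
#'   absent).
#' @param t0 Time of the first phase sample, seconds.
#' @return A list with `histogram` (tibble `bin`, `phase_center`,
#'   `proportion`), `mean_direction`, `mrl`, `n_peaks`.
#' @export
peak_phase_histogram <- function(peaks, theta_phase, rate = NULL, t0 = 0) {
  if (is.null(rate)) rate <- attr(theta_phase, "rate")
  if (nrow(peaks) == 0L) stop("no peaks to histogram", call. = FALSE)
  idx <- round((peaks$time_s - t0) * rate) + 1L
  if (any(idx < 1L | idx > length(theta_phase))) {
    stop("some peak times fall outside the phase series support", call. = FALSE)
  }
  ph <- as.numeric(theta_phase)[idx]
  counts <- tabulate(phase_bin_index(ph), nbins = 100L)
  cs <- circ_stats(ph)
  list(
    histogram = tibble::tibble(
      bin = seq_len(100L),
      phase_center = pac_bin_centers(),
      proportion = counts / sum(counts)
    ),
    mean_direction = cs$mean_direction,
    mrl = cs$mrl,
    n_peaks = length(ph)
  )
}
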