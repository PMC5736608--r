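# Cross-frequency coupling: phase-binned power, weighted MRL, comodulogram,
# and n:m phase-phase coupling.

#' Phase bin centers for coupling profiles
#'
#' 100 bins of width pi/50 rad (3.6 degrees) covering the circle; bin k is
#' centered at -pi + (k - 1/2) * pi/50.
#'
#' @return Numeric vector of 100 bin centers in radians.
#' @export
pac_bin_centers <- function() {
  -pi + (seq_len(100) - 0.5) * pi / 50
}

# Map wrapped phases in (-pi, pi] to bin index 1..100.
phase_bin_index <- function(phase) {
  idx <- ceiling((phase + pi) / (pi / 50))
  pmin(pmax(idx, 1L), 100L)
}

#' Mean power per theta-phase bin
#'
#' Averages a per-sample power series within each of 100 phase bins of
#' width pi/50. Empty bins are reported with `n = 0` and `NA` power.
#'
#' @param phase Numeric vector of wrapped phases in radians (e.g. a
#'   `phase_series`).
#' @param power Numeric vector of per-sample power, same length.
#' @return A tibble with columns `bin`, `phase_center` (radians),
#'   `mean_power`, `n`.
#' @export
phase_binned_amplitude <- function(phase, power) {
  if (length(phase) != length(power)) {
    stop("phase and power must have the same length", call. = FALSE)
  }
  ok <- is.finite(phase) & is.finite(power)
  if (!any(ok)) stop("no valid (finite) samples to bin", call. = FALSE)
  idx <- phase_bin_index(phase[ok])
  n <- tabulate(idx, nbins = 100L)
  s <- as.vector(rowsum(power[ok], idx, reorder = TRUE))
  mean_power <- rep(NA_real_, 100L)
  mean_power[sort(unique(idx))] <- s / n[sort(unique(idx))]
  tibble::tibble(
    bin = seq_len(100L),
    phase_center = pac_bin_centers(),
    mean_power = mean_power,
    n = n
  )
}

#' Weighted mean resultant length of a phase profile
#'
#' Treats a per-bin weight (here: mean gamma power per theta-phase bin) as
#' a mass on the circle and computes the mean resultant length
#' \eqn{MRL = |\sum_k w_k e^{i c_k}| / \sum_k w_k} and the direction of the
#' resultant. MRL is 0 for a flat profile (no coupling) and 1 when all
#' weight sits in one bin (perfect coupling).
#'
#' @param weights Non-negative weights, one per bin (NA bins dropped).
#' @param centers Bin centers in radians (default [pac_bin_centers()]).
#' @return A list with `mrl` and `mean_direction` (radians).
#' @export
#' @examples
#' w <- 1 + 0.5 * cos(pac_bin_centers())
#' weighted_mrl(w) # mrl ~ 0.25, direction ~ 0
weighted_mrl <- function(weights, centers = pac_bin_centers()) {
  stopifnot(length(weights) == length(centers))
  keep <- is.finite(weights)
  weights <- weights[keep]
  centers <- centers[keep]
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  tot <- sum(weights)
  if (tot == 0) stop("all weights are zero; MRL undefined", call. = FALSE)
  z <- sum(weights * exp(1i * centers)) / tot
  list(mrl = Mod(z), mean_direction = Arg(z))
}

# Sample indices (1-based) covered by the half-open epochs [t_start, t_end),
# relative to a trace of n samples at `rate` starting at t0.
epochs_to_idx <- function(epochs, rate, n, t0 = 0) {
  if (is.null(epochs)) {
    return(seq_len(n))
  }
  stopifnot(all(c("t_start_s", "t_end_s") %in% names(epochs)))
  idx <- unlist(lapply(seq_len(nrow(epochs)), function(i) {
    a <- floor((epochs$t_start_s[i] - t0) * rate) + 1L
    b <- ceiling((epochs$t_end_s[i] - t0) * rate)
    seq.int(max(a, 1L), min(b, n))
  }))
  sort(unique(idx))
}

# Shared low-level PAC: bin a phase/power pair and summarize.
pac_from_phase_power <- function(phase, power, idx = NULL) {
  if (!is.null(idx)) {
    phase <- phase[idx]
    power <- power[idx]
  }
  bins <- phase_binned_amplitude(phase, power)
  wm <- weighted_mrl(bins$mean_power, bins$phase_center)
  list(bins = bins, mrl = wm$mrl, mean_direction = wm$mean_direction,
       n_samples = sum(bins$n))
}

#' Theta-phase to gamma-power coupling (PAC)
#'
#' The full estimation pipeline: theta phase from `phase_lfp` by
#' zero-phase bandpass and Hilbert transform; gamma power from `amp_lfp`
#' by Morlet wavelet averaged across the in-band frequencies; phases
#' binned into 100 bins of width pi/50; bin-mean powers used as weights
#' for the mean resultant length. Epochs (rows with `t_start_s`,
#' `t_end_s`) are concatenated before binning. Filter- and wavelet-edge
#' samples are dropped.
#'
#' @param phase_lfp,amp_lfp [lfp_recording()]s, time-aligned, same rate
#'   (may be the same object for within-region coupling).
#' @param phase_band Phase (theta) band in Hz, default c(4, 12).
#' @param amp_band Amplitude (gamma) band in Hz, default c(30, 70).
#' @param epochs Optional tibble of epochs; NULL = whole trace.
#' @param freq_step Spacing of the wavelet frequency grid inside
#'   `amp_band`, Hz.
#' @param amp_method `"wavelet"` (default; band-mean Morlet power) or
#'   `"hilbert"` (bandpass + squared Hilbert envelope).
#' @param min_duration Minimum total selected data in seconds (default
#'   10, about 80 theta cycles); shorter input is an error.
#' @return A `pac_result`: list with `bins` (100-row tibble), `mrl`,
#'   `mean_direction`, `phase_band`, `amp_band`, `phase_region`,
#'   `amp_region`, `n_samples`.
#' @export
pac <- function(phase_lfp, amp_lfp, phase_band = c(4, 12),
                amp_band = c(30, 70), epochs = NULL, freq_step = 1,
                amp_method = c("wavelet", "hilbert"), min_duration = 10) {
  amp_method <- match.arg(amp_method)
  rate <- lfp_rate(phase_lfp)
  stopifnot(rate == lfp_rate(amp_lfp), nrow(phase_lfp) == nrow(amp_lfp))
  pp <- pac_phase_power(phase_lfp, amp_lfp, phase_band, amp_band,
    freq_step = freq_step, amp_method = amp_method
  )
  idx <- intersect(
    epochs_to_idx(epochs, rate, nrow(phase_lfp), lfp_t0(phase_lfp)),
    pp$valid
  )
  if (length(idx) / rate < min_duration) {
    stop(sprintf(
      "insufficient data for PAC: %.2f s selected, need at least %g s",
      length(idx) / rate, min_duration
    ), call. = FALSE)
  }
  res <- pac_from_phase_power(pp$phase, pp$power, idx)
  structure(
    c(res, list(
      phase_band = phase_band, amp_band = amp_band,
      phase_region = lfp_region(phase_lfp), amp_region = lfp_region(amp_lfp),
      rate = rate
    )),
    class = "pac_result"
  )
}

# Compute the phase series, band-mean power series and the valid index
# range (edges excluded) shared by pac() and epoch_coupling_series().
pac_phase_power <- function(phase_lfp, amp_lfp, phase_band, amp_band,
                            freq_step = 1, amp_method = "wavelet") {
  rate <- lfp_rate(phase_lfp)
  filt <- bandpass_zero_phase(phase_lfp, phase_band)
  phase <- instantaneous_phase(filt)
  n_edge_p <- attr(phase, "n_edge")
  if (amp_method == "wavelet") {
    freqs <- seq(amp_band[1], amp_band[2], by = freq_step)
    wp <- morlet_power(amp_lfp, freqs = freqs)
    power <- rowMeans(wp$power)
    n_edge_a <- max(wp$coi)
  } else {
    fg <- bandpass_zero_phase(amp_lfp, amp_band)
    power <- Mod(analytic_signal(as.numeric(fg)))^2
    n_edge_a <- attr(fg, "n_edge")
  }
  n <- nrow(phase_lfp)
  n_edge <- max(n_edge_p, n_edge_a)
  valid <- seq.int(n_edge + 1L, n - n_edge)
  list(phase = as.numeric(phase), power = power, valid = valid, rate = rate)
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf(
    "<pac_result> %s theta (%g-%g Hz) -> %s gamma (%g-%g Hz)\n  MRL = %.4f, mean direction = %.1f deg, n = %d samples\n",
    x$phase_region, x$phase_band[1], x$phase_band[2],
    x$amp_region, x$amp_band[1], x$amp_band[2],
    x$mrl, x$mean_direction * 180 / pi, x$n_samples
  ))
  invisible(x)
}

#' @describeIn pac Per-bin tibble of the phase-power profile.
#' @param x A `pac_result`.
#' @param ... Unused.
#' @method tidy pac_result
#' @export
tidy.pac_result <- function(x, ...) x$bins

#' @describeIn pac One-row summary tibble (`mrl`, `mean_direction`,
#'   `mean_direction_deg`, bands, regions, `n_samples`).
#' @method glance pac_result
#' @export
glance.pac_result <- function(x, ...) {
  tibble::tibble(
    mrl = x$mrl,
    mean_direction = x$mean_direction,
    mean_direction_deg = x$mean_direction * 180 / pi,
    phase_low = x$phase_band[1], phase_high = x$phase_band[2],
    amp_low = x$amp_band[1], amp_high = x$amp_band[2],
    phase_region = x$phase_region, amp_region = x$amp_region,
    n_samples = x$n_samples
  )
}

#' Time-shift surrogate distribution for a PAC estimate
#'
#' Destroys the phase-power relationship by circularly shifting the power
#' series relative to the phase series by a uniform random lag of at least
#' `min_shift` seconds, and recomputes the weighted MRL for each draw.
#' The empirical quantiles of the returned values give a significance
#' floor for an observed MRL.
#'
#' @param phase,power Aligned per-sample phase and power vectors (e.g.
#'   from the bins pipeline underlying [pac()]).
#' @param rate Sampling rate in Hz.
#' @param n_surrogates Number of shifts (default 200).
#' @param min_shift Minimum shift in seconds (default 1).
#' @return Numeric vector of surrogate MRL values.
#' @export
pac_surrogates <- function(phase, power, rate, n_surrogates = 200,
                           min_shift = 1) {
  n <- length(phase)
  stopifnot(length(power) == n, n > 2 * min_shift * rate)
  idx <- phase_bin_index(as.numeric(phase))
  counts <- tabulate(idx, nbins = 100L)
  centers <- pac_bin_centers()
  shifts <- sample.int(n - 2L * round(min_shift * rate), n_surrogates,
    replace = TRUE
  ) + round(min_shift * rate)
  vapply(shifts, function(s) {
    p <- c(power[(s + 1L):n], power[seq_len(s)])
    sums <- as.vector(rowsum(p, idx, reorder = TRUE))
    w <- rep(NA_real_, 100L)
    w[sort(unique(idx))] <- sums / counts[sort(unique(idx))]
    weighted_mrl(w, centers)$mrl
  }, numeric(1))
}

#' Phase-power comodulogram
#'
#' For every 0.5-Hz-wide low-frequency band (centers 4-20 Hz by default)
#' the instantaneous phase is extracted by zero-phase bandpass and Hilbert
#' transform, and the weighted MRL is computed against Morlet wavelet
#' power at each amplitude frequency (30-150 Hz by default), giving a
#' phase-frequency x amplitude-frequency matrix of coupling strength.
#'
#' @inheritParams pac
#' @param phase_centers Centers of the low-frequency bands, Hz.
#' @param phase_bandwidth Width of each low-frequency band, Hz (0.5).
#' @param amp_freqs Amplitude frequencies, Hz.
#' @return A `comodulogram`: list with `mrl` (matrix phase x amp),
#'   `phase_centers`, `amp_freqs`, regions.
#' @export
comodulogram <- function(phase_lfp, amp_lfp, epochs = NULL,
                         phase_centers = seq(4, 20, by = 0.5),
                         phase_bandwidth = 0.5,
                         amp_freqs = seq(30, 150, by = 1),
                         min_duration = 10) {
  rate <- lfp_rate(phase_lfp)
  stopifnot(rate == lfp_rate(amp_lfp), nrow(phase_lfp) == nrow(amp_lfp))
  n <- nrow(phase_lfp)
  wp <- morlet_power(amp_lfp, freqs = amp_freqs)
  ep_idx <- epochs_to_idx(epochs, rate, n, lfp_t0(phase_lfp))
  centers <- pac_bin_centers()
  M <- matrix(NA_real_,
    nrow = length(phase_centers), ncol = length(amp_freqs),
    dimnames = list(phase_centers, amp_freqs)
  )
  for (i in seq_along(phase_centers)) {
    band <- phase_centers[i] + c(-0.5, 0.5) * phase_bandwidth
    filt <- bandpass_zero_phase(phase_lfp, band)
    ph <- instantaneous_phase(filt)
    n_edge <- max(attr(ph, "n_edge"), max(wp$coi))
    idx <- intersect(ep_idx, seq.int(n_edge + 1L, n - n_edge))
    if (length(idx) / rate < min_duration) {
      stop(sprintf(
        "insufficient data for comodulogram at %.1f Hz: %.2f s valid, need %g s",
        phase_centers[i], length(idx) / rate, min_duration
      ), call. = FALSE)
    }
    bidx <- phase_bin_index(as.numeric(ph)[idx])
    cnt <- tabulate(bidx, nbins = 100L)
    present <- cnt > 0
    sums <- rowsum(wp$power[idx, , drop = FALSE], bidx, reorder = TRUE)
    means <- sums / cnt[present]
    zc <- exp(1i * centers[present])
    res <- t(means) %*% zc # per-amp-frequency resultant
    M[i, ] <- Mod(res[, 1]) / colSums(means)
  }
  structure(
    list(
      mrl = M, phase_centers = phase_centers, amp_freqs = amp_freqs,
      phase_region = lfp_region(phase_lfp), amp_region = lfp_region(amp_lfp)
    ),
    class = "comodulogram"
  )
}

#' @export
print.comodulogram <- function(x, ...) {
  peak <- arrayInd(which.max(x$mrl), dim(x$mrl))
  cat(sprintf(
    "<comodulogram> %s phase (%g-%g Hz) x %s power (%g-%g Hz)\n  max MRL = %.4f at phase %.1f Hz, amp %g Hz\n",
    x$phase_region, min(x$phase_centers), max(x$phase_centers),
    x$amp_region, min(x$amp_freqs), max(x$amp_freqs),
    max(x$mrl), x$phase_centers[peak[1]], x$amp_freqs[peak[2]]
  ))
  invisible(x)
}

#' @describeIn comodulogram Long tibble (`phase_freq_hz`, `amp_freq_hz`,
#'   `mrl`).
#' @param x A `comodulogram`.
#' @param ... Unused.
#' @method tidy comodulogram
#' @export
tidy.comodulogram <- function(x, ...) {
  tibble::tibble(
    phase_freq_hz = rep(x$phase_centers, times = length(x$amp_freqs)),
    amp_freq_hz = rep(x$amp_freqs, each = length(x$phase_centers)),
    mrl = as.vector(x$mrl)
  )
}

#' n:m phase-phase coupling
#'
#' Two oscillators are n:m phase-coupled when n cycles of the slow one
#' correspond to m cycles of the fast one, i.e. the wrapped difference
#' n*phi_theta - m*phi_gamma holds a consistent value. Entry (n, m) of the
#' result is the mean resultant length of that difference over all
#' samples.
#'
#' @param theta_phase,gamma_phase Aligned phase vectors (radians).
#' @param n_grid,m_grid Integer multipliers for the theta and gamma phase
#'   respectively (defaults 1:4 and 1:16).
#' @return A `phase_phase_result`: list with `mrl` (matrix n x m),
#'   `n_grid`, `m_grid`.
#' @export
phase_phase_mrl <- function(theta_phase, gamma_phase, n_grid = 1:4,
                            m_grid = 1:16) {
  if (length(theta_phase) == 0L || length(gamma_phase) == 0L) {
    stop("phase series must be non-empty", call. = FALSE)
  }
  if (length(theta_phase) != length(gamma_phase)) {
    stop("phase series must have the same length", call. = FALSE)
  }
  th <- as.numeric(theta_phase)
  ga <- as.numeric(gamma_phase)
  M <- matrix(NA_real_,
    nrow = length(n_grid), ncol = length(m_grid),
    dimnames = list(n_grid, m_grid)
  )
  for (i in seq_along(n_grid)) {
    a <- exp(1i * n_grid[i] * th)
    for (j in seq_along(m_grid)) {
      M[i, j] <- Mod(mean(a * exp(-1i * m_grid[j] * ga)))
    }
  }
  structure(
    list(mrl = M, n_grid = n_grid, m_grid = m_grid),
    class = "phase_phase_result"
  )
}

#' @export
print.phase_phase_result <- function(x, ...) {
  peak <- arrayInd(which.max(x$mrl), dim(x$mrl))
  cat(sprintf(
    "<phase_phase_result> n in %d..%d, m in %d..%d; max MRL = %.4f at n:m = %d:%d\n",
    min(x$n_grid), max(x$n_grid), min(x$m_grid), max(x$m_grid),
    max(x$mrl), x$n_grid[peak[1]], x$m_grid[peak[2]]
  ))
  invisible(x)
}

#' @describeIn phase_phase_mrl Long tibble (`n`, `m`, `mrl`).
#' @param x A `phase_phase_result`.
#' @param ... Unused.
#' @method tidy phase_phase_result
#' @export
tidy.phase_phase_result <- function(x, ...) {
  tibble::tibble(
    n = rep(x$n_grid, times = length(x$m_grid)),
    m = rep(x$m_grid, each = length(x$n_grid)),
    mrl = as.vector(x$mrl)
  )
}
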