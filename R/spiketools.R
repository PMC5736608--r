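# Unit quality filtering, spike-gamma phase locking, normalized spike
# cross-correlograms, and firing-rate-versus-coupling quartile analysis.

#' Filter units by cluster quality
#'
#' Keeps units satisfying both inclusion criteria, L-ratio <= `max_l_ratio`
#' and isolation distance >= `min_isolation` (bounds inclusive). Units with
#' a missing metric are excluded with reason `"missing"`, never silently
#' kept.
#'
#' @param units A tibble with at least `unit_id`, `l_ratio`,
#'   `isolation_distance` (e.g. from [gen_spike_trains()]).
#' @param max_l_ratio Maximum L-ratio (default 0.1).
#' @param min_isolation Minimum isolation distance (default 10).
#' @return A list with `kept` (tibble of included units) and `report`
#'   (tibble `unit_id`, `included`, `reason`; reason is `NA`, `"l_ratio"`,
#'   `"isolation_distance"`, `"both"` or `"missing"`).
#' @export
filter_units <- function(units, max_l_ratio = 0.1, min_isolation = 10) {
  stopifnot(all(c("unit_id", "l_ratio", "isolation_distance") %in% names(units)))
  lr_bad <- !is.na(units$l_ratio) & units$l_ratio > max_l_ratio
  iso_bad <- !is.na(units$isolation_distance) &
    units$isolation_distance < min_isolation
  missing <- is.na(units$l_ratio) | is.na(units$isolation_distance)
  reason <- rep(NA_character_, nrow(units))
  reason[lr_bad] <- "l_ratio"
  reason[iso_bad] <- "isolation_distance"
  reason[lr_bad & iso_bad] <- "both"
  reason[missing] <- "missing"
  included <- is.na(reason)
  list(
    kept = units[included, , drop = FALSE],
    report = tibble::tibble(
      unit_id = units$unit_id, included = included, reason = reason
    )
  )
}

#' Spike-to-oscillation phase locking
#'
#' Assigns each spike the oscillation phase at its nearest sample and
#' summarizes the spike-phase distribution: unweighted mean resultant
#' length, preferred (mean) phase, and Rayleigh test of circular
#' nonuniformity (Z = n * MRL^2).
#'
#' @param spike_times Numeric vector of spike times, seconds.
#' @param phase A `phase_series` (e.g. gamma phase from
#'   [instantaneous_phase()]).
#' @param rate Sampling rate of the phase series (from attributes if
#'   absent).
#' @param t0 Time of the first phase sample, seconds.
#' @param min_spikes Minimum spikes inside the phase support (default 10).
#' @return A one-row tibble: `n_spikes`, `mrl`, `preferred_phase`
#'   (radians), `rayleigh_z`, `rayleigh_p`.
#' @export
phase_locking <- function(spike_times, phase, rate = NULL, t0 = 0,
                          min_spikes = 10) {
  if (is.null(rate)) rate <- attr(phase, "rate")
  idx <- round((spike_times - t0) * rate) + 1L
  inside <- idx >= 1L & idx <= length(phase)
  if (!any(inside)) stop("no spikes inside the phase series support", call. = FALSE)
  ph <- as.numeric(phase)[idx[inside]]
  if (length(ph) < min_spikes) {
    stop(sprintf(
      "only %d spikes in support; need at least %d for phase locking",
      length(ph), min_spikes
    ), call. = FALSE)
  }
  ray <- rayleigh_test(ph)
  cs <- circ_stats(ph)
  tibble::tibble(
    n_spikes = length(ph), mrl = cs$mrl, preferred_phase = cs$mean_direction,
    rayleigh_z = ray$z, rayleigh_p = ray$p_value
  )
}

# Count spike pairs with |t1 - t2| <= window (inclusive), both trains sorted.
count_coincidences <- function(t1, t2, window) {
  lo <- findInterval(t1 - window, t2, left.open = TRUE)
  hi <- findInterval(t1 + window, t2)
  sum(hi - lo)
}

#' Normalized spike cross-correlogram
#'
#' The scalar CCG is \eqn{C_{12} / (T \sqrt{f_1 f_2})}, where C12 is the
#' raw count of spike pairs occurring within 1 ms of each other
#' (inclusive), T the duration of the analyzed segment, and f1, f2 the
#' mean firing rates. Dividing by T gives coincidences per second and the
#' geometric-mean rate normalization removes firing-rate dependence. The
#' lag-resolved curve bins pair lags (t2 - t1) at 0.5-ms resolution over
#' +/-50 ms with the same normalization per bin; `peak_height` is the
#' maximum over the bins covering -0.5 to 0.5 ms lag.
#'
#' @param train1,train2 Sorted spike-time vectors (seconds) of two units,
#'   restricted to `[0, T]`. Pairing a unit with itself measures
#'   autocorrelation; pipeline code excludes same-unit and
#'   same-stereotrode pairs.
#' @param T_dur Segment duration in seconds.
#' @param coincidence_window Half-width of the coincidence window for the
#'   scalar CCG, seconds (default 0.001).
#' @param lag_max Maximum lag of the curve, seconds (default 0.05).
#' @param bin_width Curve bin width, seconds (default 0.0005).
#' @return A `ccg_curve`: list with `curve` (tibble `lag_s`, `value`),
#'   `scalar_ccg`, `peak_height`, `c12`, `f1`, `f2`, `T_dur`.
#' @export
ccg <- function(train1, train2, T_dur, coincidence_window = 0.001,
                lag_max = 0.05, bin_width = 0.0005) {
  if (length(train1) == 0L || length(train2) == 0L) {
    stop("both spike trains must be non-empty (rate 0 is undefined)", call. = FALSE)
  }
  t1 <- sort(train1)
  t2 <- sort(train2)
  f1 <- length(t1) / T_dur
  f2 <- length(t2) / T_dur
  norm <- T_dur * sqrt(f1 * f2)
  c12 <- count_coincidences(t1, t2, coincidence_window)
  # lag-resolved curve: lag = t2 - t1 for every pair within +/- lag_max.
  # Bins are centered on multiples of bin_width; round-to-nearest (half to
  # even) assignment makes the (a,b) curve the exact mirror of (b,a).
  n_half <- round(lag_max / bin_width)
  n_bins <- 2L * n_half + 1L
  centers <- (-n_half:n_half) * bin_width
  lo <- findInterval(t1 - lag_max, t2, left.open = TRUE)
  hi <- findInterval(t1 + lag_max, t2)
  lags <- unlist(lapply(seq_along(t1), function(i) {
    if (hi[i] > lo[i]) t2[(lo[i] + 1L):hi[i]] - t1[i] else numeric(0)
  }))
  b <- round(lags / bin_width) + n_half + 1L
  b <- b[b >= 1L & b <= n_bins]
  counts <- tabulate(b, nbins = n_bins)
  values <- counts / norm
  central <- abs(centers) <= 0.0005 + 1e-12
  structure(
    list(
      curve = tibble::tibble(lag_s = centers, value = values),
      scalar_ccg = c12 / norm,
      peak_height = max(values[central]),
      c12 = c12, f1 = f1, f2 = f2, T_dur = T_dur
    ),
    class = "ccg_curve"
  )
}

#' @export
print.ccg_curve <- function(x, ...) {
  cat(sprintf(
    "<ccg_curve> f1 = %.2f Hz, f2 = %.2f Hz, T = %g s\n  C12 = %d, scalar CCG = %.4f, central peak = %.4f\n",
    x$f1, x$f2, x$T_dur, x$c12, x$scalar_ccg, x$peak_height
  ))
  invisible(x)
}

#' @describeIn ccg Lag-resolved curve as a tibble.
#' @param x A `ccg_curve`.
#' @param ... Unused.
#' @method tidy ccg_curve
#' @export
tidy.ccg_curve <- function(x, ...) x$curve

#' @describeIn ccg One-row scalar summary.
#' @method glance ccg_curve
#' @export
glance.ccg_curve <- function(x, ...) {
  tibble::tibble(
    scalar_ccg = x$scalar_ccg, peak_height = x$peak_height, c12 = x$c12,
    f1 = x$f1, f2 = x$f2, T_dur = x$T_dur
  )
}

#' Firing rate versus coupling strength by quartiles
#'
#' Splits a session's epochs into quartiles of coupling strength
#' (within-session ranks), z-scores each unit's per-epoch firing rate
#' across epochs, averages within unit, then within animal, then across
#' animals per quartile, and tests the rate-coupling link by regressing
#' the z-scored rate on the quartile index with animal indicator
#' covariates.
#'
#' @param epoch_data A tibble with one row per (unit, epoch):
#'   `unit_id`, `animal_id`, `epoch_id`, `coupling` (the epoch's PAC
#'   value, identical across units within an epoch), `rate_hz`.
#' @return A list with `quartile_means` (tibble `quartile`, `mean_z`,
#'   `sem_z`, `n_animals`), `per_unit` (tibble of unit x quartile means),
#'   `slope`, `slope_ci` (95%), `p_value`, `model` (the `lm` fit).
#' @export
firing_vs_coupling_quartiles <- function(epoch_data) {
  need <- c("unit_id", "animal_id", "epoch_id", "coupling", "rate_hz")
  stopifnot(all(need %in% names(epoch_data)))
  ep <- dplyr::distinct(epoch_data, .data$epoch_id, .data$coupling)
  if (nrow(ep) < 8L) {
    stop("need at least 8 epochs for a quartile split", call. = FALSE)
  }
  if (length(unique(ep$coupling)) < 4L) {
    stop("fewer than 4 distinct coupling values; quartiles undefined", call. = FALSE)
  }
  qs <- stats::quantile(ep$coupling, probs = c(0.25, 0.5, 0.75), type = 7)
  ep$quartile <- findInterval(ep$coupling, qs, left.open = TRUE) + 1L
  df <- dplyr::left_join(epoch_data, ep[, c("epoch_id", "quartile")],
    by = "epoch_id"
  ) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::mutate(z_rate = if (stats::sd(.data$rate_hz) > 0) {
      (.data$rate_hz - mean(.data$rate_hz)) / stats::sd(.data$rate_hz)
    } else {
      0
    }) |>
    dplyr::ungroup()
  per_unit <- df |>
    dplyr::group_by(.data$animal_id, .data$unit_id, .data$quartile) |>
    dplyr::summarise(mean_z = mean(.data$z_rate), .groups = "drop")
  per_animal <- per_unit |>
    dplyr::group_by(.data$animal_id, .data$quartile) |>
    dplyr::summarise(mean_z = mean(.data$mean_z), .groups = "drop")
  quartile_means <- per_animal |>
    dplyr::group_by(.data$quartile) |>
    dplyr::summarise(
      mean_z = mean(.data$mean_z),
      sem_z = stats::sd(.data$mean_z) / sqrt(dplyr::n()),
      n_animals = dplyr::n(), .groups = "drop"
    )
  # animal-indicator regression of unit x quartile means on quartile index
  fit_df <- per_unit
  fit <- if (length(unique(fit_df$animal_id)) > 1L) {
    stats::lm(mean_z ~ quartile + factor(animal_id), data = fit_df)
  } else {
    stats::lm(mean_z ~ quartile, data = fit_df)
  }
  co <- summary(fit)$coefficients
  ci <- stats::confint(fit, "quartile", level = 0.95)
  list(
    quartile_means = quartile_means,
    per_unit = per_unit,
    slope = co["quartile", "Estimate"],
    slope_ci = as.numeric(ci),
    p_value = co["quartile", "Pr(>|t|)"],
    model = fit
  )
}
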