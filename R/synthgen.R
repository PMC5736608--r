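# Synthetic LFP / spike / session generator with known ground truth.
#
# The generated world: a ventral-hippocampal trace carrying a theta
# oscillation plus 1/f noise, and a prefrontal trace carrying a lagged copy
# of theta plus slow- and fast-gamma carriers whose POWER envelope is a
# raised cosine of theta phase, 1 + m*cos(theta - preferred_phase), so the
# standard power-weighted MRL of a band equals m/2 in the noiseless
# limit. Spike trains are inhomogeneous Poisson, von Mises-locked to the
# gamma carrier phase.

#' Configuration for the synthetic generator
#'
#' Collects every generative parameter with validated defaults. Defaults
#' describe a typical rodent recording: 8-Hz theta, slow (30-70 Hz) and
#' fast (80-120 Hz) gamma bands, moderate modulation depths, 1/f noise,
#' 2000-Hz sampling.
#'
#' @param f_theta Theta frequency, Hz.
#' @param theta_amp Theta amplitude (arbitrary units, nominally uV).
#' @param slow_gamma_band,fast_gamma_band Length-2 bands in Hz; ordered,
#'   non-overlapping.
#' @param slow_gamma_amp,fast_gamma_amp Base carrier amplitudes.
#' @param mod_depth_slow,mod_depth_fast Power-modulation depths in \[0, 1\].
#' @param preferred_phase_slow,preferred_phase_fast Theta phase (radians)
#'   at which each band's power peaks; 0 = theta peak. Fast gamma defaults
#'   to the ascending phase (-pi/2).
#' @param noise_exponent 1/f^a noise slope a.
#' @param noise_amp Noise standard deviation (same units as theta_amp).
#' @param inter_region_theta_lag Phase lag (radians) of the prefrontal
#'   theta component relative to the hippocampal one.
#' @param spike_baseline_rate Mean unit firing rate r0, Hz.
#' @param spike_kappa Von Mises concentration of spike-gamma locking.
#' @param n_trials Trials per session (each contributes a sample and a
#'   choice center-arm epoch).
#' @param phase_effect Additive difference in slow-gamma modulation depth,
#'   choice minus sample, applied on correct trials only.
#' @param p_correct Probability a trial is correct (post-criterion
#'   performance).
#' @param duration_per_epoch Center-arm epoch duration, seconds (>= 1).
#' @param sample_rate Sampling rate, Hz (default 2000).
#' @param seed Default RNG seed used when a generator call omits one.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(f_theta = 8, theta_amp = 1,
                         slow_gamma_band = c(30, 70),
                         fast_gamma_band = c(80, 120),
                         slow_gamma_amp = 0.3, fast_gamma_amp = 0.2,
                         mod_depth_slow = 0.4, mod_depth_fast = 0.3,
                         preferred_phase_slow = 0,
                         preferred_phase_fast = -pi / 2,
                         noise_exponent = 1, noise_amp = 0.2,
                         inter_region_theta_lag = 0.35,
                         spike_baseline_rate = 5, spike_kappa = 2,
                         n_trials = 20, phase_effect = 0, p_correct = 0.8,
                         duration_per_epoch = 2, sample_rate = 2000,
                         seed = 1L) {
  cfg <- as.list(environment())
  bands_ok <- function(b) length(b) == 2 && b[1] > 0 && b[1] < b[2]
  if (!bands_ok(slow_gamma_band) || !bands_ok(fast_gamma_band)) {
    stop("gamma bands must be ordered (low < high) and positive", call. = FALSE)
  }
  if (slow_gamma_band[2] > fast_gamma_band[1]) {
    stop("slow and fast gamma bands must not overlap", call. = FALSE)
  }
  if (mod_depth_slow < 0 || mod_depth_slow > 1 ||
    mod_depth_fast < 0 || mod_depth_fast > 1) {
    stop("modulation depths must lie in [0, 1]", call. = FALSE)
  }
  if (sample_rate <= 2 * fast_gamma_band[2]) {
    stop("sample_rate must exceed twice the highest band edge", call. = FALSE)
  }
  if (duration_per_epoch < 1) {
    stop("duration_per_epoch must be at least 1 s", call. = FALSE)
  }
  if (p_correct < 0 || p_correct > 1) stop("p_correct must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# 1/f^a noise by spectral shaping of white Gaussian noise; unit variance.
pink_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency index, DC guarded
  W <- W * f^(-exponent / 2)
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

# Gamma carrier with per-theta-cycle frequency jitter (+/-10% around the
# band center). Returns the carrier cosine and its instantaneous phase.
gamma_carrier <- function(theta_cycle, n, rate, band) {
  fc <- mean(band)
  n_cycles <- max(theta_cycle) + 1L
  jit <- stats::runif(n_cycles, -0.1, 0.1)
  f_inst <- fc * (1 + jit[theta_cycle + 1L])
  ph <- cumsum(2 * pi * f_inst / rate) + stats::runif(1, -pi, pi)
  list(carrier = cos(ph), phase = wrap_pi(ph))
}

# Core generator: per-sample modulation depths allowed (used by
# gen_session to vary depth across epochs without boundary transients).
gen_pair_core <- function(cfg, n, m_slow, m_fast) {
  rate <- cfg$sample_rate
  t <- (seq_len(n) - 1) / rate
  theta_ph <- wrap_pi(2 * pi * cfg$f_theta * t)
  cyc <- floor(cfg$f_theta * t)
  vhpc <- cfg$theta_amp * cos(theta_ph)
  if (cfg$noise_amp > 0) {
    vhpc <- vhpc + cfg$noise_amp * pink_noise(n, cfg$noise_exponent)
  }
  env_s <- cfg$slow_gamma_amp *
    sqrt(pmax(0, 1 + m_slow * cos(theta_ph - cfg$preferred_phase_slow)))
  env_f <- cfg$fast_gamma_amp *
    sqrt(pmax(0, 1 + m_fast * cos(theta_ph - cfg$preferred_phase_fast)))
  car_s <- gamma_carrier(cyc, n, rate, cfg$slow_gamma_band)
  car_f <- gamma_carrier(cyc, n, rate, cfg$fast_gamma_band)
  mpfc <- cfg$theta_amp * cos(theta_ph - cfg$inter_region_theta_lag) +
    env_s * car_s$carrier + env_f * car_f$carrier
  if (cfg$noise_amp > 0) {
    mpfc <- mpfc + cfg$noise_amp * pink_noise(n, cfg$noise_exponent)
  }
  list(
    vhpc = vhpc, mpfc = mpfc, theta_phase = theta_ph,
    slow_gamma_phase = car_s$phase, fast_gamma_phase = car_f$phase
  )
}

#' Generate a matched vHPC / mPFC LFP pair
#'
#' The hippocampal trace is a theta cosine plus 1/f noise; the prefrontal
#' trace adds a phase-lagged theta component and two gamma carriers whose
#' power envelopes follow a raised cosine of (hippocampal) theta phase with
#' the configured depths and preferred phases, plus 1/f noise.
#'
#' @param config A [synth_config()].
#' @param duration Duration in seconds.
#' @param seed Integer RNG seed (defaults to `config$seed`). Identical
#'   `(config, seed)` give bit-identical output.
#' @return A list with `vhpc` and `mpfc` ([lfp_recording()]s) and `truth`,
#'   a list holding the generative theta phase, gamma carrier phases,
#'   modulation depths and preferred phases.
#' @export
#' @examples
#' pair <- gen_lfp_pair(synth_config(noise_amp = 0), duration = 10, seed = 1)
gen_lfp_pair <- function(config, duration = 60, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"), is.finite(duration), duration > 0)
  set.seed(seed)
  n <- round(duration * config$sample_rate)
  g <- gen_pair_core(config, n, config$mod_depth_slow, config$mod_depth_fast)
  truth <- list(
    mod_depth_slow = config$mod_depth_slow,
    mod_depth_fast = config$mod_depth_fast,
    preferred_phase_slow = config$preferred_phase_slow,
    preferred_phase_fast = config$preferred_phase_fast,
    theta_phase = g$theta_phase,
    slow_gamma_phase = structure(g$slow_gamma_phase,
      class = "phase_series", rate = config$sample_rate,
      band = config$slow_gamma_band, n_edge = 0L
    ),
    fast_gamma_phase = structure(g$fast_gamma_phase,
      class = "phase_series", rate = config$sample_rate,
      band = config$fast_gamma_band, n_edge = 0L
    ),
    seed = seed
  )
  list(
    vhpc = lfp_recording(g$vhpc, config$sample_rate, "vHPC"),
    mpfc = lfp_recording(g$mpfc, config$sample_rate, "mPFC"),
    truth = truth
  )
}

#' Generate gamma-locked spike trains
#'
#' Inhomogeneous Poisson units with intensity
#' \eqn{r(t) = r_0 \exp(\kappa \cos(\phi_\gamma(t) - \psi)) / I_0(\kappa)},
#' so the mean rate is r0. A configurable fraction of units is locked
#' (concentration `kappa`); the rest have kappa = 0 (uniform phases).
#' Simulated by thinning a homogeneous Poisson process at the intensity
#' maximum.
#'
#' @param config A [synth_config()] (supplies `spike_baseline_rate` and
#'   `spike_kappa` defaults).
#' @param gamma_phase A `phase_series` covering the session (the gamma
#'   carrier phase from [gen_lfp_pair()] ground truth, or an estimated
#'   phase).
#' @param n_units Number of units.
#' @param seed RNG seed.
#' @param frac_locked Fraction of units with kappa > 0 (default 1).
#' @param psi Optional vector of preferred gamma phases per unit; drawn
#'   uniformly when NULL.
#' @return A list with `units`, a tibble (`unit_id`, `times` list-column,
#'   `l_ratio`, `isolation_distance`, `region`, `stereotrode_id`) and
#'   `truth`, a tibble (`unit_id`, `kappa`, `psi`, `rate_hz`, `locked`).
#' @export
gen_spike_trains <- function(config, gamma_phase, n_units = 8,
                             seed = config$seed, frac_locked = 1,
                             psi = NULL) {
  stopifnot(inherits(config, "synth_config"))
  r0 <- config$spike_baseline_rate
  if (r0 <= 0) stop("spike_baseline_rate must be positive", call. = FALSE)
  rate <- attr(gamma_phase, "rate")
  if (is.null(rate)) stop("gamma_phase must carry a sampling rate", call. = FALSE)
  set.seed(seed)
  T_tot <- length(gamma_phase) / rate
  n_locked <- round(frac_locked * n_units)
  kap <- c(rep(config$spike_kappa, n_locked), rep(0, n_units - n_locked))
  if (is.null(psi)) psi <- stats::runif(n_units, -pi, pi)
  psi <- rep_len(psi, n_units)
  psi[kap == 0] <- NA_real_
  trains <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    if (kap[u] == 0) {
      nsp <- stats::rpois(1, r0 * T_tot)
      trains[[u]] <- sort(stats::runif(nsp, 0, T_tot))
    } else {
      lam_max <- r0 * exp(kap[u]) / besselI(kap[u], 0)
      ncand <- stats::rpois(1, lam_max * T_tot)
      cand <- sort(stats::runif(ncand, 0, T_tot))
      idx <- pmin(pmax(round(cand * rate) + 1L, 1L), length(gamma_phase))
      keep <- stats::runif(ncand) <
        exp(kap[u] * (cos(gamma_phase[idx] - psi[u]) - 1))
      trains[[u]] <- cand[keep]
    }
  }
  ids <- sprintf("unit%02d", seq_len(n_units))
  units <- tibble::tibble(
    unit_id = ids,
    times = trains,
    l_ratio = stats::runif(n_units, 0, 0.05),
    isolation_distance = stats::runif(n_units, 15, 40),
    region = "mPFC",
    stereotrode_id = sprintf("st%02d", seq_len(n_units))
  )
  truth <- tibble::tibble(
    unit_id = ids, kappa = kap, psi = psi, rate_hz = r0, locked = kap > 0
  )
  list(units = units, truth = truth)
}

#' Generate a full trial-structured session
#'
#' Concatenates `n_trials` sample and choice center-arm epochs (each
#' `duration_per_epoch` seconds) into one continuous LFP pair. The
#' slow-gamma modulation depth is `mod_depth_slow` during sample epochs
#' and, on correct trials only, `mod_depth_slow + phase_effect` during
#' choice epochs. Correctness is Bernoulli(`p_correct`). Spike trains are
#' locked to the slow-gamma carrier.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed.
#' @param n_units Units to simulate (0 to skip spikes).
#' @param frac_locked Fraction of locked units.
#' @return A list: `vhpc`, `mpfc` (LFP recordings), `spikes` (unit tibble
#'   or NULL), `trials` (tibble: `trial_id`, `phase`, `t_start_s`,
#'   `t_end_s`, `correct`, `delay_s`, `light`, `opsin`), and `truth`
#'   (per-epoch depth tibble, per-unit locking tibble, carrier phases).
#' @export
gen_session <- function(config, seed = config$seed, n_units = 8,
                        frac_locked = 0.5) {
  stopifnot(inherits(config, "synth_config"), config$n_trials >= 1)
  set.seed(seed)
  rate <- config$sample_rate
  n_ep <- round(config$duration_per_epoch * rate)
  n_tr <- config$n_trials
  correct <- stats::runif(n_tr) < config$p_correct
  trials <- tibble::tibble(
    trial_id = rep(seq_len(n_tr), each = 2),
    phase = rep(c("sample", "choice"), times = n_tr),
    correct = rep(correct, each = 2),
    delay_s = 10, light = "off", opsin = "none"
  )
  trials$t_start_s <- (seq_len(2 * n_tr) - 1) * config$duration_per_epoch
  trials$t_end_s <- trials$t_start_s + config$duration_per_epoch
  m_epoch <- ifelse(
    trials$phase == "choice" & trials$correct,
    pmin(1, config$mod_depth_slow + config$phase_effect),
    config$mod_depth_slow
  )
  m_slow <- rep(m_epoch, each = n_ep)
  n <- n_ep * 2L * n_tr
  g <- gen_pair_core(config, n, m_slow, config$mod_depth_fast)
  slow_phase <- structure(g$slow_gamma_phase,
    class = "phase_series", rate = rate,
    band = config$slow_gamma_band, n_edge = 0L
  )
  spikes <- NULL
  sp_truth <- NULL
  if (n_units > 0) {
    sp <- gen_spike_trains(config, slow_phase,
      n_units = n_units,
      seed = seed + 1L, frac_locked = frac_locked
    )
    spikes <- sp$units
    sp_truth <- sp$truth
  }
  truth <- list(
    epochs = dplyr::mutate(
      trials[, c("trial_id", "phase", "correct")],
      epoch_id = dplyr::row_number(),
      mod_depth_slow = m_epoch, mod_depth_fast = config$mod_depth_fast
    ),
    units = sp_truth,
    theta_phase = g$theta_phase,
    slow_gamma_phase = slow_phase,
    seed = seed
  )
  list(
    vhpc = lfp_recording(g$vhpc, rate, "vHPC"),
    mpfc = lfp_recording(g$mpfc, rate, "mPFC"),
    spikes = spikes,
    trials = trials[, c(
      "trial_id", "phase", "t_start_s", "t_end_s",
      "correct", "delay_s", "light", "opsin"
    )],
    truth = truth
  )
}

#' Write / read a synthetic session to a directory
#'
#' On-disk layout: `vhpc.f32`/`vhpc.json` and `mpfc.f32`/`mpfc.json`
#' (float32 + sidecar), `spikes.csv` (`unit_id`, `time_s`, `l_ratio`,
#' `isolation_distance`, `region`, `stereotrode_id`), `trials.csv`, and
#' `ground_truth.json`.
#'
#' @param session The list returned by [gen_session()].
#' @param dir Output directory (created if missing).
#' @return `write_session` returns `dir` invisibly; `read_session` returns
#'   a session list (`vhpc`, `mpfc`, `spikes`, `trials`; no ground-truth
#'   phases, which are kept scalar in the JSON).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lfp(session$vhpc, file.path(dir, "vhpc"))
  write_lfp(session$mpfc, file.path(dir, "mpfc"))
  if (!is.null(session$spikes)) {
    sp <- tidyr::unnest(
      session$spikes[, c(
        "unit_id", "times", "l_ratio",
        "isolation_distance", "region", "stereotrode_id"
      )],
      "times"
    )
    names(sp)[names(sp) == "times"] <- "time_s"
    utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  }
  utils::write.csv(session$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  gt <- session$truth
  jsonlite::write_json(
    list(
      epochs = gt$epochs, units = gt$units, seed = gt$seed
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  need <- c("vhpc.f32", "mpfc.f32", "trials.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing session file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  spikes <- NULL
  spk_path <- file.path(dir, "spikes.csv")
  if (file.exists(spk_path)) {
    sp <- utils::read.csv(spk_path, stringsAsFactors = FALSE)
    spikes <- sp |>
      dplyr::group_by(
        .data$unit_id, .data$l_ratio, .data$isolation_distance,
        .data$region, .data$stereotrode_id
      ) |>
      dplyr::summarise(times = list(sort(.data$time_s)), .groups = "drop") |>
      dplyr::select(
        "unit_id", "times", "l_ratio", "isolation_distance",
        "region", "stereotrode_id"
      ) |>
      dplyr::arrange(.data$unit_id)
  }
  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  list(
    vhpc = read_lfp(file.path(dir, "vhpc")),
    mpfc = read_lfp(file.path(dir, "mpfc")),
    spikes = spikes,
    trials = tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv"),
      stringsAsFactors = FALSE
    )),
    truth = truth
  )
}
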