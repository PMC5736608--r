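# Trial/epoch orchestration and behavior-linked statistics.

#' Per-epoch coupling series over a trial table
#'
#' Computes the theta-phase/gamma-power series once for the whole session,
#' then one weighted-MRL coupling value per center-arm epoch (trial-table
#' row), plus one pooled PAC profile per trial phase. Epochs can be
#' subset with dplyr-style filter conditions in `...` (e.g.
#' `correct`, `phase == "choice"`). Epochs contributing less than
#' `min_epoch` seconds of valid data (after edge trimming) are dropped and
#' counted.
#'
#' @param phase_lfp,amp_lfp Time-aligned [lfp_recording()]s.
#' @param trials Trial table with `trial_id`, `phase`, `t_start_s`,
#'   `t_end_s` (plus any columns used in `...`).
#' @param ... Optional filter conditions evaluated in the trial table.
#' @param phase_band,amp_band Bands in Hz.
#' @param freq_step Wavelet grid step inside `amp_band`, Hz.
#' @param min_epoch Minimum usable epoch duration, seconds (default 0.5).
#' @return A list with `per_epoch` (tibble: trial columns + `coupling`,
#'   `mean_direction`, `n_samples`), `pooled` (tibble: one row per trial
#'   phase with pooled `mrl`, `mean_direction`), and `n_dropped`.
#' @export
epoch_coupling_series <- function(phase_lfp, amp_lfp, trials, ...,
                                  phase_band = c(4, 12),
                                  amp_band = c(30, 70), freq_step = 1,
                                  min_epoch = 0.5) {
  sel <- dplyr::filter(trials, ...)
  if (nrow(sel) == 0L) {
    cond <- paste(vapply(rlang::enquos(...), rlang::as_label, ""), collapse = ", ")
    stop("epoch selector removed every trial row",
      if (nzchar(cond)) paste0(" (", cond, ")") else "",
      call. = FALSE
    )
  }
  rate <- lfp_rate(phase_lfp)
  pp <- pac_phase_power(phase_lfp, amp_lfp, phase_band, amp_band,
    freq_step = freq_step
  )
  res <- lapply(seq_len(nrow(sel)), function(i) {
    idx <- intersect(
      epochs_to_idx(sel[i, ], rate, nrow(phase_lfp), lfp_t0(phase_lfp)),
      pp$valid
    )
    if (length(idx) / rate < min_epoch) {
      return(tibble::tibble(
        coupling = NA_real_, mean_direction = NA_real_,
        n_samples = length(idx)
      ))
    }
    r <- pac_from_phase_power(pp$phase, pp$power, idx)
    tibble::tibble(
      coupling = r$mrl, mean_direction = r$mean_direction,
      n_samples = r$n_samples
    )
  })
  per_epoch <- dplyr::bind_cols(sel, dplyr::bind_rows(res))
  n_dropped <- sum(is.na(per_epoch$coupling))
  kept <- per_epoch[!is.na(per_epoch$coupling), , drop = FALSE]
  pooled <- kept |>
    dplyr::group_by(.data$phase) |>
    dplyr::group_modify(function(d, key) {
      idx <- intersect(
        epochs_to_idx(d, rate, nrow(phase_lfp), lfp_t0(phase_lfp)),
        pp$valid
      )
      r <- pac_from_phase_power(pp$phase, pp$power, idx)
      tibble::tibble(
        mrl = r$mrl, mean_direction = r$mean_direction,
        n_samples = r$n_samples, n_epochs = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  list(per_epoch = per_epoch, pooled = pooled, n_dropped = n_dropped)
}

#' Paired and unpaired two-sample contrasts
#'
#' Thin, bookkeeping-safe wrappers used for the session contrasts
#' (choice vs sample, long vs short delay): a paired or unpaired Student
#' t-test returning tidy output.
#'
#' @param values_a,values_b Numeric vectors; equal length when paired.
#' @param paired Paired test (default TRUE).
#' @return One-row tibble: `estimate` (mean difference a - b),
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
coupling_contrast <- function(values_a, values_b, paired = TRUE) {
  if (paired && length(values_a) != length(values_b)) {
    stop("paired contrast requires equal-length vectors", call. = FALSE)
  }
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (paired && stats::sd(values_a - values_b) == 0) {
    # identical vectors: t is 0/0; report the null result directly
    return(tibble::tibble(
      estimate = mean(values_a - values_b), statistic = 0,
      df = length(values_a) - 1, p_value = 1, method = "paired t-test"
    ))
  }
  tt <- stats::t.test(values_a, values_b, paired = paired, var.equal = !paired)
  tibble::tibble(
    estimate = unname(if (paired) tt$estimate else diff(rev(tt$estimate))),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = if (paired) "paired t-test" else "two-sample t-test"
  )
}

#' Two-way ANOVA for factorial session designs
#'
#' Fits `response ~ A * B` and reports Type II sums of squares for the
#' two main effects and their interaction (Type II matches Type I/III on
#' balanced designs and is robust to the mildly unbalanced trial counts a
#' real session produces), with exact degree-of-freedom bookkeeping.
#'
#' @param data A data frame.
#' @param response,factor_a,factor_b Column names (strings).
#' @return A tibble with one row per term (`A`, `B`, `A:B`, `Residuals`):
#'   `term`, `sumsq`, `df`, `statistic`, `p_value`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  if (nlevels(data[[factor_a]]) < 2L || nlevels(data[[factor_b]]) < 2L) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  cell_n <- table(data[[factor_a]], data[[factor_b]])
  if (any(cell_n < 2L)) {
    stop("every factor cell needs at least 2 observations", call. = FALSE)
  }
  fml <- stats::as.formula(
    paste(response, "~", factor_a, "*", factor_b)
  )
  fit <- stats::lm(fml, data = data)
  aa <- car::Anova(fit, type = 2)
  tibble::tibble(
    term = rownames(aa),
    sumsq = aa$`Sum Sq`,
    df = aa$Df,
    statistic = aa$`F value`,
    p_value = aa$`Pr(>F)`
  )
}

#' Session-level coupling-accuracy correlation
#'
#' Pearson correlation between per-session coupling strength and choice
#' accuracy at the session level; an animal-level correlation of
#' per-animal means; and, because sessions are nested in animals, a
#' significance test from a multiple regression of accuracy on coupling
#' with animal indicator covariates.
#'
#' @param sessions A tibble with `coupling`, `accuracy` (in \[0, 1\]) and
#'   `animal_id`, one row per session; at least 3 rows.
#' @return A tibble with rows `session`, `animal`, `regression`:
#'   `level`, `r` (NA for the regression row), `statistic`, `df`,
#'   `p_value`, `n`.
#' @export
accuracy_correlation <- function(sessions) {
  stopifnot(all(c("coupling", "accuracy", "animal_id") %in% names(sessions)))
  if (nrow(sessions) < 3L) stop("need at least 3 sessions", call. = FALSE)
  if (any(sessions$accuracy < 0 | sessions$accuracy > 1)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  if (stats::sd(sessions$coupling) == 0 || stats::sd(sessions$accuracy) == 0) {
    stop("zero variance in coupling or accuracy; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(sessions$coupling, sessions$accuracy)
  out <- tibble::tibble(
    level = "session", r = unname(ct$estimate),
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value, n = nrow(sessions)
  )
  by_animal <- sessions |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      coupling = mean(.data$coupling), accuracy = mean(.data$accuracy),
      .groups = "drop"
    )
  if (nrow(by_animal) >= 3L &&
    stats::sd(by_animal$coupling) > 0 && stats::sd(by_animal$accuracy) > 0) {
    ca <- stats::cor.test(by_animal$coupling, by_animal$accuracy)
    out <- dplyr::bind_rows(out, tibble::tibble(
      level = "animal", r = unname(ca$estimate),
      statistic = unname(ca$statistic), df = unname(ca$parameter),
      p_value = ca$p.value, n = nrow(by_animal)
    ))
  }
  fit <- if (length(unique(sessions$animal_id)) > 1L) {
    stats::lm(accuracy ~ coupling + factor(animal_id), data = sessions)
  } else {
    stats::lm(accuracy ~ coupling, data = sessions)
  }
  co <- summary(fit)$coefficients
  out <- dplyr::bind_rows(out, tibble::tibble(
    level = "regression", r = NA_real_,
    statistic = co["coupling", "t value"],
    df = fit$df.residual,
    p_value = co["coupling", "Pr(>|t|)"],
    n = nrow(sessions)
  ))
  out
}

#' Choice-versus-sample contrast over simulated sessions
#'
#' Generates `n_sessions` independent synthetic sessions, computes the
#' mean per-epoch coupling for sample and choice center-arm runs on
#' correct trials in each, and tests choice > sample with a paired t-test
#' across sessions. This is the end-to-end recovery experiment for the
#' generator's `phase_effect`.
#'
#' @param config A [synth_config()].
#' @param n_sessions Number of sessions (default 10).
#' @param seed Base seed; session s uses `seed + s`.
#' @param freq_step Wavelet grid step for the coupling computation, Hz.
#' @return A list with `per_session` (tibble `session`, `sample`,
#'   `choice`) and `test` (the [coupling_contrast()] row for
#'   choice vs sample).
#' @export
phase_contrast_experiment <- function(config, n_sessions = 10, seed = 1,
                                      freq_step = 2) {
  per <- purrr::map_dfr(seq_len(n_sessions), function(s) {
    ses <- gen_session(config, seed = seed + s, n_units = 0)
    ec <- epoch_coupling_series(ses$vhpc, ses$mpfc, ses$trials,
      .data$correct,
      freq_step = freq_step
    )
    ec$per_epoch |>
      dplyr::filter(!is.na(.data$coupling)) |>
      dplyr::group_by(.data$phase) |>
      dplyr::summarise(coupling = mean(.data$coupling), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "phase", values_from = "coupling") |>
      dplyr::mutate(session = s, .before = 1)
  })
  list(
    per_session = per,
    test = coupling_contrast(per$choice, per$sample, paired = TRUE)
  )
}

#' Run the full session pipeline on a data directory
#'
#' Reads a session written by [write_session()] (or the `simulate` CLI),
#' runs the spectral front end, per-epoch and pooled coupling, the
#' choice-versus-sample paired contrast on correct trials, gamma-peak
#' phase statistics, unit quality filtering and spike-gamma phase
#' locking, and pairwise CCGs; writes a JSON report plus CSV tables to
#' `out_dir`. The computation is deterministic: identical inputs give a
#' byte-identical report.
#'
#' @param data_dir Directory containing `vhpc.f32/json`, `mpfc.f32/json`,
#'   `trials.csv` and optionally `spikes.csv`.
#' @param out_dir Output directory (created if needed).
#' @param phase_band,amp_band Bands in Hz.
#' @param freq_step Wavelet grid step, Hz (default 2 for speed).
#' @return The report list, invisibly; side effect: `report.json`,
#'   `epoch_couplings.csv`, `unit_locking.csv`, `ccg_pairs.csv` in
#'   `out_dir`.
#' @export
run_pipeline <- function(data_dir, out_dir, phase_band = c(4, 12),
                         amp_band = c(30, 70), freq_step = 2) {
  ses <- read_session(data_dir)
  if (!any(ses$trials$phase == "choice")) {
    stop("trial table contains no choice epochs", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ec <- epoch_coupling_series(ses$vhpc, ses$mpfc, ses$trials,
    phase_band = phase_band, amp_band = amp_band, freq_step = freq_step
  )
  per_epoch <- ec$per_epoch
  # paired choice vs sample on correct trials with both epochs usable
  paired <- per_epoch |>
    dplyr::filter(.data$correct, !is.na(.data$coupling)) |>
    dplyr::select("trial_id", "phase", "coupling") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "coupling") |>
    dplyr::filter(!is.na(.data$sample), !is.na(.data$choice))
  contrast <- if (nrow(paired) >= 2L) {
    coupling_contrast(paired$choice, paired$sample, paired = TRUE)
  } else {
    NULL
  }
  # gamma peaks on the mPFC slow-gamma band, phases from vHPC theta
  fg <- bandpass_zero_phase(ses$mpfc, amp_band)
  peaks <- detect_gamma_peaks(fg)
  th <- instantaneous_phase(bandpass_zero_phase(ses$vhpc, phase_band))
  pph <- peak_phase_histogram(peaks, th)
  # units: quality filter, slow-gamma phase locking, pairwise CCGs
  unit_locking <- NULL
  ccg_pairs <- NULL
  if (!is.null(ses$spikes)) {
    flt <- filter_units(ses$spikes)
    gph <- instantaneous_phase(fg)
    unit_locking <- flt$kept |>
      dplyr::mutate(pl = purrr::map(.data$times, phase_locking, phase = gph)) |>
      tidyr::unnest("pl") |>
      dplyr::mutate(locked = .data$rayleigh_p < 0.05) |>
      dplyr::select(
        "unit_id", "n_spikes", "mrl", "preferred_phase",
        "rayleigh_p", "locked", "stereotrode_id"
      )
    T_dur <- nrow(ses$mpfc) / lfp_rate(ses$mpfc)
    kept <- flt$kept
    if (nrow(kept) >= 2L) {
      pairs <- utils::combn(nrow(kept), 2)
      ccg_pairs <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]
        j <- pairs[2, k]
        if (kept$stereotrode_id[i] == kept$stereotrode_id[j]) {
          return(NULL)
        }
        g <- glance(ccg(kept$times[[i]], kept$times[[j]], T_dur))
        dplyr::mutate(g,
          unit_a = kept$unit_id[i], unit_b = kept$unit_id[j],
          .before = 1
        )
      })
    }
  }
  report <- list(
    package_version = as.character(utils::packageVersion("thetagamma")),
    parameters = list(
      phase_band = phase_band, amp_band = amp_band, freq_step = freq_step
    ),
    n_trials = length(unique(ses$trials$trial_id)),
    n_epochs_total = nrow(ses$trials),
    n_epochs_dropped = ec$n_dropped,
    pooled_coupling = ec$pooled,
    choice_vs_sample_correct = contrast,
    gamma_peaks = list(
      n_peaks = pph$n_peaks,
      mean_direction_deg = pph$mean_direction * 180 / pi,
      mrl = pph$mrl
    ),
    n_units_kept = if (is.null(unit_locking)) 0L else nrow(unit_locking)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null"
  )
  utils::write.csv(per_epoch |> dplyr::select(-dplyr::any_of("times")),
    file.path(out_dir, "epoch_couplings.csv"),
    row.names = FALSE
  )
  if (!is.null(unit_locking)) {
    utils::write.csv(unit_locking, file.path(out_dir, "unit_locking.csv"),
      row.names = FALSE
    )
  }
  if (!is.null(ccg_pairs) && nrow(ccg_pairs) > 0) {
    utils::write.csv(ccg_pairs, file.path(out_dir, "ccg_pairs.csv"),
      row.names = FALSE
    )
  }
  invisible(report)
}
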