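test_that("unit quality filter: inclusive bounds, reasons, bookkeeping", {
  u <- tibble::tibble(
    unit_id = sprintf("u%02d", 1:10),
    l_ratio = c(0.1, 0.2, 0.05, 0.01, NA, 0.02, 0.3, 0.08, 0.0, 0.09),
    isolation_distance = c(10, 50, 8, 30, 20, 15, 5, 40, 12, 25)
  )
  out <- filter_units(u)
  rep <- out$report
  expect_true(rep$included[rep$unit_id == "u01"]) # both at the bound: kept
  expect_equal(rep$reason[rep$unit_id == "u02"], "l_ratio")
  expect_equal(rep$reason[rep$unit_id == "u03"], "isolation_distance")
  expect_equal(rep$reason[rep$unit_id == "u05"], "missing")
  expect_equal(rep$reason[rep$unit_id == "u07"], "both")
  expect_equal(sum(!rep$included), 4)
  expect_equal(nrow(out$kept), 6)
  # exactly 3 violating units -> exactly 7 kept
  u2 <- dplyr::mutate(u,
    isolation_distance = replace(isolation_distance, 3, 11),
    l_ratio = replace(l_ratio, 5, 0.05)
  )
  u2$l_ratio[7] <- 0.3
  u2$isolation_distance[2] <- 50
  u2$l_ratio[9] <- NA
  out2 <- filter_units(u2)
  expect_equal(nrow(out2$kept), 7)
})

test_that("phase locking: degenerate concentration and guards", {
  ph <- structure(rep(c(0.5, 0.5), 500), class = "phase_series", rate = 1000)
  pl <- phase_locking(seq(0.01, 0.99, length.out = 50), ph)
  expect_equal(pl$mrl, 1)
  expect_lt(pl$rayleigh_p, 1e-6)
  expect_equal(pl$preferred_phase, 0.5)
  expect_error(phase_locking(5000, ph), "no spikes inside")
  expect_error(phase_locking(seq(0.1, 0.2, length.out = 5), ph), "at least 10")
})

test_that("phase locking type-I error is near alpha for uniform phases", {
  set.seed(71)
  ph <- structure(runif(20000, -pi, pi), class = "phase_series", rate = 1000)
  rej <- mean(replicate(600, {
    st <- runif(100, 0, 19.9)
    phase_locking(st, ph)$rayleigh_p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("scalar CCG closed forms: identity, shift, Poisson expectation", {
  set.seed(72)
  tr <- cumsum(runif(400, 0.008, 0.02))
  T_dur <- max(tr) + 0.01
  expect_identical(ccg(tr, tr, T_dur)$scalar_ccg, 1)
  sh <- ccg(tr, tr + 0.0052, T_dur)
  expect_equal(sh$scalar_ccg, 0)
  expect_equal(sh$curve$lag_s[which.max(sh$curve$value)], 0.005)

  vals <- replicate(40, {
    a <- sort(runif(5000, 0, 500))
    b <- sort(runif(5000, 0, 500))
    ccg(a, b, 500)$scalar_ccg
  })
  # E[scalar] = 2 ms * sqrt(f1 f2) = 0.002 * 10 = 0.02
  expect_equal(mean(vals), 0.02, tolerance = 0.15)
  expect_error(ccg(numeric(0), tr, 10), "non-empty")
})

test_that("C12 matches the brute-force double loop", {
  set.seed(73)
  for (i in 1:5) {
    a <- sort(runif(300, 0, 10))
    b <- sort(runif(250, 0, 10))
    expect_equal(ccg(a, b, 10)$c12, brute_c12(a, b))
  }
})

test_that("CCG is symmetric and its curve mirrors under argument swap", {
  set.seed(74)
  a <- sort(runif(2000, 0, 100))
  b <- sort(runif(1500, 0, 100))
  ab <- ccg(a, b, 100)
  ba <- ccg(b, a, 100)
  expect_identical(ab$scalar_ccg, ba$scalar_ccg)
  expect_identical(ab$curve$value, rev(ba$curve$value))
})

test_that("geometric-mean normalization makes the CCG rate-invariant", {
  set.seed(75)
  res <- replicate(40, {
    a <- sort(runif(8000, 0, 400))
    b <- sort(runif(8000, 0, 400))
    full <- ccg(a, b, 400)$scalar_ccg
    thin <- ccg(
      a[runif(length(a)) < 0.5], b[runif(length(b)) < 0.5], 400
    )$scalar_ccg
    c(full, thin)
  })
  expect_equal(mean(res[1, ]), mean(res[2, ]), tolerance = 0.15)
})

test_that("quartile analysis: degenerate rates, guards", {
  ep <- tibble::tibble(epoch_id = 1:16, coupling = seq(0.05, 0.35, length.out = 16))
  df <- tidyr::expand_grid(unit_id = 1:4, ep) |>
    dplyr::mutate(animal_id = rep(1:2, each = 32), rate_hz = 5)
  out <- firing_vs_coupling_quartiles(df)
  expect_true(all(out$quartile_means$mean_z == 0))
  expect_equal(out$slope, 0, tolerance = 1e-12)
  expect_error(
    firing_vs_coupling_quartiles(dplyr::filter(df, epoch_id <= 6)),
    "at least 8"
  )
  df2 <- dplyr::mutate(df, coupling = 0.1)
  expect_error(firing_vs_coupling_quartiles(df2), "distinct coupling")
})

test_that("quartile analysis recovers a positive rate-coupling link", {
  sim_q <- function(b, seed) {
    set.seed(seed)
    ep <- tibble::tibble(epoch_id = 1:24, coupling = runif(24, 0.05, 0.3))
    df <- tidyr::expand_grid(unit_id = 1:6, ep) |>
      dplyr::mutate(
        animal_id = (unit_id - 1) %% 3 + 1,
        rate_hz = 5 + b * coupling + rnorm(dplyr::n(), 0, 0.5)
      )
    firing_vs_coupling_quartiles(df)
  }
  pos <- vapply(1:20, function(s) sim_q(10, s)$slope > 0, logical(1))
  expect_gte(mean(pos), 0.95)
  set.seed(76)
  cover <- vapply(1:150, function(s) {
    r <- sim_q(0, s + 500)
    r$slope_ci[1] < 0 && r$slope_ci[2] > 0
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1)
})

test_that("shared-envelope pairs show higher synchrony in top coupling quartile", {
  # two units driven by a common slow-gamma envelope: epochs with strong
  # coupling concentrate spikes at the same phase, raising coincidences
  set.seed(77)
  rate <- 2000
  dur <- 40
  ph <- structure(wrap_pi(2 * pi * 50 * seq(0, dur, by = 1 / rate)),
    class = "phase_series", rate = rate
  )
  cfg_hi <- synth_config(spike_baseline_rate = 30, spike_kappa = 4)
  cfg_lo <- synth_config(spike_baseline_rate = 30, spike_kappa = 0.01)
  hi <- gen_spike_trains(cfg_hi, ph, n_units = 2, seed = 78, psi = c(0, 0))
  lo <- gen_spike_trains(cfg_lo, ph, n_units = 2, seed = 79, psi = c(0, 0))
  ccg_hi <- ccg(hi$units$times[[1]], hi$units$times[[2]], dur)$scalar_ccg
  ccg_lo <- ccg(lo$units$times[[1]], lo$units$times[[2]], dur)$scalar_ccg
  expect_gt(ccg_hi, ccg_lo)
})
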