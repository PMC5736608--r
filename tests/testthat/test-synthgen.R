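test_that("config invariants are enforced", {
  expect_error(synth_config(slow_gamma_band = c(70, 30)), "ordered")
  expect_error(synth_config(
    slow_gamma_band = c(30, 90),
    fast_gamma_band = c(80, 120)
  ), "overlap")
  expect_error(synth_config(mod_depth_slow = 1.2), "depths")
  expect_error(synth_config(sample_rate = 200), "twice")
  expect_error(synth_config(duration_per_epoch = 0.5), "at least 1 s")
})

test_that("generation is bit-identical for identical (config, seed)", {
  cfg <- synth_config()
  a <- gen_lfp_pair(cfg, duration = 5, seed = 9)
  b <- gen_lfp_pair(cfg, duration = 5, seed = 9)
  expect_identical(a$vhpc$voltage, b$vhpc$voltage)
  expect_identical(a$mpfc$voltage, b$mpfc$voltage)
  c <- gen_lfp_pair(cfg, duration = 5, seed = 10)
  expect_false(identical(a$mpfc$voltage, c$mpfc$voltage))
  # serialized round trip is byte-identical too
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_lfp(a$mpfc, file.path(d1, "m"))
  write_lfp(b$mpfc, file.path(d2, "m"))
  expect_identical(
    readBin(file.path(d1, "m.f32"), "raw", 1e7),
    readBin(file.path(d2, "m.f32"), "raw", 1e7)
  )
})

test_that("zero modulation depth gives a flat gamma envelope", {
  pr <- mod_pair(0, duration = 20, seed = 2)
  fg <- bandpass_zero_phase(pr$mpfc, c(30, 70))
  env2 <- Mod(thetagamma:::analytic_signal(as.numeric(fg)))^2
  ne <- attr(fg, "n_edge")
  mid <- (ne + 1):(length(env2) - ne)
  prof <- phase_binned_amplitude(pr$truth$theta_phase[mid], env2[mid])
  # coefficient of variation of bin means is small: no phase preference
  expect_lt(sd(prof$mean_power) / mean(prof$mean_power), 0.05)
})

test_that("full modulation at phase 0 peaks exactly at theta peak samples", {
  cfg <- synth_config(
    mod_depth_slow = 1, preferred_phase_slow = 0,
    noise_amp = 0
  )
  pr <- gen_lfp_pair(cfg, duration = 10, seed = 3)
  th <- pr$truth$theta_phase
  env <- sqrt(pmax(0, 1 + cos(th))) # generative envelope shape
  expect_equal(which.max(env), which.min(abs(th)))
})

test_that("vHPC spectral peak sits at f_theta when noiseless", {
  cfg <- synth_config(noise_amp = 0, f_theta = 8)
  pr <- gen_lfp_pair(cfg, duration = 10, seed = 4)
  w <- morlet_power(pr$vhpc, freqs = seq(2, 100, by = 1))
  prof <- colMeans(w$power[5000:15000, ])
  expect_lt(abs(w$freqs[which.max(prof)] - 8), 1 + 1e-9)
})

test_that("unlocked units produce uniform spike phases at the nominal alpha", {
  cfg <- synth_config(spike_baseline_rate = 10)
  ph <- structure(wrap_pi(2 * pi * 50 * seq(0, 20, by = 1 / 2000)),
    class = "phase_series", rate = 2000
  )
  set.seed(31)
  rej <- mean(replicate(400, {
    sp <- gen_spike_trains(cfg, ph,
      n_units = 1, seed = sample.int(1e6, 1),
      frac_locked = 0
    )
    phase_locking(sp$units$times[[1]], ph)$rayleigh_p < 0.05
  }))
  expect_gt(rej, 0.05 - 0.035)
  expect_lt(rej, 0.05 + 0.035)
})

test_that("locked units recover psi and kappa from spike phases", {
  ph <- structure(wrap_pi(2 * pi * 50 * seq(0, 100, by = 1 / 2000)),
    class = "phase_series", rate = 2000
  )
  for (k in c(1, 2, 4)) {
    cfg <- synth_config(spike_baseline_rate = 100, spike_kappa = k)
    sp <- gen_spike_trains(cfg, ph, n_units = 1, seed = 7, frac_locked = 1, psi = 0)
    pl <- phase_locking(sp$units$times[[1]], ph)
    expect_gt(pl$n_spikes, 5000)
    expect_lt(abs(pl$preferred_phase), 5 * pi / 180)
    expect_lt(abs(kappa_from_mrl(pl$mrl) - k) / k, 0.2)
  }
})

test_that("spike counts follow the Poisson mean", {
  cfg <- synth_config(spike_baseline_rate = 10)
  ph <- structure(wrap_pi(2 * pi * 50 * seq(0, 100, by = 1 / 2000)),
    class = "phase_series", rate = 2000
  )
  sp <- gen_spike_trains(cfg, ph, n_units = 3, seed = 8, frac_locked = 1)
  for (tr in sp$units$times) {
    expect_gt(length(tr), 1000 - 4 * sqrt(1000))
    expect_lt(length(tr), 1000 + 4 * sqrt(1000))
  }
})

test_that("session bookkeeping: epochs, labels, ground-truth depths", {
  cfg <- synth_config(n_trials = 20, phase_effect = 0)
  ses <- gen_session(cfg, seed = 5, n_units = 0)
  expect_equal(nrow(ses$trials), 40)
  expect_setequal(unique(ses$trials$phase), c("sample", "choice"))
  # phase_effect = 0: all epochs share the configured depth
  expect_true(all(ses$truth$epochs$mod_depth_slow == cfg$mod_depth_slow))
  # epochs tile the session
  expect_equal(ses$trials$t_start_s[-1], ses$trials$t_end_s[-40])
  expect_equal(nrow(ses$vhpc), 40 * cfg$duration_per_epoch * cfg$sample_rate)

  cfg2 <- synth_config(n_trials = 10, phase_effect = 0.2)
  ses2 <- gen_session(cfg2, seed = 6, n_units = 0)
  gt <- ses2$truth$epochs
  expect_true(all(gt$mod_depth_slow[gt$phase == "choice" & gt$correct] ==
    cfg2$mod_depth_slow + 0.2))
  expect_true(all(gt$mod_depth_slow[gt$phase == "sample"] == cfg2$mod_depth_slow))
})

test_that("session round-trips through the on-disk container", {
  cfg <- synth_config(n_trials = 3, duration_per_epoch = 1)
  ses <- gen_session(cfg, seed = 12, n_units = 4)
  d <- withr::local_tempdir()
  write_session(ses, d)
  back <- read_session(d)
  expect_equal(back$trials, ses$trials, ignore_attr = TRUE)
  expect_equal(nrow(back$spikes), 4)
  expect_equal(back$spikes$times[[1]], ses$spikes$times[[1]], tolerance = 1e-6)
  expect_equal(back$mpfc$voltage, ses$mpfc$voltage, tolerance = 1e-5)
  expect_error(read_session(file.path(d, "nope")), "missing session file")
})
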