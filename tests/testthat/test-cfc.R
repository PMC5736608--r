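test_that("phase-binned power: constants, point masses, dense cosine", {
  set.seed(41)
  ph <- runif(50000, -pi, pi)
  out <- phase_binned_amplitude(ph, rep(3.5, length(ph)))
  expect_equal(nrow(out), 100)
  expect_true(all(abs(out$mean_power - 3.5) < 1e-12))

  pw <- as.numeric(abs(ph) < 3.6 * pi / 180)
  out2 <- phase_binned_amplitude(ph, pw)
  center_bins <- which(abs(out2$phase_center) < 3.6 * pi / 180)
  expect_gt(sum(out2$mean_power[center_bins] * out2$n[center_bins]),
    0.999 * sum(pw))

  pw3 <- 1 + 0.5 * cos(ph)
  out3 <- phase_binned_amplitude(ph, pw3)
  expect_lt(max(abs(out3$mean_power - (1 + 0.5 * cos(out3$phase_center)))), 0.01)

  expect_error(phase_binned_amplitude(ph, pw[-1]), "same length")
  expect_error(phase_binned_amplitude(NaN, NaN), "no valid")
})

test_that("weighted MRL: symmetry, point mass, raised-cosine closed form", {
  expect_lt(weighted_mrl(rep(1, 100))$mrl, 1e-12)
  w1 <- rep(0, 100)
  w1[37] <- 2
  r1 <- weighted_mrl(w1)
  expect_equal(r1$mrl, 1)
  expect_equal(r1$mean_direction, pac_bin_centers()[37])
  for (phi0 in c(0, pi / 3, -2)) {
    r <- weighted_mrl(1 + 0.5 * cos(pac_bin_centers() - phi0))
    expect_equal(r$mrl, 0.25, tolerance = 1e-3)
    expect_lt(abs(wrap_pi(r$mean_direction - phi0)), 1e-6)
  }
  expect_error(weighted_mrl(rep(0, 100)), "zero")
  expect_error(weighted_mrl(c(-1, rep(1, 99))), "non-negative")
})

test_that("weighted MRL equals brute-force complex summation on random weights", {
  set.seed(42)
  centers <- pac_bin_centers()
  for (i in 1:200) {
    w <- runif(100)^2
    got <- weighted_mrl(w)
    z <- sum(w * cos(centers)) + 1i * sum(w * sin(centers))
    expect_equal(got$mrl, Mod(z) / sum(w), tolerance = 1e-12)
    expect_equal(got$mean_direction, Arg(z), tolerance = 1e-12)
  }
})

test_that("pac enforces the minimum-duration contract and epoch concatenation", {
  pr <- mod_pair(0.8, duration = 30, seed = 43, noise = 0.2)
  expect_error(
    pac(pr$vhpc, pr$mpfc, epochs = tibble::tibble(t_start_s = 5, t_end_s = 8)),
    "at least 10"
  )
  ep <- tibble::tibble(t_start_s = c(4, 16), t_end_s = c(12, 24))
  p <- pac(pr$vhpc, pr$mpfc, epochs = ep, freq_step = 2)
  expect_equal(p$n_samples, 16 * 2000)
  expect_true(p$mrl >= 0 && p$mrl <= 1)
})

test_that("pac recovers the preferred phase and is monotone in depth", {
  # wavelet path: direction recovery at 45 degrees
  for (seed in 0:2) {
    pr <- mod_pair(0.8, phi0 = pi / 4, duration = 30, seed = seed)
    p <- pac(pr$vhpc, pr$mpfc, freq_step = 2)
    expect_lt(abs(wrap_pi(p$mean_direction - pi / 4)), 10 * pi / 180)
  }
  # strictly increasing MRL across modulation depths, several seeds
  for (seed in 0:2) {
    mrls <- vapply(c(0.2, 0.4, 0.8), function(m) {
      pr <- mod_pair(m, duration = 30, seed = seed, noise = 0.2)
      pac(pr$vhpc, pr$mpfc, freq_step = 2)$mrl
    }, numeric(1))
    expect_true(all(diff(mrls) > 0))
  }
})

test_that("time-shift surrogates separate modulated from unmodulated signals", {
  pr <- mod_pair(0.8, duration = 30, seed = 44, noise = 0.2)
  pp <- thetagamma:::pac_phase_power(pr$vhpc, pr$mpfc, c(4, 12), c(30, 70),
    freq_step = 2
  )
  obs <- thetagamma:::pac_from_phase_power(pp$phase, pp$power, pp$valid)$mrl
  set.seed(45)
  surr <- pac_surrogates(pp$phase[pp$valid], pp$power[pp$valid], 2000,
    n_surrogates = 200
  )
  expect_gt(obs, quantile(surr, 0.95))

  pr0 <- mod_pair(0, duration = 30, seed = 46, noise = 0.2)
  pp0 <- thetagamma:::pac_phase_power(pr0$vhpc, pr0$mpfc, c(4, 12), c(30, 70),
    freq_step = 2
  )
  obs0 <- thetagamma:::pac_from_phase_power(pp0$phase, pp0$power, pp0$valid)$mrl
  set.seed(47)
  surr0 <- pac_surrogates(pp0$phase[pp0$valid], pp0$power[pp0$valid], 2000,
    n_surrogates = 200
  )
  expect_lt(obs0, quantile(surr0, 0.95))
})

test_that("n:m coupling: identity, exact 5:1 locking, independence floor", {
  set.seed(48)
  th <- wrap_pi(2 * pi * 8 * seq(0, 60, by = 1 / 2000))
  ga <- wrap_pi(5 * th + 0.3)
  pp <- phase_phase_mrl(th, ga, n_grid = 1:6, m_grid = 1:2)
  expect_equal(pp$mrl["5", "1"], 1.0, tolerance = 1e-9)
  expect_lt(pp$mrl["4", "1"], 0.05)
  expect_equal(phase_phase_mrl(th, th, n_grid = 1, m_grid = 1)$mrl[1, 1], 1.0)
  expect_error(phase_phase_mrl(numeric(0), numeric(0)), "non-empty")

  # independent uniform phases: E[MRL] ~ sqrt(pi)/(2 sqrt(N))
  N <- 2000
  vals <- replicate(400, {
    phase_phase_mrl(runif(N, -pi, pi), runif(N, -pi, pi),
      n_grid = 1, m_grid = 1
    )$mrl[1, 1]
  })
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(N)), tolerance = 0.1)
})

test_that("comodulogram entries are bounded and ordered by modulation", {
  pr <- mod_pair(0.8, duration = 45, seed = 49, noise = 0.2)
  pr0 <- mod_pair(0, duration = 45, seed = 49, noise = 0.2)
  pcs <- seq(6, 10, by = 0.5)
  afs <- seq(30, 70, by = 5)
  cm <- comodulogram(pr$vhpc, pr$mpfc, phase_centers = pcs, amp_freqs = afs)
  cm0 <- comodulogram(pr0$vhpc, pr0$mpfc, phase_centers = pcs, amp_freqs = afs)
  expect_true(all(cm$mrl >= 0 & cm$mrl <= 1))
  expect_gt(max(cm$mrl), max(cm0$mrl))
  expect_equal(dim(cm$mrl), c(length(pcs), length(afs)))
})

test_that("tidiers return well-formed tibbles", {
  pr <- mod_pair(0.8, duration = 15, seed = 50, noise = 0.2)
  ep <- tibble::tibble(t_start_s = 2, t_end_s = 14)
  p <- pac(pr$vhpc, pr$mpfc, epochs = ep, freq_step = 5)
  expect_equal(nrow(tidy(p)), 100)
  g <- glance(p)
  expect_equal(g$phase_region, "vHPC")
  expect_equal(g$amp_region, "mPFC")
  expect_s3_class(autoplot(p), "ggplot")
})
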