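# Shared fixtures, built in code at test time.

# A bare cosine LFP at frequency f (Hz).
cosine_lfp <- function(f, duration = 20, rate = 2000, region = "vHPC",
                       amp = 1, phase0 = 0) {
  t <- seq(0, duration, by = 1 / rate)
  lfp_recording(amp * cos(2 * pi * f * t + phase0), rate = rate, region = region)
}

# Quick noiseless theta-modulated pair with given slow-gamma depth/phase.
mod_pair <- function(m, phi0 = 0, duration = 30, seed = 1, noise = 0) {
  cfg <- synth_config(
    mod_depth_slow = m, preferred_phase_slow = phi0,
    noise_amp = noise
  )
  gen_lfp_pair(cfg, duration = duration, seed = seed)
}

# Brute-force O(N^2) pair count within +/- window (CCG oracle).
brute_c12 <- function(t1, t2, window = 0.001) {
  sum(abs(outer(t1, t2, "-")) <= window)
}

# Brute-force check that all peak times are >= min_sep apart.
brute_separation_ok <- function(times, min_sep = 0.1) {
  if (length(times) < 2) {
    return(TRUE)
  }
  d <- abs(outer(times, times, "-"))
  all(d[upper.tri(d)] >= min_sep)
}
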