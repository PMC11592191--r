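# Shared fixtures: small, deterministic objects built in code.

# Noise-free copy of the default generator parameters.
quiet_params <- function(...) {
  p <- channel_params(...)
  p$noise_sd_current <- 0
  p$noise_sd_voltage <- 0
  p
}

# A purely passive RC membrane: tau = 8 ms, R = 200 MOhm, C = 40 pF.
rc_params <- function(g_leak = 5, c_m = 40, e_leak = -65) {
  channel_params(g_leak = g_leak, e_leak = e_leak, c_m = c_m,
                 lva = list(g_max = 0), hva = list(g_max = 0),
                 spike = list(g_na = 0),
                 noise_sd_current = 0, noise_sd_voltage = 0)
}

# Synthetic AP-shaped voltage trace: resting baseline with one (or more)
# Gaussian depolarizations of known peak time/height.
synthetic_ap_trace <- function(peaks_ms, amp = 80, width = 0.5, rest = -65,
                               total = 60, dt = 0.02, onset = 20) {
  t <- seq(0, total, by = dt)
  v <- rep(rest, length(t))
  for (pk in peaks_ms) v <- v + amp * exp(-((t - pk)^2) / (2 * width^2))
  tr <- tibble::tibble(time_ms = t, voltage_mV = v)
  attr(tr, "onset") <- onset
  attr(tr, "sampling_interval") <- dt
  tr
}

# Current-clamp family built from flat / spiking synthetic traces with a
# prescribed number of spiking repetitions per amplitude.
counts_family <- function(spiking_per_level, reps = 10) {
  amps <- as.numeric(names(spiking_per_level))
  t <- seq(0, 60, by = 0.05)
  flat <- rep(-65, length(t))
  spike <- -65 + 80 * exp(-((t - 26)^2) / (2 * 0.5^2))
  cols <- list()
  info <- list()
  for (a in seq_along(amps)) {
    n_spk <- spiking_per_level[[a]]
    for (r in seq_len(reps)) {
      cols[[length(cols) + 1L]] <- if (r <= n_spk) spike else flat
      info[[length(info) + 1L]] <- tibble::tibble(amplitude_pA = amps[a],
                                                  rep = r)
    }
  }
  fam <- sweep_family(t, do.call(cbind, cols), dplyr::bind_rows(info),
                      kind = "voltage")
  attr(fam, "onset") <- 20
  fam
}

# Random Boltzmann parameter draws used by the closed-form/quadrature
# property checks.
random_boltzmann_params <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      b = runif(n, 0, 0.5),
      v50 = runif(n, -80, 10),
      k = runif(n, 1, 20),
      g_max = runif(n, 1, 100),
      c_int = runif(n, -500, 500)
    )
  })
}
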