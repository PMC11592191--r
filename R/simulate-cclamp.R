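flatten_params <- function(p) {
  c(g_leak = p$g_leak, e_leak = p$e_leak, e_k = p$e_k, c_m = p$c_m,
    lva_g = p$lva$g_max, lva_v50 = p$lva$v50, lva_k = p$lva$k,
    lva_b = p$lva$b, lva_tau = p$lva$tau,
    hva_g = p$hva$g_max, hva_v50 = p$hva$v50, hva_k = p$hva$k,
    hva_b = p$hva$b, hva_tau = p$hva$tau,
    g_na = p$spike$g_na, e_na = p$spike$e_na,
    act_v50 = p$spike$act_v50, act_k = p$spike$act_k,
    inact_v50 = p$spike$inact_v50, inact_k = p$spike$inact_k,
    tau_m = p$spike$tau_m, tau_h = p$spike$tau_h)
}

#' Simulate a current-clamp voltage trace
#'
#' Integrates the single-compartment model
#' \eqn{C_m\,dV/dt = -I_{ion}(V) + I_{inj}(t)} with a fixed step (default
#' 0.01 ms) from the model's resting state.  A square current pulse of
#' `amplitude` pA is applied from `onset` for `duration` ms.  Subthreshold
#' negative steps give mono-exponential charging; suprathreshold steps
#' produce one or more action potentials via the sodium mechanism.  Gaussian
#' recording noise of SD `params$noise_sd_voltage` is added to the recorded
#' samples only (it does not enter the dynamics), so the same seed yields a
#' bit-identical trace.
#'
#' @param params A [channel_params()] object.
#' @param stim List with `amplitude` (pA), `onset` (ms, default 20) and
#'   `duration` (ms, default 100).
#' @param seed Integer seed for the recording noise (optional).
#' @param dt Integration step, ms; must be <= 0.01 unless explicitly relaxed.
#' @param record_dt Sampling interval of the returned trace, ms (a multiple
#'   of `dt`).
#' @param post Recording time after stimulus offset, ms.
#' @param noise_sd Override for voltage recording noise SD, mV.
#' @param v0 Initial voltage; defaults to the model's resting potential.
#' @return A tibble with columns `time_ms`, `voltage_mV`, plus attributes
#'   `onset`, `duration`, `amplitude`, `sampling_interval`.
#' @export
simulate_cclamp_trace <- function(params,
                                  stim = list(amplitude = -10, onset = 20,
                                              duration = 100),
                                  seed = NULL, dt = 0.01, record_dt = 0.02,
                                  post = 20, noise_sd = NULL, v0 = NULL) {
  stopifnot(inherits(params, "channel_params"))
  stim <- utils::modifyList(list(onset = 20, duration = 100), as.list(stim))
  if (is.null(stim$amplitude)) abort("`stim$amplitude` is required.")
  if (stim$duration <= 0) abort("`stim$duration` must be > 0.")
  record_every <- as.integer(round(record_dt / dt))
  if (abs(record_every * dt - record_dt) > 1e-9) {
    abort("`record_dt` must be an integer multiple of `dt`.")
  }
  if (is.null(noise_sd)) noise_sd <- params$noise_sd_voltage
  if (is.null(v0)) v0 <- resting_potential(params)
  total <- stim$onset + stim$duration + post

  v <- cclamp_integrate_cpp(flatten_params(params), v0 = v0,
                            i_amp = stim$amplitude, onset = stim$onset,
                            dur = stim$duration, total = total, dt = dt,
                            record_every = record_every)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  out <- tibble(time_ms = seq(0, by = record_dt, length.out = length(v)),
                voltage_mV = v)
  attr(out, "onset") <- stim$onset
  attr(out, "duration") <- stim$duration
  attr(out, "amplitude") <- stim$amplitude
  attr(out, "sampling_interval") <- record_dt
  out
}

#' Simulate a current-clamp sweep family
#'
#' Repetitions of square current injections at one or more amplitudes,
#' returned as a [sweep_family()] (`kind = "voltage"`) whose `info` tibble has
#' columns `amplitude_pA` and `rep`.  Noise seeds are derived
#' deterministically per (amplitude, repetition) from `seed`, so simulating a
#' subset of amplitudes reproduces exactly the sweeps the full protocol would
#' contain.
#'
#' @inheritParams simulate_cclamp_trace
#' @param amplitudes Injected current amplitudes, pA.
#' @param reps Repetitions per amplitude (default 10).
#' @param onset,duration Stimulus timing, ms.
#' @return A [sweep_family()].
#' @export
simulate_cclamp_family <- function(params, amplitudes, reps = 10,
                                   onset = 20, duration = 100,
                                   seed = NULL, dt = 0.01, record_dt = 0.02,
                                   post = 20, noise_sd = NULL) {
  if (length(amplitudes) < 1L) abort("`amplitudes` must be non-empty.")
  if (is.null(noise_sd)) noise_sd <- params$noise_sd_voltage
  v0 <- resting_potential(params)
  info <- tidyr::expand_grid(amplitude_pA = amplitudes, rep = seq_len(reps))
  cols <- vector("list", nrow(info))
  for (idx in seq_len(nrow(info))) {
    sub_seed <- if (is.null(seed)) NULL else
      abs(seed + 7919L * as.integer(round(2 * info$amplitude_pA[idx])) +
            104729L * info$rep[idx]) %% .Machine$integer.max
    tr <- simulate_cclamp_trace(
      params,
      stim = list(amplitude = info$amplitude_pA[idx], onset = onset,
                  duration = duration),
      seed = sub_seed, dt = dt, record_dt = record_dt, post = post,
      noise_sd = noise_sd, v0 = v0)
    cols[[idx]] <- tr$voltage_mV
  }
  time_ms <- seq(0, by = record_dt,
                 length.out = length(cols[[1]]))
  fam <- sweep_family(time_ms, do.call(cbind, cols), info, kind = "voltage")
  attr(fam, "onset") <- onset
  attr(fam, "duration") <- duration
  fam
}
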