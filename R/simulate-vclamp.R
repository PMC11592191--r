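#' Voltage-clamp step protocol
#'
#' The standard protocol steps the command potential from -100 to +20 mV in
#' 5-mV increments for 150 ms.  Command levels are nominal (amplifier)
#' values; the liquid junction potential `ljp` (default -10 mV) is the offset
#' between the true membrane potential and the nominal command, applied once
#' during analysis by [correct_junction_potential()].
#'
#' @param levels Nominal command levels, mV, sorted ascending with a uniform
#'   increment.
#' @param holding Nominal holding potential before the step, mV.
#' @param duration Step duration, ms.
#' @param ljp Liquid junction potential, mV.
#' @param sampling_interval Sampling interval of simulated traces, ms.
#' @return A `vclamp_protocol` object.
#' @export
vclamp_protocol <- function(levels = seq(-100, 20, by = 5),
                            holding = -70,
                            duration = 150,
                            ljp = -10,
                            sampling_interval = 0.1) {
  if (length(levels) < 1L) abort("`levels` must be non-empty.")
  if (is.unsorted(levels, strictly = TRUE)) {
    abort("`levels` must be sorted strictly ascending.")
  }
  if (length(levels) > 1L) {
    incr <- diff(levels)
    if (diff(range(incr)) > 1e-9) abort("`levels` must be uniformly spaced.")
  }
  if (duration <= 10) abort("`duration` must exceed 10 ms.")
  if (!is.finite(ljp)) abort("`ljp` must be finite.")
  structure(
    list(levels = levels, holding = holding, duration = duration,
         increment = if (length(levels) > 1L) diff(levels)[1] else NA_real_,
         ljp = ljp, ljp_corrected = FALSE,
         sampling_interval = sampling_interval),
    class = "vclamp_protocol"
  )
}

#' @export
print.vclamp_protocol <- function(x, ...) {
  cat(sprintf("<vclamp_protocol> %d levels %g..%g mV (step %g), %g ms, hold %g mV, LJP %g mV%s\n",
              length(x$levels), min(x$levels), max(x$levels), x$increment,
              x$duration, x$holding, x$ljp,
              if (x$ljp_corrected) " [corrected]" else ""))
  invisible(x)
}

#' Simulate a voltage-clamp sweep family
#'
#' Produces one current trace per command level from the conductance model in
#' [channel_params()].  The membrane potential is clamped, so each potassium
#' conductance relaxes first-order from its holding-level activation to its
#' steady state at the step level with its activation time constant
#' (`lva$tau`, `hva$tau`); the recorded current is the instantaneous ionic
#' current plus i.i.d. Gaussian recording noise of SD
#' `params$noise_sd_current`.  The simulation operates at the true membrane
#' voltage, i.e. nominal command plus the protocol's junction potential, so
#' that junction-corrected analysis recovers the generator's voltage axis.
#' Capacitive transients and series-resistance error are not modeled.
#'
#' Because activation time constants are a few ms and the steady-state window
#' sits more than 25 time constants into a 150-ms step, late-window currents
#' equal the analytic steady state to floating-point precision in the
#' noise-free case.
#'
#' @param params A [channel_params()] object.
#' @param protocol A [vclamp_protocol()].
#' @param seed Integer seed; the same seed yields a bit-identical family.
#' @param noise_sd Override for the recording-noise SD, pA (default: value in
#'   `params`).
#' @return A [sweep_family()] of `kind = "current"` with `info` column
#'   `command_mV` (nominal levels).
#' @export
simulate_vclamp_family <- function(params, protocol = vclamp_protocol(),
                                   seed = NULL, noise_sd = NULL) {
  stopifnot(inherits(params, "channel_params"),
            inherits(protocol, "vclamp_protocol"))
  if (is.null(noise_sd)) noise_sd <- params$noise_sd_current
  time_ms <- seq(0, protocol$duration, by = protocol$sampling_interval)
  v_true <- protocol$levels + protocol$ljp
  v_hold <- protocol$holding + protocol$ljp
  hold_gates <- gate_inf(params, v_hold)

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  sweeps <- vapply(seq_along(v_true), function(j) {
    v <- v_true[j]
    g <- gate_inf(params, v)
    a_l <- g$a_lva + (hold_gates$a_lva - g$a_lva) * exp(-time_ms / params$lva$tau)
    a_h <- g$a_hva + (hold_gates$a_hva - g$a_hva) * exp(-time_ms / params$hva$tau)
    i <- params$g_leak * (v - params$e_leak) +
      params$lva$g_max * a_l * (v - params$e_k) +
      params$hva$g_max * a_h * (v - params$e_k)
    if (noise_sd > 0) i <- i + rnorm(length(i), sd = noise_sd)
    i
  }, numeric(length(time_ms)))

  sweep_family(time_ms, sweeps,
               info = tibble(command_mV = protocol$levels),
               kind = "current", protocol = protocol)
}
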