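#' Spike-detection settings
#'
#' The recordings' source papers rarely state their detectors, so detection
#' is explicit and configurable: an action potential is an upward crossing of
#' `dvdt_min` by dV/dt whose subsequent local maximum exceeds `peak_min`.
#'
#' @param dvdt_min Minimum upward dV/dt, mV/ms.
#' @param peak_min Minimum peak voltage, mV.
#' @param smooth_ms Width (ms) of the running-mean smoothing applied to the
#'   derivative before rate measurements; plays the role of the recording
#'   chain's low-pass filter and keeps the max-|dV/dt| statistics from being
#'   dominated by sample noise at high digitization rates.  Set 0 to disable.
#' @return A named list.
#' @export
detection_settings <- function(dvdt_min = 10, peak_min = -20,
                               smooth_ms = 0.2) {
  list(dvdt_min = dvdt_min, peak_min = peak_min, smooth_ms = smooth_ms)
}

# Central-difference dV/dt on the native grid (one-sided at the ends),
# optionally smoothed with a centered running mean of width smooth_ms.
dvdt <- function(v, dt, smooth_ms = 0) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  k <- if (smooth_ms > 0) max(1L, as.integer(round(smooth_ms / dt))) else 1L
  if (k > 1L) {
    kernel <- rep(1 / k, k)
    sm <- stats::filter(d, kernel, sides = 2)
    d <- ifelse(is.na(sm), d, as.numeric(sm))
  }
  d
}

#' Detect action potentials in a voltage trace
#'
#' Deterministic event detection: candidate events start where dV/dt crosses
#' `dvdt_min` upward; each event's peak is the voltage maximum before dV/dt
#' next returns below zero for good; events whose peak does not exceed
#' `peak_min` are discarded, and overlapping windows are merged so events are
#' non-overlapping and time-ordered.  The event window extends from the
#' upward crossing to the post-peak minimum (trough) preceding the next
#' event (or trace end).
#'
#' @param trace A voltage trace: tibble with `time_ms` and `voltage_mV`.
#' @param detection [detection_settings()].
#' @return A tibble with one row per action potential: `peak_time_ms`,
#'   `peak_mV`, `start_ms`, `end_ms` (empty when no APs).
#' @export
detect_aps <- function(trace, detection = detection_settings()) {
  t <- trace$time_ms
  v <- trace$voltage_mV
  n <- length(v)
  empty <- tibble(peak_time_ms = numeric(), peak_mV = numeric(),
                  start_ms = numeric(), end_ms = numeric())
  if (n < 3L) return(empty)
  dt <- t[2] - t[1]
  dv <- dvdt(v, dt, detection$smooth_ms %||% 0)
  up <- which(dv[-1] >= detection$dvdt_min & dv[-n] < detection$dvdt_min) + 1L
  if (length(up) == 0L) return(empty)

  events <- list()
  last_end <- 0L
  for (s in up) {
    if (s <= last_end) next
    # peak: maximum V between crossing and the point where dV/dt has gone
    # negative and V has dropped 5 mV below the running max (end of upstroke).
    j <- s
    vmax <- v[s]; jmax <- s
    while (j < n) {
      j <- j + 1L
      if (v[j] > vmax) { vmax <- v[j]; jmax <- j }
      if (dv[j] < 0 && v[j] < vmax - 5) break
    }
    if (vmax < detection$peak_min) { last_end <- j; next }
    # window end: trough after the peak (first local minimum / dv upturn)
    e <- jmax
    while (e < n - 1L && !(dv[e] < 0 && dv[e + 1L] >= 0)) e <- e + 1L
    events[[length(events) + 1L]] <- c(start = s, peak = jmax, end = e)
    last_end <- e
  }
  if (length(events) == 0L) return(empty)
  ev <- do.call(rbind, events)
  tibble(peak_time_ms = t[ev[, "peak"]], peak_mV = v[ev[, "peak"]],
         start_ms = t[ev[, "start"]], end_ms = t[ev[, "end"]])
}

#' Action-potential features of a single trace
#'
#' Features of the first detected action potential, following the standard
#' definitions: latency is the time from stimulus onset to the AP *peak*;
#' rise rate is the maximum positive dV/dt and repolarization rate the
#' maximum negative dV/dt within the AP window (finite differences on the
#' native grid); peak amplitude is the absolute peak voltage.
#'
#' @param trace Voltage trace tibble (`time_ms`, `voltage_mV`).
#' @param onset Stimulus onset, ms (default: trace attribute).
#' @param detection [detection_settings()].
#' @return A one-row tibble: `latency_ms`, `rise_rate`, `repol_rate` (mV/ms,
#'   negative), `peak_mV`, `n_spikes`.
#' @export
ap_features <- function(trace, onset = attr(trace, "onset"),
                        detection = detection_settings()) {
  if (is.null(onset)) abort("`onset` must be supplied.")
  aps <- detect_aps(trace, detection)
  if (nrow(aps) == 0L) abort("No action potentials detected.")
  t <- trace$time_ms
  v <- trace$voltage_mV
  dt <- t[2] - t[1]
  dv <- dvdt(v, dt, detection$smooth_ms %||% 0)
  w <- t >= aps$start_ms[1] & t <= aps$end_ms[1]
  tibble(latency_ms = aps$peak_time_ms[1] - onset,
         rise_rate = max(dv[w]),
         repol_rate = min(dv[w]),
         peak_mV = aps$peak_mV[1],
         n_spikes = nrow(aps))
}

#' Apply the current-threshold rule to a current-clamp family
#'
#' The current threshold `I_T` is the lowest injected amplitude that evokes
#' at least one action potential on 5 or more of 10 repetitions.  When fewer
#' than 10 repetitions exist the rule generalizes to at least half of the
#' repetitions.  The suprathreshold stimulation amplitude is defined as 25%
#' above threshold, `1.25 * I_T`.
#'
#' @param family A [sweep_family()] of voltage sweeps whose `info` has
#'   `amplitude_pA` and `rep` columns (ascending amplitudes).
#' @param detection [detection_settings()].
#' @return A list of class `threshold_result`: `i_t` (pA or NA), `found`,
#'   `suprathreshold_pA` (`1.25 * i_t`), and `spike_counts` (tibble:
#'   `amplitude_pA`, `n_reps`, `n_spiking`).
#' @export
find_current_threshold <- function(family, detection = detection_settings()) {
  stopifnot(inherits(family, "sweep_family"))
  if (family$kind != "voltage") abort("`family` must contain voltage sweeps.")
  info <- family$info
  spiking <- vapply(seq_len(ncol(family$sweeps)), function(j) {
    nrow(detect_aps(family_trace(family, j), detection)) >= 1L
  }, logical(1))
  counts <- tibble(amplitude_pA = info$amplitude_pA, spiking = spiking) |>
    dplyr::group_by(.data$amplitude_pA) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     n_spiking = sum(.data$spiking), .groups = "drop") |>
    dplyr::arrange(.data$amplitude_pA)
  hit <- counts$n_spiking >= pmax(counts$n_reps / 2, 1)
  i_t <- if (any(hit)) counts$amplitude_pA[which(hit)[1]] else NA_real_
  structure(list(i_t = i_t, found = !is.na(i_t),
                 suprathreshold_pA = 1.25 * i_t,
                 spike_counts = counts),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<threshold_result> I_T = %g pA (suprathreshold %g pA)\n",
                x$i_t, x$suprathreshold_pA))
  } else {
    cat("<threshold_result> no amplitude satisfied the >=5-of-10 rule\n")
  }
  invisible(x)
}

#' Average action-potential features over suprathreshold repetitions
#'
#' Per-repetition features ([ap_features()]) are averaged arithmetically over
#' the repetitions that contain at least one action potential; the number of
#' contributing repetitions is reported.
#'
#' @param family A [sweep_family()] of repetitions at the suprathreshold
#'   amplitude.
#' @param onset Stimulus onset, ms (default: family attribute).
#' @param detection [detection_settings()].
#' @return A one-row tibble: mean `latency_ms`, `rise_rate`, `repol_rate`,
#'   `peak_mV`, plus `n_contributing` and `n_reps`.
#' @export
mean_suprathreshold_features <- function(family,
                                         onset = attr(family, "onset"),
                                         detection = detection_settings()) {
  stopifnot(inherits(family, "sweep_family"))
  if (is.null(onset)) abort("`onset` must be supplied.")
  feats <- purrr::map(seq_len(ncol(family$sweeps)), function(j) {
    tr <- family_trace(family, j)
    tryCatch(ap_features(tr, onset = onset, detection = detection),
             error = function(e) NULL)
  })
  feats <- purrr::compact(feats)
  if (length(feats) == 0L) {
    abort("No repetition contained a detectable action potential.")
  }
  all <- dplyr::bind_rows(feats)
  out <- dplyr::summarise(all, dplyr::across(dplyr::everything(), mean))
  out$n_contributing <- length(feats)
  out$n_reps <- ncol(family$sweeps)
  out
}

#' Passive membrane properties from a -10 pA step response
#'
#' The membrane time constant `tau` is obtained by least-squares fit of a
#' single exponential \eqn{V(t) = V_{ss} + \Delta V e^{-(t - t_0)/\tau}} to
#' the first 10 ms of the voltage response for early-embryonic (E13) cells,
#' or the first 5 ms for E20-21 cells; the first 0.1 ms after onset is
#' blanked to avoid the stimulus edge.  Input resistance `R_in` is the
#' voltage change (averaged over the last 5 ms of the injection, relative to
#' the 20-ms pre-onset baseline) divided by the injected current, and the
#' capacitance follows from the RC identity `C = tau / R_in` (held exactly
#' by construction).  The pre-onset baseline mean is reported as the resting
#' membrane potential.
#'
#' @param trace Voltage trace tibble (`time_ms`, `voltage_mV`) of the
#'   response to a negative current step.
#' @param onset,duration Stimulus timing, ms (defaults: trace attributes;
#'   duration 100 ms).
#' @param amplitude Injected current, pA (default: trace attribute or -10).
#' @param age `"E13"` (10-ms fit window) or `"E20_21"` (5-ms window).
#' @param blank Post-onset blanking, ms.
#' @return A one-row tibble: `tau_ms`, `r_in_MOhm`, `c_m_pF`, `rmp_mV`,
#'   `fit_window_ms`.
#' @export
passive_properties <- function(trace, onset = attr(trace, "onset"),
                               duration = attr(trace, "duration") %||% 100,
                               amplitude = attr(trace, "amplitude") %||% -10,
                               age = c("E13", "E20_21"), blank = 0.1) {
  age <- match.arg(age)
  if (is.null(onset)) abort("`onset` must be supplied.")
  if (amplitude >= 0) abort("Passive properties require a negative current step.")
  t <- trace$time_ms
  v <- trace$voltage_mV
  if (onset + duration > max(t) + 1e-9) abort("Stimulus window lies outside the trace.")

  base_sel <- t >= onset - 20 & t < onset
  if (!any(base_sel)) abort("No pre-onset baseline samples.")
  rmp <- mean(v[base_sel])

  ss_sel <- t >= onset + duration - 5 & t < onset + duration
  delta_v <- mean(v[ss_sel]) - rmp
  if (delta_v > 0) {
    abort("Positive-going response to a negative current step (polarity violation).")
  }
  r_in <- delta_v / amplitude * 1000  # mV/pA = GOhm -> MOhm

  fit_win <- if (age == "E13") 10 else 5
  fsel <- t > onset + blank & t <= onset + fit_win
  d <- tibble(ts = t[fsel] - onset, y = v[fsel])
  # the charging plateau is measured directly from the late window, so the
  # exponential fit only estimates the amplitude and the time constant
  d$vss <- rmp + delta_v
  start <- list(dv = d$y[1] - d$vss[1], tau = fit_win / 2)
  res <- nls_safe(y ~ vss + dv * exp(-ts / tau), d, start = start,
                  lower = c(dv = -100, tau = 0.05),
                  upper = c(dv = 100, tau = 200))
  if (!res$ok || !res$converged) {
    abort("Exponential fit of the charging response failed to converge.")
  }
  tau <- unname(res$estimate["tau"])
  tibble(tau_ms = tau, r_in_MOhm = r_in,
         c_m_pF = tau / r_in * 1000,  # ms/MOhm = nF -> pF
         rmp_mV = rmp, fit_window_ms = fit_win)
}
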