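#' Ground-truth channel parameters for the conductance-model generator
#'
#' A single-compartment membrane with a passive leak, two Boltzmann-activated
#' potassium conductances (LVA, Kv1-like; HVA, Kv3-like), and a minimal
#' Hodgkin-Huxley-style sodium conductance used only to produce action
#' potentials in current clamp.  All conductances in nS, voltages in mV,
#' capacitance in pF, time constants in ms.
#'
#' The defaults describe an early-embryonic (E13) high-frequency
#' cochlear-nucleus neuron and were calibrated once so that the analysis
#' pipeline applied to noise-free simulated sweeps reproduces the magnitudes
#' typical of control recordings (input resistance near 210 MOhm, membrane
#' time constant near 8.5 ms, differential conductance near 20 nS at
#' -42.5 mV and near 70 nS at +17.5 mV, steady-state current near 460 pA at
#' a -40 mV step).  The sodium mechanism is a fixture that yields a brief
#' onset spike; it makes no scientific claim about sodium currents.
#'
#' @param g_leak Leak conductance, nS.
#' @param e_leak Leak reversal potential, mV.
#' @param e_k Potassium reversal potential, mV.
#' @param c_m Membrane capacitance, pF.
#' @param lva,hva Potassium channel descriptions: lists with `g_max` (nS),
#'   `v50` (mV), `k` (mV), `b` (baseline open fraction in `[0,1)`), and
#'   `tau` (first-order activation time constant, ms).
#' @param spike Sodium spike mechanism: `g_na` (nS), `e_na` (mV), activation
#'   `act_v50`/`act_k` and inactivation `inact_v50`/`inact_k` (mV), gating
#'   time constants `tau_m`/`tau_h` (ms).  Gating is m^3 h.
#' @param noise_sd_current Additive Gaussian recording noise on current
#'   traces, pA.
#' @param noise_sd_voltage Additive Gaussian recording noise on voltage
#'   traces, mV.
#' @return A `channel_params` object (nested list).
#' @examples
#' p <- channel_params()
#' steady_state_model_current(p, v = c(-80, -40, 0))
#' @export
channel_params <- function(g_leak = 3.81,
                           e_leak = -66,
                           e_k = -90,
                           c_m = 42,
                           lva = list(g_max = 6.37, v50 = -50, k = 4,
                                      b = 0, tau = 2),
                           hva = list(g_max = 24.0, v50 = -5, k = 10,
                                      b = 0, tau = 1),
                           spike = list(g_na = 1200, e_na = 50,
                                        act_v50 = -30, act_k = 6,
                                        inact_v50 = -40, inact_k = 6,
                                        tau_m = 0.15, tau_h = 1),
                           noise_sd_current = 20,
                           noise_sd_voltage = 0.3) {
  lva <- utils::modifyList(formals(channel_params)$lva |> eval(), as.list(lva))
  hva <- utils::modifyList(formals(channel_params)$hva |> eval(), as.list(hva))
  spike <- utils::modifyList(formals(channel_params)$spike |> eval(),
                             as.list(spike))
  p <- structure(
    list(g_leak = g_leak, e_leak = e_leak, e_k = e_k, c_m = c_m,
         lva = lva, hva = hva, spike = spike,
         noise_sd_current = noise_sd_current,
         noise_sd_voltage = noise_sd_voltage),
    class = "channel_params"
  )
  validate_channel_params(p)
}

validate_channel_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) abort(msg)
  chk(p$g_leak >= 0, "`g_leak` must be >= 0.")
  chk(p$c_m > 0, "`c_m` must be > 0.")
  for (ch in c("lva", "hva")) {
    chk(p[[ch]]$g_max >= 0, sprintf("`%s$g_max` must be >= 0.", ch))
    chk(p[[ch]]$k > 0, sprintf("`%s$k` must be > 0.", ch))
    chk(p[[ch]]$b >= 0 && p[[ch]]$b < 1, sprintf("`%s$b` must be in [0,1).", ch))
    chk(p[[ch]]$tau > 0, sprintf("`%s$tau` must be > 0.", ch))
  }
  chk(p$spike$g_na >= 0, "`spike$g_na` must be >= 0.")
  chk(p$spike$tau_m > 0 && p$spike$tau_h > 0, "spike gating taus must be > 0.")
  chk(p$noise_sd_current >= 0 && p$noise_sd_voltage >= 0,
      "noise SDs must be >= 0.")
  p
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n")
  cat(sprintf("  leak: %.3g nS @ %.4g mV;  C_m %.3g pF;  E_K %.4g mV\n",
              x$g_leak, x$e_leak, x$c_m, x$e_k))
  for (ch in c("lva", "hva")) {
    cat(sprintf("  %s : G_max %.4g nS, V50 %.4g mV, K %.3g mV, B %.3g, tau %.3g ms\n",
                toupper(ch), x[[ch]]$g_max, x[[ch]]$v50, x[[ch]]$k,
                x[[ch]]$b, x[[ch]]$tau))
  }
  cat(sprintf("  Na  : g %.4g nS, m3h, act %.4g/%.3g, inact %.4g/%.3g mV\n",
              x$spike$g_na, x$spike$act_v50, x$spike$act_k,
              x$spike$inact_v50, x$spike$inact_k))
  cat(sprintf("  noise: %.3g pA (I), %.3g mV (V)\n",
              x$noise_sd_current, x$noise_sd_voltage))
  invisible(x)
}

# Steady-state gating values used both by the analytic steady state and as
# initial conditions of the current-clamp integrator.
gate_inf <- function(p, v) {
  list(
    a_lva = p$lva$b + (1 - p$lva$b) * plogis((v - p$lva$v50) / p$lva$k),
    a_hva = p$hva$b + (1 - p$hva$b) * plogis((v - p$hva$v50) / p$hva$k),
    m = plogis((v - p$spike$act_v50) / p$spike$act_k),
    h = plogis(-(v - p$spike$inact_v50) / p$spike$inact_k)
  )
}

#' Noise-free steady-state membrane current of the generator model
#'
#' Analytic steady state of the single-compartment model:
#' \deqn{I(V) = g_{leak}(V - E_{leak}) + \sum_{c \in \{LVA, HVA\}}
#'   G_{max,c}\,P_{O,c}(V)\,(V - E_K) + g_{Na} m_\infty^3 h_\infty (V-E_{Na}),}
#' with each potassium open probability given by [boltzmann_po()].  The sodium
#' window term is negligible at potassium-measurement voltages but is included
#' so the zero of this function is exactly the model's resting potential.
#'
#' @param params A [channel_params()] object.
#' @param v Membrane voltage(s), mV.
#' @param include_na Include the sodium window current (default TRUE).
#' @return Current, pA (positive outward).
#' @export
steady_state_model_current <- function(params, v, include_na = TRUE) {
  stopifnot(inherits(params, "channel_params"), all(is.finite(v)))
  g <- gate_inf(params, v)
  i <- params$g_leak * (v - params$e_leak) +
    params$lva$g_max * g$a_lva * (v - params$e_k) +
    params$hva$g_max * g$a_hva * (v - params$e_k)
  if (include_na && params$spike$g_na > 0) {
    i <- i + params$spike$g_na * g$m^3 * g$h * (v - params$spike$e_na)
  }
  i
}

# Analytic slope dI/dV of the generator steady state (potassium + leak part).
# Used as an oracle in tests and for effective-conductance diagnostics.
model_didv <- function(params, v, include_na = FALSE) {
  dchan <- function(ch) {
    po <- ch$b + (1 - ch$b) * plogis((v - ch$v50) / ch$k)
    s <- plogis((v - ch$v50) / ch$k)
    dpo <- (1 - ch$b) * s * (1 - s) / ch$k
    ch$g_max * (po + dpo * (v - params$e_k))
  }
  out <- params$g_leak + dchan(params$lva) + dchan(params$hva)
  if (include_na && params$spike$g_na > 0) {
    sp <- params$spike
    m <- plogis((v - sp$act_v50) / sp$act_k)
    h <- plogis(-(v - sp$inact_v50) / sp$inact_k)
    dm <- m * (1 - m) / sp$act_k
    dh <- -h * (1 - h) / sp$inact_k
    out <- out + sp$g_na * (m^3 * h + (3 * m^2 * dm * h + m^3 * dh) *
                              (v - sp$e_na))
  }
  out
}

#' Resting membrane potential of the generator model
#'
#' Solves `steady_state_model_current(params, v) = 0` for the resting
#' potential by bisection on `[-95, -30]` mV.
#'
#' @inheritParams steady_state_model_current
#' @return Resting potential, mV.
#' @export
resting_potential <- function(params) {
  f <- function(v) steady_state_model_current(params, v)
  # take the most hyperpolarized zero crossing (the stable rest); a strong
  # sodium window current can create further depolarized equilibria
  grid <- seq(-95, -30, by = 0.5)
  vals <- f(grid)
  cross <- which(vals[-length(vals)] < 0 & vals[-1] >= 0)
  if (length(cross) == 0L) abort("No resting potential found in [-95, -30] mV.")
  stats::uniroot(f, lower = grid[cross[1]], upper = grid[cross[1] + 1],
                 tol = 1e-10)$root
}

# Choose e_leak so the model rests exactly at `rmp`: from I_ss(rmp) = 0,
# E_leak = rmp + I_other(rmp) / g_leak.
leak_reversal_for_rmp <- function(params, rmp) {
  i_other <- steady_state_model_current(params, rmp) -
    params$g_leak * (rmp - params$e_leak)
  rmp + i_other / params$g_leak
}
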