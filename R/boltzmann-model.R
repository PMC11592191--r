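#' Boltzmann open probability
#'
#' Steady-state open probability of a voltage-gated channel,
#' \deqn{P_O(V) = B + \frac{1 - B}{1 + e^{(V_{50} - V)/K}},}
#' a sigmoid rising from the baseline open fraction `B` (as \eqn{V \to -\infty})
#' to 1 (as \eqn{V \to +\infty}), with half-activation voltage `v50` and slope
#' factor `k` (mV).  Evaluation is overflow-safe for any finite voltage.
#'
#' @param v Membrane voltage(s), mV.
#' @param v50 Half-activation voltage, mV.
#' @param k Slope factor, mV; must be positive.
#' @param b Baseline open fraction in `[0, 1)`.  Default 0.
#' @return Numeric vector of open probabilities in `[b, 1]`.
#' @examples
#' boltzmann_po(-40, v50 = -40, k = 5)        # 0.5 at the half-activation point
#' boltzmann_po(-35, v50 = -40, k = 5)        # one slope factor above v50
#' @export
boltzmann_po <- function(v, v50, k, b = 0) {
  stopifnot(is.numeric(v), is.numeric(v50), is.numeric(k), is.numeric(b))
  if (any(k <= 0)) abort("`k` (slope factor) must be positive.")
  if (any(b < 0 | b >= 1)) abort("`b` must lie in [0, 1).")
  b + (1 - b) * plogis((v - v50) / k)
}

#' Boltzmann differential conductance
#'
#' The slope of the steady-state I-V curve implied by a Boltzmann-activated
#' conductance: \eqn{dI/dV = G_{max} \, P_O(V)} with `P_O` from
#' [boltzmann_po()].  This is the model curve fitted to empirical differential
#' conductance and evaluated at the standard read-out voltages.
#'
#' @inheritParams boltzmann_po
#' @param g_max Maximal differential conductance, nS.
#' @return Differential conductance, nS.
#' @export
boltzmann_conductance <- function(v, v50, k, g_max, b = 0) {
  if (any(g_max < 0)) abort("`g_max` must be non-negative.")
  g_max * boltzmann_po(v, v50 = v50, k = k, b = b)
}

#' Integrated Boltzmann I-V curve (closed form)
#'
#' Antiderivative of the Boltzmann differential conductance with respect to
#' voltage: integrating \eqn{dI/dV = G_{max}[B + (1-B)/(1 + e^{(V_{50}-V)/K})]}
#' gives
#' \deqn{I(V) = B\,G_{max}\,V + G_{max}(1-B)\,K\,
#'   \ln\!\left(e^{V/K} + e^{V_{50}/K}\right) + C,}
#' where `c_int` is the integration constant fixed by the I-V curve's offset.
#' The log-sum term is evaluated in a log-sum-exp form,
#' \eqn{\max(V, V_{50}) + K \log(1 + e^{-|V - V_{50}|/K})}, so the expression
#' is finite for any voltage.
#'
#' This closed form is fitted directly to in-bin raw (V, I) points by
#' [fit_integrated_iv()].
#'
#' @inheritParams boltzmann_conductance
#' @param c_int Integration constant, pA.
#' @return Current, pA.
#' @examples
#' v <- seq(-60, -25, by = 5)
#' integrated_iv(v, v50 = -40, k = 5, g_max = 20, c_int = 0)
#' @export
integrated_iv <- function(v, v50, k, g_max, c_int, b = 0) {
  if (any(k <= 0)) abort("`k` (slope factor) must be positive.")
  lse <- pmax(v, v50) + k * log1p(exp(-abs(v - v50) / k))
  b * g_max * v + g_max * (1 - b) * lse + c_int
}

#' Voltage bins for channel classes
#'
#' The analysis separates the I-V curve into a low-voltage-activated (LVA,
#' Kv1-like) bin and a high-voltage-activated (HVA, Kv3-like) bin on the
#' junction-corrected voltage axis.  Bin membership is a closed interval and a
#' voltage pair contributes to the differential conductance only when both
#' endpoints are in the bin.  For the LVA bin the baseline open fraction `B`
#' is fixed at zero; for the HVA bin it is free in `[0, 1)` so that residual
#' LVA current is absorbed as a baseline.
#'
#' @param name `"LVA"` or `"HVA"`.
#' @param lo,hi Bin bounds, mV (closed interval).  Defaults are the standard
#'   bins: LVA `[-60, -25]`, HVA `[-20, +30]`.
#' @return A `voltage_bin` object.
#' @export
voltage_bin <- function(name = c("LVA", "HVA"), lo = NULL, hi = NULL) {
  name <- match.arg(name)
  if (is.null(lo)) lo <- if (name == "LVA") -60 else -20
  if (is.null(hi)) hi <- if (name == "LVA") -25 else 30
  if (lo >= hi) abort("`lo` must be less than `hi`.")
  structure(
    list(name = name, lo = lo, hi = hi,
         b_policy = if (name == "LVA") "fixed_zero" else "free"),
    class = "voltage_bin"
  )
}

#' @rdname voltage_bin
#' @export
lva_bin <- function() voltage_bin("LVA")

#' @rdname voltage_bin
#' @export
hva_bin <- function() voltage_bin("HVA")

#' @export
print.voltage_bin <- function(x, ...) {
  cat(sprintf("<voltage_bin> %s: [%g, %g] mV, B %s\n", x$name, x$lo, x$hi,
              if (x$b_policy == "fixed_zero") "fixed at 0" else "free in [0,1)"))
  invisible(x)
}

in_bin <- function(v, bin, tol = 1e-9) {
  v >= bin$lo - tol & v <= bin$hi + tol
}

#' Standard read-out voltages
#'
#' The voltages at which fitted open probability and differential conductance
#' are compared across conditions: -42.5 mV for the LVA channel class and
#' -2.5 mV (open probability) / +17.5 mV (differential conductance) for the
#' HVA class.  All three are midpoints of the 5-mV command increments.
#'
#' @return Named numeric vector, mV.
#' @export
readout_voltages <- function() {
  c(lva = -42.5, hva_po = -2.5, hva_g = 17.5)
}
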