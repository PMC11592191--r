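#' Correct command voltages for the liquid junction potential
#'
#' Adds the liquid junction potential (default -10 mV for the standard
#' K-gluconate internal) to nominal command levels:
#' `corrected = nominal + ljp`.  Order is preserved.  When given a
#' [vclamp_protocol()], the protocol's own `ljp` is used and a
#' `ljp_corrected` flag guards against applying the correction twice.
#'
#' @param x Numeric vector of nominal command levels (mV), or a
#'   [vclamp_protocol()].
#' @param ljp Liquid junction potential, mV (ignored when `x` is a protocol).
#' @return Corrected levels (numeric) or a corrected protocol.
#' @examples
#' correct_junction_potential(c(-40, 0), ljp = -10)  # -50, -10
#' @export
correct_junction_potential <- function(x, ljp = -10) {
  if (inherits(x, "vclamp_protocol")) {
    if (isTRUE(x$ljp_corrected)) {
      abort("Protocol levels are already junction-corrected.")
    }
    x$levels <- x$levels + x$ljp
    x$holding <- x$holding + x$ljp
    x$ljp_corrected <- TRUE
    return(x)
  }
  if (!is.finite(ljp)) abort("`ljp` must be finite.")
  x + ljp
}

#' Steady-state current of one voltage-clamp sweep
#'
#' Averages the current over a 1-ms window placed 3 ms before the end of the
#' voltage command: for a 150-ms command the window is `[147, 148)` ms.  The
#' window is half-open and resolved to the sample grid, and sits late enough
#' that activation transients have fully decayed while avoiding the
#' capacitive artifact at command offset.
#'
#' @param trace A two-column tibble/data.frame with `time_ms` and `current_pA`
#'   (or any second numeric column).
#' @param duration Command duration, ms.
#' @param end_offset Window start measured back from command end, ms.
#' @param width Window width, ms.
#' @return Mean current over the window, pA.
#' @export
steady_state_current <- function(trace, duration, end_offset = 3, width = 1) {
  if (duration - end_offset < 0 || width <= 0) {
    abort("Window must lie within the command: need duration - end_offset >= 0 and width > 0.")
  }
  t <- trace$time_ms
  y <- trace[[setdiff(names(trace), "time_ms")[1]]]
  t0 <- duration - end_offset
  t1 <- t0 + width
  if (t0 < min(t) - 1e-9 || t1 > max(t) + 1e-9) {
    abort(sprintf("Averaging window [%g, %g) ms lies outside the trace extent.", t0, t1))
  }
  sel <- t >= t0 - 1e-9 & t < t1 - 1e-9
  if (!any(sel)) abort("No samples fall inside the averaging window.")
  mean(y[sel])
}

#' Build a junction-corrected I-V curve from a voltage-clamp family
#'
#' Applies the liquid-junction-potential correction once to the command
#' levels and computes the steady-state current ([steady_state_current()])
#' of each sweep, returning the points of the steady-state I-V relation
#' sorted by ascending corrected voltage.
#'
#' @param family A [sweep_family()] of `kind = "current"` whose protocol is a
#'   [vclamp_protocol()].
#' @param end_offset,width Steady-state window settings, ms.
#' @return A tibble of class `nm_iv` with columns `v_mV` (corrected command)
#'   and `i_pA`, and attribute `ljp_corrected = TRUE`.
#' @export
build_iv_curve <- function(family, end_offset = 3, width = 1) {
  stopifnot(inherits(family, "sweep_family"))
  if (family$kind != "current") abort("`family` must contain current sweeps.")
  proto <- family$protocol
  if (is.null(proto)) abort("`family` carries no voltage-clamp protocol.")
  if (!"command_mV" %in% names(family$info)) {
    abort("`family$info` must have a `command_mV` column.")
  }
  v <- family$info$command_mV
  if (!isTRUE(proto$ljp_corrected)) v <- v + proto$ljp
  i <- vapply(seq_len(ncol(family$sweeps)), function(j) {
    steady_state_current(family_trace(family, j), duration = proto$duration,
                         end_offset = end_offset, width = width)
  }, numeric(1))
  ord <- order(v)
  out <- tibble(v_mV = v[ord], i_pA = i[ord])
  class(out) <- c("nm_iv", class(out))
  attr(out, "ljp_corrected") <- TRUE
  out
}

#' Read the steady-state current at (or nearest to) a voltage
#'
#' @param iv An I-V curve from [build_iv_curve()].
#' @param v Corrected voltage, mV.  Matched to the nearest available level;
#'   errors if the nearest level is more than `tol` away.
#' @param tol Matching tolerance, mV.
#' @return Current, pA.
#' @export
iv_current_at <- function(iv, v, tol = 2.6) {
  j <- which.min(abs(iv$v_mV - v))
  if (abs(iv$v_mV[j] - v) > tol) {
    abort(sprintf("No I-V level within %g mV of %g mV.", tol, v))
  }
  iv$i_pA[j]
}

#' @export
autoplot.nm_iv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v_mV, y = .data$i_pA)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Command voltage, junction-corrected (mV)",
                  y = "Steady-state current (pA)") +
    ggplot2::theme_minimal()
}
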