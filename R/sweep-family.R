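#' Sweep family container
#'
#' A family of sweeps recorded (or simulated) on a shared uniform time base:
#' a time vector in ms plus one column per sweep.  Used for both voltage-clamp
#' families (one current sweep per command level, `kind = "current"`) and
#' current-clamp families (repetitions per injected amplitude,
#' `kind = "voltage"`).  Construct with `sweep_family()`; convert to a long
#' tibble with [tidy()] for plotting and ad hoc analysis.
#'
#' @param time_ms Uniform, strictly increasing time grid (ms), length >= 2.
#' @param sweeps Numeric matrix, `length(time_ms)` rows, one column per sweep.
#' @param info Tibble describing the columns of `sweeps` (one row per sweep),
#'   e.g. columns `command_mV` or `amplitude_pA`, `rep`.
#' @param kind `"current"` (pA) or `"voltage"` (mV).
#' @param protocol Optional protocol object stored alongside the data.
#' @return A `sweep_family` object.
#' @export
sweep_family <- function(time_ms, sweeps, info, kind = c("current", "voltage"),
                         protocol = NULL) {
  kind <- match.arg(kind)
  sweeps <- as.matrix(sweeps)
  if (length(time_ms) < 2L) abort("A sweep needs at least 2 samples.")
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * dt[1]) {
    abort("`time_ms` must be strictly increasing and uniform.")
  }
  if (nrow(sweeps) != length(time_ms)) {
    abort("`sweeps` must have one row per time sample.")
  }
  info <- as_tibble(info)
  if (nrow(info) != ncol(sweeps)) {
    abort("`info` must have one row per sweep column.")
  }
  structure(
    list(time_ms = as.numeric(time_ms), sweeps = sweeps, info = info,
         kind = kind, protocol = protocol,
         sampling_interval = dt[1]),
    class = "sweep_family"
  )
}

#' @export
print.sweep_family <- function(x, ...) {
  cat(sprintf("<sweep_family> %d %s sweep(s), %d samples @ %.4g ms (%.4g-%.4g ms)\n",
              ncol(x$sweeps), x$kind, length(x$time_ms),
              x$sampling_interval, min(x$time_ms), max(x$time_ms)))
  print(x$info, n = 5)
  invisible(x)
}

#' @export
#' @rdname sweep_family
#' @param x A `sweep_family`.
#' @param ... Unused.
tidy.sweep_family <- function(x, ...) {
  value_col <- if (x$kind == "current") "current_pA" else "voltage_mV"
  n_t <- length(x$time_ms)
  out <- x$info[rep(seq_len(nrow(x$info)), each = n_t), , drop = FALSE]
  out$sweep_id <- rep(seq_len(ncol(x$sweeps)), each = n_t)
  out$time_ms <- rep(x$time_ms, times = ncol(x$sweeps))
  out[[value_col]] <- as.vector(x$sweeps)
  as_tibble(out)
}

# Pull one sweep as a two-column tibble (time_ms + value column).
family_trace <- function(x, j) {
  value_col <- if (x$kind == "current") "current_pA" else "voltage_mV"
  tibble(time_ms = x$time_ms, !!value_col := x$sweeps[, j])
}

#' @export
autoplot.sweep_family <- function(object, ...) {
  df <- tidy(object)
  value_col <- if (object$kind == "current") "current_pA" else "voltage_mV"
  lab <- if (object$kind == "current") "Current (pA)" else "Voltage (mV)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data[[value_col]],
                                   group = .data$sweep_id)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::labs(x = "Time (ms)", y = lab) +
    ggplot2::theme_minimal()
}
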