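#' Differential conductance of an I-V curve
#'
#' Forward difference between consecutive in-bin I-V points, reported at the
#' midpoint of each voltage increment:
#' \eqn{g_j = (I_{j+1} - I_j)/(V_{j+1} - V_j)} at \eqn{(V_j + V_{j+1})/2}.
#' With pA and mV this is directly in nS.  A pair contributes only when both
#' of its endpoints lie inside the (closed) bin, so no midpoint straddles the
#' gap between the LVA and HVA bins.  With 5-mV increments this scheme puts
#' midpoints exactly on the standard read-out grid (-42.5, -2.5, +17.5 mV).
#'
#' @param iv An I-V curve ([build_iv_curve()]) on corrected voltages.
#' @param bin A [voltage_bin()].
#' @return A tibble of class `nm_conductance` with columns `v_mid` (mV) and
#'   `g` (nS), plus attributes `bin`.
#' @export
differential_conductance <- function(iv, bin) {
  stopifnot(inherits(bin, "voltage_bin"))
  sub <- iv[in_bin(iv$v_mV, bin), , drop = FALSE]
  sub <- sub[order(sub$v_mV), , drop = FALSE]
  if (nrow(sub) < 2L) {
    abort(sprintf("Need at least 2 I-V points inside the %s bin [%g, %g] mV.",
                  bin$name, bin$lo, bin$hi))
  }
  dv <- diff(sub$v_mV)
  g <- diff(sub$i_pA) / dv
  out <- tibble(v_mid = sub$v_mV[-nrow(sub)] + dv / 2, g = g)
  class(out) <- c("nm_conductance", class(out))
  attr(out, "bin") <- bin
  out
}

#' Normalize differential conductance to open probability
#'
#' Divides each differential-conductance value by the largest value in the
#' bin, mapping the curve to an empirical open probability in `[0, 1]` whose
#' maximum is exactly 1.  Small negative slopes (recording noise) are clipped
#' to zero before normalization and flagged; normalization is per bin.
#'
#' @param gc A conductance curve from [differential_conductance()].
#' @param clip_negative Clip negative slopes to 0 (default TRUE).
#' @return A tibble of class `nm_openprob` with columns `v_mid`, `p_o`, and
#'   logical `clipped`; attributes `g_max_empirical` (nS, the normalizer) and
#'   `bin`.
#' @export
normalize_open_probability <- function(gc, clip_negative = TRUE) {
  g <- gc$g
  clipped <- rep(FALSE, length(g))
  if (clip_negative && any(g < 0)) {
    clipped <- g < 0
    g[clipped] <- 0
  }
  g_max <- max(g)
  if (!is.finite(g_max) || g_max <= 0) {
    abort("Maximum differential conductance is not positive; curve is not an outward activation curve.")
  }
  out <- tibble(v_mid = gc$v_mid, p_o = g / g_max, clipped = clipped)
  class(out) <- c("nm_openprob", class(out))
  attr(out, "g_max_empirical") <- g_max
  attr(out, "bin") <- attr(gc, "bin")
  out
}

new_boltzmann_fit <- function(estimate, se, bin, converged, residual_rms,
                              n, method, data, v_range) {
  structure(
    list(estimate = estimate, se = se, bin = bin, converged = converged,
         residual_rms = residual_rms, n = n, method = method, data = data,
         v_range = v_range),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> %s (%s), %s\n", x$bin$name, x$method,
              if (x$converged) "converged" else "NOT converged"))
  est <- x$estimate
  se <- x$se
  for (nm in names(est)) {
    cat(sprintf("  %-6s %10.5g  (SE %.3g)\n", nm, est[[nm]],
                if (is.na(se[[nm]])) NA else se[[nm]]))
  }
  cat(sprintf("  n = %d points on [%g, %g] mV, residual RMS = %.4g\n",
              x$n, x$v_range[1], x$v_range[2], x$residual_rms))
  invisible(x)
}

#' @export
tidy.boltzmann_fit <- function(x, conf.level = 0.95, ...) {
  z <- qt(1 - (1 - conf.level) / 2, df = max(x$n - sum(!is.na(x$se)), 1))
  tibble(
    term = names(x$estimate),
    estimate = unname(unlist(x$estimate)),
    std.error = unname(unlist(x$se)),
    conf.low = unname(unlist(x$estimate)) - z * unname(unlist(x$se)),
    conf.high = unname(unlist(x$estimate)) + z * unname(unlist(x$se))
  )
}

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(bin = x$bin$name, method = x$method, converged = x$converged,
         residual_rms = x$residual_rms, n = x$n,
         v_lo = x$v_range[1], v_hi = x$v_range[2])
}

# Run nlsLM over a list of candidate starts and keep the lowest-RSS success.
# The integrated I-V closed form can be weakly identified on a handful of
# in-bin points, so a single start occasionally lands on a singular gradient.
nls_multistart <- function(formula, data, starts, lower, upper) {
  # data-driven primary start first; fall back to the grid only when it
  # fails or does not converge
  first <- nls_safe(formula, data, starts[[1]], lower, upper)
  if (first$ok && first$converged) {
    first$rss <- sum(first$resid^2)
    return(first)
  }
  best <- NULL       # lowest-RSS converged candidate
  best_any <- NULL   # lowest-RSS candidate of any convergence status
  msg <- "no candidate start succeeded"
  for (st in starts) {
    res <- nls_safe(formula, data, st, lower, upper)
    if (!res$ok) { msg <- res$message; next }
    res$rss <- sum(res$resid^2)
    if (is.null(best_any) || res$rss < best_any$rss - 1e-12) best_any <- res
    if (res$converged && (is.null(best) || res$rss < best$rss - 1e-12)) {
      best <- res
    }
  }
  if (!is.null(best)) return(best)
  if (!is.null(best_any)) return(best_any)
  list(ok = FALSE, message = msg)
}

nls_safe <- function(formula, data, start, lower, upper) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-9,
                                     ptol = 1e-9)
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower[names(start)], upper = upper[names(start)],
                      control = ctrl),
    error = function(e) e
  )
  if (!inherits(fit, "error")) {
    est <- coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) setNames(rep(NA_real_, length(est)),
                                                names(est)))
    info <- fit$convInfo
    converged <- isTRUE(info$isConv) ||
      (!is.null(info$stopCode) && info$stopCode %in% 1:4)
    return(list(ok = TRUE, estimate = est, se = se, converged = converged,
                resid = stats::resid(fit)))
  }
  # nlsLM builds an `nls` object after optimizing, which fails when the
  # solution sits on a rank-deficient ridge; rerun raw Levenberg-Marquardt
  # on the residual function and report honest (possibly NA) uncertainties.
  lhs <- all.vars(formula[[2]])
  rhs <- formula[[3]]
  resid_fn <- function(par) {
    data[[lhs]] - eval(rhs, c(as.list(data), as.list(par)))
  }
  lm <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = lower[names(start)],
                       upper = upper[names(start)], control = ctrl),
    error = function(e) e
  )
  if (inherits(lm, "error")) {
    return(list(ok = FALSE, message = conditionMessage(lm)))
  }
  est <- unlist(lm$par)
  n <- length(lm$fvec)
  p <- length(est)
  sigma2 <- lm$deviance / max(n - p, 1)
  covm <- tryCatch(sigma2 * solve(lm$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) setNames(rep(NA_real_, p), names(est)) else
    setNames(sqrt(pmax(diag(covm), 0)), names(est))
  list(ok = TRUE, estimate = est, se = se, converged = lm$info %in% 1:3,
       resid = lm$fvec)
}

#' Fit the Boltzmann activation curve to an open-probability curve
#'
#' Nonlinear least-squares fit of [boltzmann_po()] to the normalized
#' differential conductance (`v_mid`, `p_o`).  For the LVA bin the baseline
#' open fraction `B` is fixed at zero (2 free parameters, requires >= 3
#' points); for the HVA bin `B` is free in `[0, 1)` (3 free parameters,
#' requires >= 4 points).  The slope factor is constrained positive so the
#' fitted sigmoid is increasing.
#'
#' @param po An open-probability curve from [normalize_open_probability()],
#'   or any tibble with `v_mid` and `p_o` columns.
#' @param bin A [voltage_bin()]; defaults to the bin attribute of `po`.
#' @param init Optional named list of starting values (`v50`, `k`, `b`).
#' @return A `boltzmann_fit` with estimates and standard errors for `b`,
#'   `v50`, `k` (and `g_max = NA`, `c_int = NA`, which this fit does not
#'   determine).
#' @export
fit_boltzmann <- function(po, bin = attr(po, "bin"), init = NULL) {
  stopifnot(inherits(bin, "voltage_bin"))
  d <- tibble(v = po$v_mid, y = po$p_o)
  free_b <- bin$b_policy == "free"
  need <- if (free_b) 4L else 3L
  if (nrow(d) < need) {
    abort(sprintf("Need at least %d points to fit the %s bin.", need, bin$name))
  }
  start <- list(
    v50 = d$v[which.min(abs(d$y - 0.5 * (max(d$y) + min(d$y))))],
    k = max(diff(range(d$v)) / 6, 1)
  )
  if (free_b) start$b <- max(min(d$y), 0.01)
  if (!is.null(init)) start <- utils::modifyList(start, as.list(init))

  grid <- expand.grid(
    v50 = unique(c(start$v50, unname(stats::quantile(d$v, c(0.25, 0.5, 0.75))))),
    k = unique(c(start$k, 2, 8)))
  if (free_b) {
    starts <- purrr::pmap(grid, function(v50, k)
      list(b = start$b, v50 = v50, k = k))
    res <- nls_multistart(y ~ b + (1 - b) * plogis((v - v50) / k), d,
                          starts = c(list(start[c("b", "v50", "k")]), starts),
                          lower = c(b = 0, v50 = -150, k = 0.05),
                          upper = c(b = 0.999, v50 = 60, k = 100))
  } else {
    starts <- purrr::pmap(grid, function(v50, k) list(v50 = v50, k = k))
    res <- nls_multistart(y ~ plogis((v - v50) / k), d,
                          starts = c(list(start[c("v50", "k")]), starts),
                          lower = c(v50 = -150, k = 0.05),
                          upper = c(v50 = 60, k = 100))
  }
  if (!res$ok) abort(sprintf("Boltzmann fit failed: %s", res$message))
  est <- list(b = if (free_b) unname(res$estimate["b"]) else 0,
              v50 = unname(res$estimate["v50"]),
              k = unname(res$estimate["k"]),
              g_max = unname(attr(po, "g_max_empirical") %||% NA_real_),
              c_int = NA_real_)
  se <- list(b = if (free_b) unname(res$se["b"]) else NA_real_,
             v50 = unname(res$se["v50"]),
             k = unname(res$se["k"]),
             g_max = NA_real_, c_int = NA_real_)
  new_boltzmann_fit(est, se, bin, res$converged,
                    sqrt(mean(res$resid^2)), nrow(d), "open_probability",
                    data = d, v_range = range(d$v))
}

#' Fit the integrated Boltzmann I-V closed form to raw I-V points
#'
#' Fits [integrated_iv()] directly to the in-bin (V, I) points of the
#' steady-state I-V curve, estimating `v50`, `k`, `g_max`, and the
#' integration constant `c_int` (plus the baseline `b` for the HVA bin).
#' Because the command grid has no point at V = 0, the integration constant
#' is initialized so the model passes through the lowest-voltage in-bin point
#' and is then co-fitted; this preserves its role as the additive offset of
#' the I-V curve while keeping the fit well posed.  The fitted `g_max` values
#' are the per-neuron maximal differential conductances compared across
#' conditions.
#'
#' @param iv An I-V curve on corrected voltages ([build_iv_curve()]).
#' @param bin A [voltage_bin()].
#' @param init Optional named list of starting values
#'   (`v50`, `k`, `g_max`, `c_int`, `b`).
#' @return A `boltzmann_fit` with estimates, standard errors, convergence
#'   flag, and residual RMS.
#' @export
fit_integrated_iv <- function(iv, bin, init = NULL) {
  stopifnot(inherits(bin, "voltage_bin"))
  sub <- iv[in_bin(iv$v_mV, bin), , drop = FALSE]
  sub <- sub[order(sub$v_mV), , drop = FALSE]
  free_b <- bin$b_policy == "free"
  n_par <- if (free_b) 5L else 4L
  if (nrow(sub) < n_par + 1L) {
    abort(sprintf("Need at least %d in-bin I-V points for the %s fit.",
                  n_par + 1L, bin$name))
  }
  d <- tibble(v = sub$v_mV, i = sub$i_pA)
  slope <- diff(d$i) / diff(d$v)
  vmid <- d$v[-nrow(d)] + diff(d$v) / 2
  g0 <- max(max(slope), 1e-3)
  half <- which.min(abs(slope - 0.5 * g0))
  start <- list(v50 = vmid[half], k = max(diff(range(d$v)) / 6, 1), g_max = g0)
  if (free_b) start$b <- min(max(min(slope) / g0, 0.01), 0.8)
  b0 <- if (free_b) start$b else 0
  start$c_int <- d$i[1] - integrated_iv(d$v[1], v50 = start$v50, k = start$k,
                                        g_max = start$g_max, c_int = 0,
                                        b = b0)
  if (!is.null(init)) start <- utils::modifyList(start, as.list(init))

  c_for <- function(st) {
    d$i[1] - integrated_iv(d$v[1], v50 = st$v50, k = st$k, g_max = st$g_max,
                           c_int = 0, b = st$b %||% 0)
  }
  grid <- expand.grid(
    v50 = unique(c(start$v50, unname(stats::quantile(d$v, c(0.25, 0.75))))),
    k = unique(c(start$k, 2, 10)),
    g_max = unique(c(start$g_max, start$g_max / 2)),
    b = if (free_b) unique(c(start$b, 0.3)) else 0)
  alt <- purrr::pmap(grid, function(v50, k, g_max, b) {
    st <- list(v50 = v50, k = k, g_max = g_max)
    if (free_b) st$b <- b
    st$c_int <- c_for(st)
    st
  })
  keys <- if (free_b) c("b", "v50", "k", "g_max", "c_int") else
    c("v50", "k", "g_max", "c_int")
  starts <- c(list(start[keys]), purrr::map(alt, ~ .x[keys]))
  if (free_b) {
    res <- nls_multistart(
      i ~ integrated_iv(v, v50 = v50, k = k, g_max = g_max, c_int = c_int,
                        b = b),
      d, starts = starts,
      lower = c(b = 0, v50 = -150, k = 0.05, g_max = 1e-6, c_int = -1e7),
      upper = c(b = 0.999, v50 = 60, k = 40, g_max = 1e5, c_int = 1e7))
  } else {
    res <- nls_multistart(
      i ~ integrated_iv(v, v50 = v50, k = k, g_max = g_max, c_int = c_int),
      d, starts = starts,
      lower = c(v50 = -150, k = 0.05, g_max = 1e-6, c_int = -1e7),
      upper = c(v50 = 60, k = 40, g_max = 1e5, c_int = 1e7))
  }
  if (!res$ok) abort(sprintf("Integrated I-V fit failed: %s", res$message))
  if (any(!is.finite(res$se))) {
    warn(sprintf("%s integrated I-V fit is rank-deficient: some standard errors are not finite.",
                 bin$name))
  }
  est <- list(b = if (free_b) unname(res$estimate["b"]) else 0,
              v50 = unname(res$estimate["v50"]),
              k = unname(res$estimate["k"]),
              g_max = unname(res$estimate["g_max"]),
              c_int = unname(res$estimate["c_int"]))
  se <- list(b = if (free_b) unname(res$se["b"]) else NA_real_,
             v50 = unname(res$se["v50"]),
             k = unname(res$se["k"]),
             g_max = unname(res$se["g_max"]),
             c_int = unname(res$se["c_int"]))
  new_boltzmann_fit(est, se, bin, res$converged, sqrt(mean(res$resid^2)),
                    nrow(d), "integrated_iv",
                    data = d, v_range = range(d$v))
}

#' Read out fitted open probability and differential conductance
#'
#' Evaluates a fitted Boltzmann model at one or more voltages, returning the
#' open probability and the model differential conductance
#' \eqn{g(V) = G_{max} P_O(V)}.  The standard comparison voltages are
#' [readout_voltages()]: -42.5 mV (LVA), -2.5 mV (HVA open probability) and
#' +17.5 mV (HVA differential conductance).
#'
#' @param fit A converged `boltzmann_fit`.
#' @param v Voltage(s), mV.
#' @return A tibble with columns `v_mV`, `p_o`, `g_nS`.
#' @export
readout_at <- function(fit, v) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (!fit$converged) abort("Cannot read out an unconverged fit.")
  p <- boltzmann_po(v, v50 = fit$estimate$v50, k = fit$estimate$k,
                    b = fit$estimate$b)
  tibble(v_mV = v, p_o = p, g_nS = fit$estimate$g_max * p)
}

#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  d <- object$data
  vv <- seq(min(d$v) - 5, max(d$v) + 5, length.out = 200)
  if (object$method == "open_probability") {
    curve <- tibble(v = vv, y = boltzmann_po(vv, v50 = object$estimate$v50,
                                             k = object$estimate$k,
                                             b = object$estimate$b))
    ylab <- "Open probability"
  } else {
    curve <- tibble(v = vv, y = integrated_iv(vv, v50 = object$estimate$v50,
                                              k = object$estimate$k,
                                              g_max = object$estimate$g_max,
                                              c_int = object$estimate$c_int,
                                              b = object$estimate$b))
    ylab <- "Steady-state current (pA)"
  }
  names(d)[2] <- "y"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$v, y = .data$y)) +
    ggplot2::geom_line(data = curve, color = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Voltage (mV)", y = ylab,
                  title = sprintf("%s bin (%s)", object$bin$name, object$method)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
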