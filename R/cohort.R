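#' Experimental condition specification for cohort simulation
#'
#' Describes one experimental group as multiplicative scalings of the base
#' potassium conductances plus the distribution of resting potentials and the
#' group size.  Condition effects are represented *only* as conductance
#' scalings: the BDNF presets scale the LVA and HVA maximal conductances by
#' the ratios of the printed treated/control differential-conductance group
#' means (11.92/20.19 for LVA, 50.40/72.76 for HVA), the TrkB-antagonist
#' rescue presets by the corresponding rescue ratios, and the antagonist-only
#' control by 1.
#'
#' @param name Condition: `"control"`, `"BDNF"`, `"BDNF_ANA12"`,
#'   `"BDNF_GNF5837"`, `"ANA12"`.
#' @param age `"E13"` or `"E20_21"`.
#' @param region `"high_freq"` or `"low_freq"`.
#' @param scale_lva,scale_hva Positive multipliers on the base LVA/HVA
#'   `g_max`.
#' @param rmp_mean,rmp_sd Resting-potential distribution, mV.
#' @param n_neurons Group size (>= 1).
#' @param cv Per-neuron log-normal coefficients of variation for `g_leak`,
#'   `lva`, `hva` conductances and `c_m` (calibrated to the printed group
#'   SDs).
#' @return A `condition_spec` object.
#' @export
condition_spec <- function(name = c("control", "BDNF", "BDNF_ANA12",
                                    "BDNF_GNF5837", "ANA12"),
                           age = c("E13", "E20_21"),
                           region = c("high_freq", "low_freq"),
                           scale_lva = 1, scale_hva = 1,
                           rmp_mean = -65, rmp_sd = 2.5,
                           n_neurons = 16,
                           cv = list(g_leak = 0.3, lva = 0.17, hva = 0.28,
                                     c_m = 0.12)) {
  name <- match.arg(name)
  age <- match.arg(age)
  region <- match.arg(region)
  if (scale_lva <= 0 || scale_hva <= 0) abort("Scale multipliers must be > 0.")
  if (n_neurons < 1) abort("`n_neurons` must be >= 1.")
  cv <- utils::modifyList(list(g_leak = 0.3, lva = 0.17, hva = 0.28,
                               c_m = 0.12), as.list(cv))
  structure(
    list(name = name, age = age, region = region,
         scale_lva = scale_lva, scale_hva = scale_hva,
         rmp_mean = rmp_mean, rmp_sd = rmp_sd,
         n_neurons = as.integer(n_neurons), cv = cv),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> %s (%s, %s): n = %d, scale LVA %.4g / HVA %.4g, RMP %g +/- %g mV\n",
              x$name, x$age, x$region, x$n_neurons, x$scale_lva, x$scale_hva,
              x$rmp_mean, x$rmp_sd))
  invisible(x)
}

#' Built-in condition presets (E13 high-frequency groups)
#'
#' Group sizes and conductance-scaling ratios for the early-embryonic
#' high-frequency experiment: control (n = 16), BDNF (n = 20, LVA scaled
#' 11.92/20.19, HVA 50.40/72.76), BDNF + ANA-12 rescue (n = 11, 18.39/20.19
#' and 80.16/72.76), and ANA-12 alone (n = 6, no scaling).
#'
#' @param name Condition name.
#' @param n_neurons Optional group-size override.
#' @return A [condition_spec()].
#' @export
nm_condition <- function(name = c("control", "BDNF", "BDNF_ANA12", "ANA12"),
                         n_neurons = NULL) {
  name <- match.arg(name)
  preset <- switch(
    name,
    control = list(scale_lva = 1, scale_hva = 1, n = 16L),
    BDNF = list(scale_lva = 11.92 / 20.19, scale_hva = 50.40 / 72.76, n = 20L),
    BDNF_ANA12 = list(scale_lva = 18.39 / 20.19, scale_hva = 80.16 / 72.76,
                      n = 11L),
    ANA12 = list(scale_lva = 1, scale_hva = 1, n = 6L)
  )
  condition_spec(name = name, age = "E13", region = "high_freq",
                 scale_lva = preset$scale_lva, scale_hva = preset$scale_hva,
                 n_neurons = n_neurons %||% preset$n)
}

lognormal_jitter <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  mean * exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a cohort of neurons under one condition
#'
#' Draws `n_neurons` per-neuron parameter sets from the base
#' [channel_params()] -- log-normal jitter on conductances and capacitance
#' (positivity and right skew), condition scaling on the potassium `g_max`
#' values, per-neuron resting potential via the leak reversal, and a series
#' resistance drawn from N(6, 2) MOhm truncated at 2 -- then simulates the
#' voltage-clamp family and (optionally) the current-clamp protocol for each
#' neuron.  The current-clamp protocol mirrors the bench workflow: a -10 pA
#' passive step, an ascending threshold search in 10-pA increments with 10
#' repetitions per amplitude (stopping once the 5-of-10 rule is satisfied),
#' and 10 repetitions at 1.25 x threshold.
#'
#' Generation is a pure function of `(spec, base, seed)`: per-neuron child
#' seeds are derived deterministically from the root seed, so cohorts are
#' reproducible bit-for-bit.  A maximum of 6 neurons share an embryo label.
#'
#' @param spec A [condition_spec()].
#' @param base A [channel_params()] object (condition scalings are applied on
#'   top of it).
#' @param seed Integer root seed.
#' @param include_cclamp Simulate current-clamp families (default TRUE).
#'   Voltage-clamp-only cohorts are considerably faster and are sufficient
#'   for conductance fitting.
#' @param vclamp A [vclamp_protocol()].
#' @param search_amplitudes Threshold-search amplitudes, pA.
#' @param search_record_dt,fine_record_dt Sampling intervals (ms) for the
#'   stored threshold-search sweeps and for passive/suprathreshold sweeps.
#' @return An `nm_cohort`: a tibble with one row per neuron (`neuron_id`,
#'   `embryo_id`, `condition`, `age`, `region`, `rmp_target_mV`,
#'   `series_resistance_MOhm`, plus list-columns `params`, `vclamp`,
#'   `cclamp`), with the spec, base, and seed stored as attributes.
#' @export
make_cohort <- function(spec, base = channel_params(), seed = 1,
                        include_cclamp = TRUE,
                        vclamp = vclamp_protocol(),
                        search_amplitudes = seq(-100, 500, by = 10),
                        search_record_dt = 0.1,
                        fine_record_dt = 0.02) {
  stopifnot(inherits(spec, "condition_spec"),
            inherits(base, "channel_params"))
  n <- spec$n_neurons

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seeds[i])
    p <- base
    p$g_leak <- lognormal_jitter(1, base$g_leak, spec$cv$g_leak)
    p$c_m <- lognormal_jitter(1, base$c_m, spec$cv$c_m)
    p$lva$g_max <- lognormal_jitter(1, base$lva$g_max * spec$scale_lva,
                                    spec$cv$lva)
    p$hva$g_max <- lognormal_jitter(1, base$hva$g_max * spec$scale_hva,
                                    spec$cv$hva)
    rmp_target <- rnorm(1, spec$rmp_mean, spec$rmp_sd)
    p$e_leak <- leak_reversal_for_rmp(p, rmp_target)
    rs <- max(2, rnorm(1, 6, 2))

    vc <- simulate_vclamp_family(p, vclamp, seed = child_seeds[i] %% 1000000L)
    cc <- NULL
    if (include_cclamp) {
      cc <- simulate_cclamp_protocol(
        p, seed = child_seeds[i] %% 1000000L + 1L,
        search_amplitudes = search_amplitudes,
        search_record_dt = search_record_dt,
        fine_record_dt = fine_record_dt)
    }
    rows[[i]] <- tibble(
      neuron_id = sprintf("%s_%s_%s_n%02d", spec$age, spec$region, spec$name, i),
      embryo_id = sprintf("%s_%s_e%02d", spec$name, spec$age, ceiling(i / 6)),
      condition = spec$name, age = spec$age, region = spec$region,
      rmp_target_mV = rmp_target, series_resistance_MOhm = rs,
      params = list(p), vclamp = list(vc), cclamp = list(cc)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nm_cohort", class(out))
  attr(out, "spec") <- spec
  attr(out, "base") <- base
  attr(out, "seed") <- seed
  out
}

# One neuron's bench-style current-clamp session: passive step, ascending
# threshold search that stops once the 5-of-10 rule is met, suprathreshold
# repetitions at 1.25 * I_T.
simulate_cclamp_protocol <- function(params, seed,
                                     search_amplitudes = seq(-100, 500, by = 10),
                                     reps = 10,
                                     search_record_dt = 0.1,
                                     fine_record_dt = 0.02,
                                     detection = detection_settings()) {
  passive <- simulate_cclamp_trace(
    params, stim = list(amplitude = -10, onset = 20, duration = 100),
    seed = seed, record_dt = fine_record_dt)

  searched <- list()
  i_t <- NA_real_
  pos <- search_amplitudes[search_amplitudes != 0]
  for (amp in pos) {
    fam <- simulate_cclamp_family(params, amplitudes = amp, reps = reps,
                                  seed = seed, record_dt = search_record_dt)
    searched[[as.character(amp)]] <- fam
    if (amp > 0) {
      n_spk <- sum(vapply(seq_len(reps), function(j) {
        nrow(detect_aps(family_trace(fam, j), detection)) >= 1L
      }, logical(1)))
      if (n_spk >= reps / 2) { i_t <- amp; break }
    }
  }
  search <- merge_families(searched)

  supra <- NULL
  if (!is.na(i_t)) {
    supra <- simulate_cclamp_family(params, amplitudes = 1.25 * i_t,
                                    reps = reps, seed = seed + 1L,
                                    record_dt = fine_record_dt)
  }
  list(passive = passive, search = search, supra = supra)
}

merge_families <- function(fams) {
  fams <- purrr::compact(fams)
  if (length(fams) == 0L) return(NULL)
  time_ms <- fams[[1]]$time_ms
  sweeps <- do.call(cbind, purrr::map(fams, "sweeps"))
  info <- dplyr::bind_rows(purrr::map(fams, "info"))
  out <- sweep_family(time_ms, sweeps, info, kind = fams[[1]]$kind)
  attr(out, "onset") <- attr(fams[[1]], "onset")
  attr(out, "duration") <- attr(fams[[1]], "duration")
  out
}

#' @export
print.nm_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<nm_cohort> %d neurons, condition %s (%s, %s), seed %s\n",
              nrow(x), spec$name, spec$age, spec$region,
              format(attr(x, "seed"))))
  NextMethod()
}
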