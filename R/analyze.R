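#' Analyze one neuron's sweep families
#'
#' Runs the full single-neuron pipeline: junction-corrected I-V curve from
#' the voltage-clamp family; per-bin differential conductance, normalized
#' open probability, Boltzmann fit, and integrated-I-V fit; fitted read-outs
#' at the standard comparison voltages; and, when current-clamp data are
#' present, the current threshold, averaged suprathreshold action-potential
#' features, and passive membrane properties.
#'
#' @param vclamp A voltage-clamp [sweep_family()].
#' @param cclamp Optional list with elements `passive` (trace), `search`
#'   (threshold-search family) and `supra` (suprathreshold family), as
#'   produced by [make_cohort()].
#' @param age `"E13"` or `"E20_21"` (selects the passive fit window).
#' @param bins List of the two [voltage_bin()]s.
#' @param detection [detection_settings()].
#' @return A list: `iv` (the I-V tibble), `fits` (per-bin `boltzmann_fit`
#'   objects, open-probability and integrated), and `features` (a one-row
#'   tibble of scalar per-neuron measures).
#' @export
analyze_neuron <- function(vclamp, cclamp = NULL, age = "E13",
                           bins = list(lva_bin(), hva_bin()),
                           detection = detection_settings()) {
  iv <- build_iv_curve(vclamp)
  ro <- readout_voltages()

  fits <- list()
  feat <- tibble(.rows = 1)
  for (bin in bins) {
    key <- tolower(bin$name)
    gc <- differential_conductance(iv, bin)
    po <- normalize_open_probability(gc)
    bf <- fit_boltzmann(po, bin)
    ivf <- fit_integrated_iv(iv, bin)
    fits[[paste0(key, "_po")]] <- bf
    fits[[paste0(key, "_iv")]] <- ivf
    feat[[paste0("gmax_", key, "_nS")]] <- ivf$estimate$g_max
    feat[[paste0("v50_", key, "_mV")]] <- ivf$estimate$v50
    feat[[paste0("k_", key, "_mV")]] <- ivf$estimate$k
    feat[[paste0("converged_", key)]] <- ivf$converged && bf$converged
    if (bin$name == "LVA") {
      r <- readout_at(ivf, ro[["lva"]])
      feat$g_lva_m42.5_nS <- r$g_nS
      feat$po_lva_m42.5 <- readout_at(bf, ro[["lva"]])$p_o
    } else {
      feat$po_hva_m2.5 <- readout_at(bf, ro[["hva_po"]])$p_o
      feat$g_hva_p17.5_nS <- readout_at(ivf, ro[["hva_g"]])$g_nS
    }
  }
  feat$i_m40_pA <- iv_current_at(iv, -40)
  feat$i_top_pA <- iv$i_pA[nrow(iv)]
  feat$v_top_mV <- iv$v_mV[nrow(iv)]

  if (!is.null(cclamp)) {
    pp <- passive_properties(cclamp$passive, age = age)
    feat <- dplyr::bind_cols(feat, pp[, c("tau_ms", "r_in_MOhm", "c_m_pF",
                                          "rmp_mV")])
    if (!is.null(cclamp$search)) {
      thr <- find_current_threshold(cclamp$search, detection)
      feat$i_t_pA <- thr$i_t
      feat$supra_pA <- thr$suprathreshold_pA
    }
    if (!is.null(cclamp$supra)) {
      ap <- tryCatch(
        mean_suprathreshold_features(cclamp$supra, detection = detection),
        error = function(e) NULL)
      if (!is.null(ap)) {
        feat$latency_ms <- ap$latency_ms
        feat$rise_rate <- ap$rise_rate
        feat$repol_rate <- ap$repol_rate
        feat$peak_mV <- ap$peak_mV
        feat$n_ap_reps <- ap$n_contributing
      }
    }
  }
  list(iv = iv, fits = fits, features = feat)
}

#' Analyze a simulated (or imported) cohort
#'
#' Applies [analyze_neuron()] to every neuron of an `nm_cohort` and collects
#' a tidy per-neuron feature table, applying the inclusion criteria
#' ([apply_inclusion()]).  Neurons whose sweep data cannot be analyzed are
#' kept in the table with NA features and a note, so one corrupted neuron
#' does not abort a cohort.
#'
#' @param cohort An `nm_cohort` from [make_cohort()] or [read_cohort()].
#' @param bins,detection See [analyze_neuron()].
#' @param keep_fits Attach the per-neuron fit objects as a list-column
#'   (default FALSE to keep the table light).
#' @return A tibble, one row per neuron: identifiers, measured features,
#'   `included` flag and `exclusion_reason`.
#' @export
analyze_cohort <- function(cohort, bins = list(lva_bin(), hva_bin()),
                           detection = detection_settings(),
                           keep_fits = FALSE) {
  stopifnot(inherits(cohort, "nm_cohort") || is.data.frame(cohort))
  rows <- vector("list", nrow(cohort))
  fit_col <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    res <- tryCatch(
      analyze_neuron(cohort$vclamp[[i]], cohort$cclamp[[i]],
                     age = cohort$age[i], bins = bins, detection = detection),
      error = function(e) e)
    meta <- tibble(
      neuron_id = cohort$neuron_id[i], embryo_id = cohort$embryo_id[i],
      condition = cohort$condition[i], age = cohort$age[i],
      region = cohort$region[i],
      series_resistance_MOhm = cohort$series_resistance_MOhm[i])
    if (inherits(res, "error")) {
      meta$analysis_note <- conditionMessage(res)
      rows[[i]] <- meta
    } else {
      meta$analysis_note <- NA_character_
      rows[[i]] <- dplyr::bind_cols(meta, res$features)
      fit_col[[i]] <- res$fits
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!"rmp_mV" %in% names(out)) {
    # no current clamp: gate on the generator's target RMP when available
    out$rmp_mV <- if ("rmp_target_mV" %in% names(cohort))
      cohort$rmp_target_mV else NA_real_
  }
  out <- apply_inclusion(out)
  if (keep_fits) out$fits <- fit_col
  out
}

#' Run the condition-comparison statistics battery
#'
#' For each stratum (age x region) and each requested metric, compares the
#' experimental groups: Welch's t-test when exactly two conditions are
#' present, the ANOVA battery (classic ANOVA with Bonferroni comparisons
#' plus Brown-Forsythe and Welch ANOVAs) when three or more are.  Neurons
#' failing the inclusion criteria are dropped first; the two-SD outlier rule
#' is applied per metric within each age x region x condition group (single
#' pass, when the group has at least 3 values).  Boltzmann read-out metrics
#' are compared exactly at the standard voltages because they are computed
#' that way upstream.
#'
#' @param features Per-neuron feature table from [analyze_cohort()] (rows
#'   from several conditions bound together).
#' @param metrics Character vector of feature columns to compare.
#' @param outlier_k SD multiplier of the outlier rule; `NULL` disables it.
#' @return A tibble with one row per stratum x metric: test name, statistic,
#'   dfs, p-value, stars, group summary and pairwise comparisons as nested
#'   list-columns.
#' @export
run_condition_battery <- function(features,
                                  metrics = c("g_lva_m42.5_nS",
                                              "po_hva_m2.5",
                                              "g_hva_p17.5_nS"),
                                  outlier_k = 2) {
  stopifnot(is.data.frame(features))
  if (!"included" %in% names(features)) features$included <- TRUE
  dat <- dplyr::filter(features, .data$included)
  if (nrow(dat) == 0L) abort("No included neurons to compare.")
  missing <- setdiff(metrics, names(dat))
  if (length(missing)) {
    abort(paste0("Metrics not present in the feature table: ",
                 paste(missing, collapse = ", "),
                 ". Available: ",
                 paste(setdiff(names(dat), c("neuron_id", "embryo_id")),
                       collapse = ", ")))
  }
  strata <- dplyr::distinct(dat, .data$age, .data$region)
  out <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- dplyr::filter(dat, .data$age == strata$age[s],
                         .data$region == strata$region[s])
    conds <- unique(sub$condition)
    if (length(conds) < 2L) {
      abort(sprintf("Stratum %s/%s has fewer than 2 conditions.",
                    strata$age[s], strata$region[s]))
    }
    for (metric in metrics) {
      groups <- purrr::map(setNames(conds, conds), function(cn) {
        x <- sub[[metric]][sub$condition == cn]
        x <- x[!is.na(x)]
        if (!is.null(outlier_k) && length(x) >= 3L) {
          exclude_outliers(x, k = outlier_k)$kept
        } else x
      })
      groups <- purrr::keep(groups, ~ length(.x) >= 2L)
      if (length(groups) < 2L) next
      if (length(groups) == 2L) {
        tst <- welch_t(groups[[1]], groups[[2]])
        anova_res <- NULL
      } else {
        anova_res <- anova_bonferroni(groups)
        tst <- bf_welch_anova(groups)
      }
      # normality is reported per group for transparency; it never gates
      # the choice of test
      shapiro <- purrr::imap_dfr(groups, function(x, nm) {
        p <- if (length(x) >= 3L && var(x) > 0) shapiro.test(x)$p.value
             else NA_real_
        tibble(group = nm, shapiro_p = p)
      })
      out[[length(out) + 1L]] <- tibble(
        age = strata$age[s], region = strata$region[s], metric = metric,
        test = tst$test, statistic = tst$statistic,
        df1 = tst$df[1], df2 = if (length(tst$df) > 1) tst$df[2] else NA_real_,
        p.value = tst$p_value, stars = tst$stars,
        groups = list(tst$groups),
        comparisons = list(tst$comparisons),
        anova = list(anova_res),
        brown_forsythe = list(tst$brown_forsythe %||% NULL),
        shapiro = list(shapiro)
      )
    }
  }
  dplyr::bind_rows(out)
}
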