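#' Write a cohort to a directory of flat files
#'
#' On-disk layout (one directory per cohort, inspectable and
#' language-portable): `neurons.csv` (per-neuron metadata),
#' `vclamp.csv` (long: neuron_id, sweep_id, command_mV, time_ms, current_pA),
#' `cclamp.csv` (long: neuron_id, family, amplitude_pA, rep, sweep_id,
#' time_ms, voltage_mV; absent for voltage-clamp-only cohorts),
#' `ground_truth.json` (per-neuron generator parameters), and
#' `manifest.json` (protocol, condition spec, seed, package version).
#'
#' @param cohort An `nm_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dplyr::select(as_tibble(cohort), -dplyr::any_of(c("params", "vclamp",
                                                           "cclamp")))
  write.csv(meta, file.path(dir, "neurons.csv"), row.names = FALSE)

  vc <- purrr::map2_dfr(cohort$neuron_id, cohort$vclamp, function(id, fam) {
    d <- tidy(fam)
    d$neuron_id <- id
    d
  })
  write.csv(vc, file.path(dir, "vclamp.csv"), row.names = FALSE)

  if (any(!vapply(cohort$cclamp, is.null, logical(1)))) {
    cc <- purrr::map2_dfr(cohort$neuron_id, cohort$cclamp, function(id, fams) {
      if (is.null(fams)) return(NULL)
      purrr::imap_dfr(purrr::compact(fams), function(fam, nm) {
        if (is.data.frame(fam)) {  # passive single trace
          tibble(family = nm, amplitude_pA = attr(fam, "amplitude"),
                 rep = 1L, sweep_id = 1L,
                 time_ms = fam$time_ms, voltage_mV = fam$voltage_mV)
        } else {
          d <- tidy(fam)
          d$family <- nm
          d
        }
      }) |> dplyr::mutate(neuron_id = id)
    })
    write.csv(cc, file.path(dir, "cclamp.csv"), row.names = FALSE)
  }

  truth <- purrr::map2(cohort$neuron_id, cohort$params,
                       function(id, p) unclass(p))
  names(truth) <- cohort$neuron_id
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  spec <- attr(cohort, "spec")
  proto <- cohort$vclamp[[1]]$protocol
  manifest <- list(
    package = "nmephys",
    version = as.character(utils::packageVersion("nmephys")),
    seed = attr(cohort, "seed"),
    condition = unclass(spec),
    vclamp_protocol = unclass(proto)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `nm_cohort` equivalent to the one written (ground-truth
#'   parameters, sweep families, metadata, seed).
#' @export
read_cohort <- function(dir) {
  for (f in c("neurons.csv", "vclamp.csv", "manifest.json")) {
    if (!file.exists(file.path(dir, f))) {
      abort(sprintf("Malformed cohort directory: missing %s.", f))
    }
  }
  meta <- as_tibble(read.csv(file.path(dir, "neurons.csv")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  pr <- manifest$vclamp_protocol
  proto <- vclamp_protocol(levels = unlist(pr$levels), holding = pr$holding,
                           duration = pr$duration, ljp = pr$ljp,
                           sampling_interval = pr$sampling_interval)
  proto$ljp_corrected <- isTRUE(pr$ljp_corrected)

  truth <- NULL
  if (file.exists(file.path(dir, "ground_truth.json"))) {
    truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  }

  vc_long <- read.csv(file.path(dir, "vclamp.csv"))
  cc_long <- if (file.exists(file.path(dir, "cclamp.csv"))) {
    read.csv(file.path(dir, "cclamp.csv"))
  } else NULL

  rebuild_family <- function(d, info_cols, kind) {
    value_col <- if (kind == "current") "current_pA" else "voltage_mV"
    d <- d[order(d$sweep_id, d$time_ms), ]
    ids <- unique(d$sweep_id)
    time_ms <- d$time_ms[d$sweep_id == ids[1]]
    sweeps <- vapply(ids, function(s) d[[value_col]][d$sweep_id == s],
                     numeric(length(time_ms)))
    info <- dplyr::distinct(dplyr::select(
      as_tibble(d), dplyr::all_of(c(info_cols, "sweep_id"))))
    info <- dplyr::select(info[match(ids, info$sweep_id), ], -"sweep_id")
    sweep_family(time_ms, sweeps, info, kind = kind)
  }

  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$neuron_id[i]
    fam <- rebuild_family(vc_long[vc_long$neuron_id == id, ],
                          "command_mV", "current")
    fam$protocol <- proto
    p <- NULL
    if (!is.null(truth[[id]])) {
      tp <- truth[[id]]
      p <- channel_params(g_leak = tp$g_leak, e_leak = tp$e_leak,
                          e_k = tp$e_k, c_m = tp$c_m,
                          lva = tp$lva, hva = tp$hva, spike = tp$spike,
                          noise_sd_current = tp$noise_sd_current,
                          noise_sd_voltage = tp$noise_sd_voltage)
    }
    cc <- NULL
    if (!is.null(cc_long)) {
      sub <- cc_long[cc_long$neuron_id == id, ]
      if (nrow(sub) > 0) {
        cc <- list(passive = NULL, search = NULL, supra = NULL)
        for (nm in intersect(c("passive", "search", "supra"),
                             unique(sub$family))) {
          ssub <- sub[sub$family == nm, ]
          if (nm == "passive") {
            tr <- tibble(time_ms = ssub$time_ms, voltage_mV = ssub$voltage_mV)
            attr(tr, "onset") <- 20; attr(tr, "duration") <- 100
            attr(tr, "amplitude") <- ssub$amplitude_pA[1]
            cc$passive <- tr
          } else {
            f <- rebuild_family(ssub, c("amplitude_pA", "rep"), "voltage")
            attr(f, "onset") <- 20; attr(f, "duration") <- 100
            cc[[nm]] <- f
          }
        }
      }
    }
    rows[[i]] <- tibble(params = list(p), vclamp = list(fam),
                        cclamp = list(cc))
  }
  out <- dplyr::bind_cols(meta, dplyr::bind_rows(rows))
  class(out) <- c("nm_cohort", class(out))
  spec_l <- manifest$condition
  spec <- condition_spec(name = spec_l$name, age = spec_l$age,
                         region = spec_l$region,
                         scale_lva = spec_l$scale_lva,
                         scale_hva = spec_l$scale_hva,
                         rmp_mean = spec_l$rmp_mean, rmp_sd = spec_l$rmp_sd,
                         n_neurons = spec_l$n_neurons,
                         cv = spec_l$cv)
  attr(out, "spec") <- spec
  attr(out, "seed") <- manifest$seed
  out
}

#' Export per-neuron fit results as a tidy table
#'
#' One row per neuron x bin x method with the Boltzmann parameters, their
#' standard errors, convergence flag and residual RMS; suitable for CSV
#' export and for the group statistics.
#'
#' @param features Feature table from [analyze_cohort()] with
#'   `keep_fits = TRUE`.
#' @return A tibble.
#' @export
fits_table <- function(features) {
  if (!"fits" %in% names(features)) {
    abort("Run analyze_cohort(..., keep_fits = TRUE) to retain fit objects.")
  }
  purrr::map2_dfr(features$neuron_id, features$fits, function(id, fl) {
    if (is.null(fl)) return(NULL)
    purrr::imap_dfr(fl, function(f, nm) {
      tibble(neuron_id = id, fit = nm, bin = f$bin$name, method = f$method,
             b = f$estimate$b, v50_mV = f$estimate$v50, k_mV = f$estimate$k,
             g_max_nS = f$estimate$g_max, c_int_pA = f$estimate$c_int,
             se_v50 = f$se$v50, se_k = f$se$k, se_g_max = f$se$g_max,
             converged = f$converged, residual_rms = f$residual_rms)
    })
  })
}
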