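#' Simulate condition cohorts and write them to disk
#'
#' Batch entry point binding the generator to the on-disk format: simulates
#' one cohort per condition preset and writes each to
#' `<out>/<condition>/` via [write_cohort()].
#'
#' @param conditions Character vector of [nm_condition()] preset names, or a
#'   list of [condition_spec()] objects.
#' @param out Output directory.
#' @param base Base [channel_params()].
#' @param seed Root seed; per-condition seeds are derived deterministically.
#' @param include_cclamp Simulate current-clamp protocols too.
#' @param quiet Suppress the per-cohort summary lines.
#' @return Invisibly, a tibble summarising the written cohorts.
#' @export
run_simulate <- function(conditions = c("control", "BDNF"), out,
                         base = channel_params(), seed = 1,
                         include_cclamp = TRUE, quiet = FALSE) {
  specs <- if (is.character(conditions)) {
    purrr::map(conditions, nm_condition)
  } else conditions
  rows <- purrr::imap(specs, function(spec, k) {
    stopifnot(inherits(spec, "condition_spec"))
    cohort <- make_cohort(spec, base = base, seed = seed + 131L * k,
                          include_cclamp = include_cclamp)
    dir <- file.path(out, spec$name)
    write_cohort(cohort, dir)
    if (!quiet) {
      message(sprintf("wrote %s: %d neurons (%s, %s)", dir,
                      nrow(cohort), spec$age, spec$region))
    }
    tibble(condition = spec$name, n_neurons = nrow(cohort), dir = dir)
  })
  invisible(dplyr::bind_rows(rows))
}

#' Analyze cohorts on disk and write tidy feature/fit tables
#'
#' Reads every cohort directory under `in_dir`, runs [analyze_cohort()],
#' and writes `features.csv` (per-neuron features, inclusion flags and
#' exclusion reasons) and `fits.csv` (per-neuron Boltzmann parameters)
#' under `out`.  Neurons that fail analysis are retained with a note.
#'
#' @param in_dir Directory containing cohort subdirectories from
#'   [run_simulate()], or a single cohort directory.
#' @param out Output directory for the tables.
#' @param quiet Suppress progress and exclusion-audit messages.
#' @return The combined feature table, invisibly.
#' @export
run_analyze <- function(in_dir, out, quiet = FALSE) {
  dirs <- if (file.exists(file.path(in_dir, "neurons.csv"))) {
    in_dir
  } else {
    subs <- list.dirs(in_dir, recursive = FALSE)
    subs[file.exists(file.path(subs, "neurons.csv"))]
  }
  if (length(dirs) == 0L) abort("No cohort directories found.")
  feats <- purrr::map_dfr(dirs, function(d) {
    cohort <- read_cohort(d)
    analyze_cohort(cohort, keep_fits = TRUE)
  })
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.csv(dplyr::select(feats, -dplyr::any_of("fits")),
            file.path(out, "features.csv"), row.names = FALSE)
  ft <- fits_table(feats)
  write.csv(ft, file.path(out, "fits.csv"), row.names = FALSE)
  if (!quiet) {
    excl <- dplyr::filter(feats, !.data$included)
    for (i in seq_len(nrow(excl))) {
      message(sprintf("excluded %s: %s", excl$neuron_id[i],
                      excl$exclusion_reason[i]))
    }
    message(sprintf("analyzed %d neurons (%d included) -> %s",
                    nrow(feats), sum(feats$included), out))
  }
  invisible(feats)
}

#' Run the statistics battery on a feature table and write the report
#'
#' @param features Feature table (tibble or path to `features.csv`).
#' @param out Output directory; writes `stats.csv` (flat results) and
#'   `stats.json` (full report with group summaries and pairwise
#'   comparisons).
#' @param metrics Metrics to compare (see [run_condition_battery()]).
#' @param quiet Suppress the star-coded summary lines.
#' @return The battery result tibble, invisibly.
#' @export
run_stats <- function(features, out,
                      metrics = c("g_lva_m42.5_nS", "po_hva_m2.5",
                                  "g_hva_p17.5_nS"),
                      quiet = FALSE) {
  if (is.character(features)) {
    features <- as_tibble(read.csv(features))
  }
  res <- run_condition_battery(features, metrics = metrics)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  flat <- dplyr::select(res, -dplyr::any_of(c("groups", "comparisons",
                                              "anova", "brown_forsythe",
                                              "shapiro")))
  write.csv(flat, file.path(out, "stats.csv"), row.names = FALSE)
  report <- purrr::map(seq_len(nrow(res)), function(i) {
    list(age = res$age[i], region = res$region[i], metric = res$metric[i],
         test = res$test[i], statistic = res$statistic[i],
         df = c(res$df1[i], res$df2[i]), p_value = res$p.value[i],
         stars = res$stars[i],
         groups = res$groups[[i]],
         comparisons = res$comparisons[[i]],
         brown_forsythe = res$brown_forsythe[[i]],
         shapiro = res$shapiro[[i]])
  })
  jsonlite::write_json(report, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!quiet) {
    for (i in seq_len(nrow(res))) {
      message(sprintf("%-18s %s/%s  %s  p = %.3g  %s", res$metric[i],
                      res$age[i], res$region[i], res$test[i],
                      res$p.value[i], res$stars[i]))
    }
  }
  invisible(res)
}
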