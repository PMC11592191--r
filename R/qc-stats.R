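#' Apply per-neuron inclusion criteria
#'
#' A neuron is included when its resting membrane potential is more
#' hyperpolarized than the age-specific cut-off (below -50 mV for E13,
#' below -55 mV for E20-21) and its series resistance does not exceed
#' 10 MOhm.  Exclusion reasons are recorded.  Works on a per-neuron feature
#' table (one row per neuron) with columns `rmp_mV`, `series_resistance_MOhm`
#' and `age`.
#'
#' @param records A tibble with columns `rmp_mV`, `series_resistance_MOhm`,
#'   `age` (values `"E13"` or `"E20_21"`).
#' @param rs_max Series-resistance cut-off, MOhm.
#' @return The input with logical `included` and character
#'   `exclusion_reason` (NA when included) columns added/replaced.
#' @export
apply_inclusion <- function(records, rs_max = 10) {
  need <- c("rmp_mV", "series_resistance_MOhm", "age")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("Missing QC columns: ", paste(missing, collapse = ", ")))
  }
  if (any(!records$age %in% c("E13", "E20_21"))) {
    abort("`age` must be 'E13' or 'E20_21'.")
  }
  cutoff <- ifelse(records$age == "E13", -50, -55)
  rmp_ok <- records$rmp_mV < cutoff
  rs_ok <- records$series_resistance_MOhm <= rs_max
  reason <- dplyr::case_when(
    !rmp_ok & !rs_ok ~ "rmp; series_resistance",
    !rmp_ok ~ "rmp",
    !rs_ok ~ "series_resistance",
    TRUE ~ NA_character_
  )
  dplyr::mutate(records, included = rmp_ok & rs_ok, exclusion_reason = reason)
}

#' Two-standard-deviation outlier rule
#'
#' Single-pass rule: the mean and sample SD are computed once on the full
#' set, and values more than `k` SDs from the mean are excluded.  The rule is
#' not iterated.  Intended to be applied per metric within each
#' age x region x condition group.
#'
#' @param values Numeric vector, length >= 3.
#' @param k SD multiplier (default 2).
#' @return List with `kept` and `excluded` (both subsets of `values`, order
#'   preserved) and logical `keep` mask.
#' @export
exclude_outliers <- function(values, k = 2) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) abort("Need at least 3 values for the outlier rule.")
  m <- mean(values)
  s <- sd(values)
  keep <- if (s == 0) rep(TRUE, length(values)) else abs(values - m) <= k * s
  list(kept = values[keep], excluded = values[!keep], keep = keep)
}

stars_for <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

new_ephys_test <- function(test, statistic, df, p_value, groups,
                           comparisons = NULL, note = NULL) {
  structure(
    list(test = test, statistic = statistic, df = df, p_value = p_value,
         groups = groups, comparisons = comparisons,
         stars = stars_for(p_value), note = note),
    class = "ephys_test"
  )
}

#' @export
print.ephys_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("<ephys_test> %s: statistic = %.4g, df = %s, p = %.4g %s\n",
              x$test, x$statistic, dfs, x$p_value, x$stars))
  print(x$groups)
  if (!is.null(x$comparisons)) {
    cat("pairwise comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' @export
tidy.ephys_test <- function(x, ...) {
  if (!is.null(x$comparisons)) return(x$comparisons)
  tibble(test = x$test, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p.value = x$p_value, stars = x$stars)
}

#' @export
glance.ephys_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic,
         df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p.value = x$p_value, stars = x$stars)
}

group_summary <- function(groups) {
  tibble(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, sd, numeric(1)),
    sem = vapply(groups, function(g) sd(g) / sqrt(length(g)), numeric(1))
  )
}

check_groups <- function(groups, min_k) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (length(groups) < min_k) {
    abort(sprintf("Need at least %d groups.", min_k))
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    abort("Each group needs at least 2 values.")
  }
  if (all(vapply(groups, var, numeric(1)) == 0)) {
    abort("All groups have zero variance; the test is degenerate.")
  }
  groups
}

#' Welch's unpaired t-test
#'
#' Two-sided unpaired t-test with Welch's correction (unequal variances,
#' Welch-Satterthwaite degrees of freedom), the standard two-group
#' comparison for electrophysiological features.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @return An `ephys_test` with statistic, df, p, and group summaries.
#' @export
welch_t <- function(a, b) {
  g <- check_groups(list(a = a, b = b), 2L)
  ht <- t.test(g$a, g$b, var.equal = FALSE)
  new_ephys_test("welch_t", unname(ht$statistic), unname(ht$parameter),
                 ht$p.value, group_summary(g))
}

#' One-way ANOVA with Bonferroni pairwise comparisons
#'
#' Classic (equal-variance) one-way ANOVA for three or more groups, followed
#' by all-pairs Welch t comparisons with Bonferroni adjustment (raw p times
#' the number of comparisons, capped at 1).  Set `reference` to restrict the
#' comparison family to contrasts against one group.
#'
#' @param groups Named list of numeric vectors (>= 3 groups, n >= 2 each).
#' @param reference Optional group name; when given, only
#'   reference-vs-other comparisons form the Bonferroni family.
#' @return An `ephys_test`; `$comparisons` holds the adjusted pairwise table.
#' @export
anova_bonferroni <- function(groups, reference = NULL) {
  g <- check_groups(groups, 3L)
  values <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), vapply(g, length, integer(1))),
                levels = names(g))
  ow <- oneway.test(values ~ fac, var.equal = TRUE)
  comp <- pairwise_welch(g, reference)
  new_ephys_test("anova_bonferroni", unname(ow$statistic),
                 unname(ow$parameter), ow$p.value, group_summary(g),
                 comparisons = comp)
}

pairwise_welch <- function(g, reference = NULL) {
  pairs <- utils::combn(names(g), 2, simplify = FALSE)
  if (!is.null(reference)) {
    if (!reference %in% names(g)) abort("`reference` is not a group name.")
    pairs <- purrr::keep(pairs, ~ reference %in% .x)
  }
  m <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    ht <- t.test(g[[pr[1]]], g[[pr[2]]], var.equal = FALSE)
    tibble(group1 = pr[1], group2 = pr[2],
           statistic = unname(ht$statistic), df = unname(ht$parameter),
           p.value = ht$p.value,
           p.adj = min(1, ht$p.value * m))
  }) |>
    dplyr::mutate(stars = stars_for(.data$p.adj))
}

#' Brown-Forsythe and Welch ANOVAs
#'
#' Heteroscedasticity-robust one-way ANOVAs for three or more groups:
#' the Welch ANOVA (W statistic with Welch-Satterthwaite denominator df) and
#' the Brown-Forsythe ANOVA for means,
#' \deqn{F^* = \frac{\sum_i n_i(\bar x_i - \bar x)^2}
#'                  {\sum_i (1 - n_i/N)\, s_i^2},}
#' with Satterthwaite-approximated denominator degrees of freedom.  Pairwise
#' Welch t comparisons with Bonferroni adjustment are attached.
#'
#' @inheritParams anova_bonferroni
#' @return An `ephys_test` (test = `"bf_welch_anova"`): `$statistic` and
#'   `$p_value` are the Welch ANOVA's; `$brown_forsythe` holds the F*,
#'   df pair, and p of the Brown-Forsythe test.
#' @export
bf_welch_anova <- function(groups, reference = NULL) {
  g <- check_groups(groups, 3L)
  values <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), vapply(g, length, integer(1))),
                levels = names(g))
  wl <- oneway.test(values ~ fac, var.equal = FALSE)

  n <- vapply(g, length, numeric(1))
  s2 <- vapply(g, var, numeric(1))
  m <- vapply(g, mean, numeric(1))
  N <- sum(n)
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  den_terms <- (1 - n / N) * s2
  f_star <- num / sum(den_terms)
  ci <- den_terms / sum(den_terms)
  df2 <- 1 / sum(ci^2 / (n - 1))
  df1 <- length(g) - 1
  p_bf <- pf(f_star, df1, df2, lower.tail = FALSE)

  out <- new_ephys_test("bf_welch_anova", unname(wl$statistic),
                        unname(wl$parameter), wl$p.value, group_summary(g),
                        comparisons = pairwise_welch(g, reference))
  out$brown_forsythe <- list(statistic = f_star, df = c(df1, df2),
                             p_value = p_bf)
  out
}

#' Shapiro-Wilk normality check
#'
#' Reported alongside the battery for transparency; it does not gate the
#' choice of test.
#'
#' @param values Numeric vector (3 <= n <= 5000).
#' @return An `ephys_test`.
#' @export
shapiro_wilk <- function(values) {
  ht <- shapiro.test(values)
  new_ephys_test("shapiro_wilk", unname(ht$statistic), NA_real_, ht$p.value,
                 tibble(group = "all", n = length(values),
                        mean = mean(values), sd = sd(values),
                        sem = sd(values) / sqrt(length(values))))
}
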