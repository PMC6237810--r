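#' Classical two-sample Student's t-test
#'
#' Equal-variance (pooled) two-sided t-test, the closed-form used for
#' repair-experiment statistics:
#' `t = (mean_a - mean_b) / sqrt(sp2 * (1/n_a + 1/n_b))` with the pooled
#' variance `sp2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)`.
#' Degenerate input with zero pooled variance gives `t = 0, p = 1` when
#' the means are equal and is an error otherwise.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param alpha significance level for the `significant` flag.
#' @param fraction optional fraction name carried into the result.
#' @param groups optional length-2 labels for the compared groups.
#' @return an object of class `nla_ttest`: `statistic`, `df`, `p_value`,
#'   `significant`, `fraction`, `groups`.
#' @export
students_t <- function(group_a, group_b, alpha = 0.05, fraction = NA_character_,
                       groups = c("a", "b")) {
  na <- length(group_a); nb <- length(group_b)
  assert_that(na >= 2L && nb >= 2L, "each group needs >= 2 observations")
  assert_that(all(is.finite(group_a)) && all(is.finite(group_b)),
              "non-finite observations")
  ma <- mean(group_a); mb <- mean(group_b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  if (sp2 == 0) {
    assert_that(ma == mb,
                "zero pooled variance with unequal means: t undefined")
    t_stat <- 0; p <- 1
  } else {
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(statistic = t_stat, df = df, p_value = p,
                 significant = p < alpha, alpha = alpha,
                 fraction = fraction, groups = groups),
            class = "nla_ttest")
}

#' @export
print.nla_ttest <- function(x, ...) {
  cat(sprintf("Student's t: t = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha)
              else ""))
  invisible(x)
}

fractions_to_wide <- function(report) {
  stats::setNames(report$percentage, report$region)
}

#' Summarize a dose-response series of fraction reports
#'
#' Per-fraction mean and sd versus dose, plus the Spearman rank
#' correlation of each damage fraction (and of the combined
#' behind + front crosslink signal) with dose. Replicate reports at the
#' same dose are supported; fully tied (constant) fractions get rho = 0.
#'
#' @param doses numeric vector of doses, one per report (>= 3 distinct
#'   doses required).
#' @param reports list of `nla_fractions` reports of the same length.
#' @return list with `table` (dose x fraction mean/sd, long format) and
#'   `spearman` (named rho vector over fractions plus
#'   `behind_plus_front`).
#' @export
summarize_dose_response <- function(doses, reports) {
  assert_that(length(doses) == length(reports),
              "one dose per report required")
  assert_that(length(unique(doses)) >= 3L, "need >= 3 distinct doses")
  wide <- do.call(rbind, lapply(reports, fractions_to_wide))
  long <- do.call(rbind, lapply(colnames(wide), function(fr) {
    agg_m <- tapply(wide[, fr], doses, mean)
    agg_s <- tapply(wide[, fr], doses, stats::sd)
    data.frame(fraction = fr, dose = as.numeric(names(agg_m)),
               mean = as.numeric(agg_m), sd = as.numeric(agg_s),
               stringsAsFactors = FALSE)
  }))
  rho_of <- function(v) {
    if (stats::sd(v) == 0) return(0)  # fully tied: no rank trend
    suppressWarnings(stats::cor(doses, v, method = "spearman"))
  }
  rho <- vapply(colnames(wide), function(fr) rho_of(wide[, fr]), 0)
  rho <- c(rho, behind_plus_front = rho_of(wide[, "behind"] +
                                             wide[, "front"]))
  list(table = long, spearman = rho)
}

#' Compile a repair-experiment report
#'
#' For each DNA fraction and each pair of conditions, an equal-variance
#' Student's t-test over replicate percentages, flagged at `alpha` (0.05
#' by default, the usual P < 0.05 convention; no multiple-testing
#' correction unless `bonferroni = TRUE`).
#'
#' @param experiment named list: one element per condition (e.g. `"0h"`,
#'   `"24h"`, `"48h"`), each a list of replicate `nla_fractions` reports
#'   (>= 2 replicates per condition).
#' @param alpha significance level.
#' @param bonferroni apply a Bonferroni correction across all tests.
#' @return list of class `nla_report`: `fractions` (condition x region
#'   mean/sd table) and `tests` (one row per fraction per condition
#'   pair).
#' @export
compile_report <- function(experiment, alpha = 0.05, bonferroni = FALSE) {
  conds <- names(experiment)
  assert_that(!is.null(conds) && all(nzchar(conds)),
              "experiment conditions must be named")
  assert_that(all(vapply(experiment, length, 0L) >= 2L),
              "need >= 2 replicates per condition")
  wide <- lapply(experiment, function(reps)
    do.call(rbind, lapply(reps, fractions_to_wide)))
  fractions <- do.call(rbind, lapply(conds, function(cd)
    do.call(rbind, lapply(colnames(wide[[cd]]), function(fr)
      data.frame(condition = cd, fraction = fr,
                 mean = mean(wide[[cd]][, fr]),
                 sd = stats::sd(wide[[cd]][, fr]),
                 n = nrow(wide[[cd]]), stringsAsFactors = FALSE)))))
  pairs <- if (length(conds) >= 2L) utils::combn(conds, 2L, simplify = FALSE)
           else list()
  frs <- colnames(wide[[1]])
  n_tests <- length(pairs) * length(frs)
  a_eff <- if (bonferroni && n_tests > 0) alpha / n_tests else alpha
  tests <- do.call(rbind, lapply(pairs, function(pr)
    do.call(rbind, lapply(frs, function(fr) {
      tt <- students_t(wide[[pr[1]]][, fr], wide[[pr[2]]][, fr],
                       alpha = a_eff, fraction = fr, groups = pr)
      data.frame(fraction = fr, group_a = pr[1], group_b = pr[2],
                 t = tt$statistic, df = tt$df, p_value = tt$p_value,
                 significant = tt$significant, stringsAsFactors = FALSE)
    }))))
  structure(list(fractions = fractions,
                 tests = tests %||% data.frame(),
                 alpha = alpha, bonferroni = bonferroni),
            class = "nla_report")
}

#' Write a compiled report to CSV/JSON (and optional Markdown)
#'
#' @param report an `nla_report`.
#' @param prefix output path prefix; writes `<prefix>_fractions.csv`,
#'   `<prefix>_tests.csv`, `<prefix>.json` and optionally `<prefix>.md`.
#' @param markdown also emit a Markdown summary.
#' @export
write_report <- function(report, prefix, markdown = FALSE) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$fractions, paste0(prefix, "_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, paste0(prefix, "_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(fractions = report$fractions,
                            tests = report$tests, alpha = report$alpha),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (markdown) {
    lines <- c("# NLA repair report", "",
               "## Fraction percentages (mean +/- sd)", "",
               utils::capture.output(print(report$fractions)), "",
               "## Student's t-tests", "",
               utils::capture.output(print(report$tests)))
    writeLines(lines, paste0(prefix, ".md"))
  }
  invisible(prefix)
}
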