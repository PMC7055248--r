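## Full behavioural analysis chain on a cohort: preprocessing, lag
## estimation and aggregation, ANOVA, post-hocs, and ratings tests.

#' Analyze a behavioural cohort
#'
#' Runs the complete analysis chain on a cohort directory or an
#' in-memory cohort (as returned by [generate_cohort()]): averages the
#' four non-thumb finger channels per trial, estimates per-trial phase
#' lags with the CWT estimator, aggregates them per participant and
#' condition, fits the 2 x 2 repeated-measures ANOVA (on both the
#' real-hand and the virtual-hand lag) with Bonferroni post-hoc paired
#' t-tests, and, when ratings are present, the Friedman and pairwise
#' Wilcoxon tests per question.
#'
#' @param cohort a cohort directory path, or a list with `trials`,
#'   `manifest` and optionally `ratings`.
#' @return object of class `"phasematch_analysis"`: a list with
#'   `lag_table`, `anova` (per dependent), `posthoc`, `ratings_tests`
#'   (or NULL), and `manifest`.
#' @export
analyze_cohort <- function(cohort) {
  ratings <- NULL
  if (is.character(cohort)) {
    dat <- read_cohort_dir(cohort)
    rpath <- file.path(cohort, "ratings.csv")
    if (file.exists(rpath)) ratings <- utils::read.csv(rpath)
    trials <- dat$trials
    manifest <- dat$manifest
  } else {
    trials <- cohort$trials
    manifest <- cohort$manifest
    ratings <- cohort$ratings
  }
  lag_table <- aggregate_lags(trials, manifest)
  anova <- list(lag_real = rm_anova_2x2(lag_table, "lag_real"),
                lag_virtual = rm_anova_2x2(lag_table, "lag_virtual"))
  posthoc <- posthoc_paired_tests(lag_table, dependent = "lag_real")
  ratings_tests <- NULL
  if (!is.null(ratings)) {
    ratings_tests <- lapply(c(Q1 = "Q1", Q2 = "Q2"), function(q)
      list(friedman = friedman_test(ratings, q),
           wilcoxon = tryCatch(wilcoxon_pairs(ratings, q),
                               error = function(e) {
                                 warning("Wilcoxon skipped for ", q, ": ",
                                         conditionMessage(e), call. = FALSE)
                                 NULL
                               })))
  } else {
    warning("no ratings table: reporting ANOVA and post-hocs only",
            call. = FALSE)
  }
  structure(list(lag_table = lag_table, anova = anova, posthoc = posthoc,
                 ratings_tests = ratings_tests, manifest = manifest),
            class = "phasematch_analysis")
}

#' @export
print.phasematch_analysis <- function(x, ...) {
  n <- length(unique(x$lag_table$participant))
  cat(sprintf("Behavioural cohort analysis: %d participants x 4 conditions\n",
              n))
  means <- stats::aggregate(cbind(lag_real, lag_virtual) ~ condition,
                            data = x$lag_table, FUN = mean)
  cat("Condition mean lags (s):\n")
  print(cbind(means["condition"], round(means[-1L], 4)), row.names = FALSE)
  a <- x$anova$lag_real
  cat("RM-ANOVA on real-hand lag:\n")
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-12s F(%d,%d) = %.2f, p = %.3g\n", a$effect[i],
                a$df1[i], a$df2[i], a$F[i], a$p[i]))
  if (!is.null(x$ratings_tests)) {
    for (q in names(x$ratings_tests)) {
      fr <- x$ratings_tests[[q]]$friedman
      cat(sprintf("Friedman %s: chi2(%d) = %.2f, p = %.3g\n", q, fr$df,
                  fr$chi2, fr$p))
    }
  }
  invisible(x)
}

#' @export
summary.phasematch_analysis <- function(object, ...) {
  print(object, ...)
  cat("Post-hoc paired t-tests (real-hand lag, Bonferroni):\n")
  ph <- object$posthoc
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  %-24s t(%d) = %.2f, corrected p = %.3g\n",
                ph$comparison[i], ph$df[i], ph$t[i], ph$p_corrected[i]))
  invisible(object)
}
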