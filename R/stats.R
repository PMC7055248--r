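## Within-subject statistics of the behavioural analysis: 2x2
## repeated-measures ANOVA, Bonferroni-corrected paired t-tests, and the
## nonparametric Friedman / Wilcoxon chain for the ratings.

lag_table_matrix <- function(table, dependent) {
  stopifnot(dependent %in% c("lag_real", "lag_virtual"))
  tab <- table[!is.na(table[[dependent]]), , drop = FALSE]
  wide <- stats::reshape(
    tab[, c("participant", "condition", dependent)],
    idvar = "participant", timevar = "condition", direction = "wide")
  need <- paste(dependent, c("vh_cong", "rh_cong", "vh_incong", "rh_incong"),
                sep = ".")
  if (!all(need %in% names(wide)) || anyNA(wide[, need]))
    stop("incomplete crossed design: every participant needs all 4 conditions",
         call. = FALSE)
  m <- as.matrix(wide[, need])
  colnames(m) <- sub(paste0(dependent, "."), "", colnames(m), fixed = TRUE)
  rownames(m) <- wide$participant
  m
}

#' 2 x 2 repeated-measures ANOVA on a lag table
#'
#' Within-subject ANOVA with factors task (VH, RH) and congruence (cong,
#' incong) on the chosen dependent lag, fitted with [stats::aov()] and
#' participant-level error strata.  Because both factors have two levels,
#' every F statistic equals the squared paired t of the corresponding
#' contrast; this identity is computed as a built-in self-check and a
#' mismatch beyond 1e-8 raises an error.
#'
#' @param table a `"lag_table"` (see [aggregate_lags()]).
#' @param dependent `"lag_real"` or `"lag_virtual"`.
#' @return data frame of class `"rm_anova"`: one row per effect (task,
#'   congruence, interaction) with `F`, `df1`, `df2`, `p`, and the
#'   contrast `t` of the self-check.
#' @export
rm_anova_2x2 <- function(table, dependent = c("lag_real", "lag_virtual")) {
  dependent <- match.arg(dependent)
  m <- lag_table_matrix(table, dependent)
  long <- data.frame(
    participant = factor(rep(rownames(m), 4L)),
    task = factor(rep(c("VH", "RH", "VH", "RH"), each = nrow(m))),
    congruence = factor(rep(c("cong", "cong", "incong", "incong"),
                            each = nrow(m))),
    y = as.vector(m))
  fit <- stats::aov(y ~ task * congruence +
                      Error(participant / (task * congruence)), data = long)
  s <- summary(fit)
  pick <- function(stratum, term) {
    tab <- s[[stratum]][[1L]]
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"])
  }
  res <- rbind(task = pick("Error: participant:task", "task"),
               congruence = pick("Error: participant:congruence",
                                 "congruence"),
               interaction = pick("Error: participant:task:congruence",
                                  "task:congruence"))
  ## paired-contrast self-check: each effect is a paired t on a contrast
  contrasts <- list(
    task = (m[, "vh_cong"] + m[, "vh_incong"] -
              m[, "rh_cong"] - m[, "rh_incong"]) / 2,
    congruence = (m[, "vh_incong"] + m[, "rh_incong"] -
                    m[, "vh_cong"] - m[, "rh_cong"]) / 2,
    interaction = (m[, "vh_incong"] - m[, "vh_cong"]) -
      (m[, "rh_incong"] - m[, "rh_cong"]))
  tval <- vapply(contrasts, function(d) {
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 0 else Inf)
    mean(d) / (stats::sd(d) / sqrt(length(d)))
  }, numeric(1L))
  ## zero-variance contrasts make aov report NaN (or rounding noise);
  ## the contrast view is exact there (no effect, no error variance)
  degen <- !is.finite(res[, "F"]) |
    vapply(contrasts, stats::sd, numeric(1L)) == 0
  res[degen, "F"] <- tval[degen]^2
  res[degen, "p"] <- ifelse(tval[degen] == 0, 1, 0)
  bad <- abs(res[, "F"] - tval^2) > 1e-8 * pmax(1, abs(res[, "F"]))
  if (any(bad[is.finite(res[, "F"])], na.rm = TRUE))
    stop("internal self-check failed: F != t^2 for ",
         paste(rownames(res)[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(effect = rownames(res), res, t = tval,
                    row.names = NULL, check.names = FALSE)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Post-hoc paired t-tests with Bonferroni correction
#'
#' Two-tailed paired t-tests between named conditions; p-values are
#' multiplied by the number of comparisons and capped at 1.  A pair with
#' zero difference variance is flagged `degenerate` (t infinite when the
#' mean difference is nonzero, 0 otherwise).
#'
#' @param table a `"lag_table"`.
#' @param comparisons list of length-2 character vectors of condition
#'   names; default: the four standard pairwise comparisons (congruence
#'   within task, task within congruence).
#' @param dependent `"lag_real"` or `"lag_virtual"`.
#' @param correction only `"bonferroni"` is implemented.
#' @return data frame: one row per comparison with `t`, `df`, `p`,
#'   `p_corrected`, `degenerate`.
#' @export
posthoc_paired_tests <- function(table,
                                 comparisons = list(
                                   c("vh_cong", "vh_incong"),
                                   c("rh_cong", "rh_incong"),
                                   c("vh_cong", "rh_cong"),
                                   c("vh_incong", "rh_incong")),
                                 dependent = c("lag_real", "lag_virtual"),
                                 correction = "bonferroni") {
  dependent <- match.arg(dependent)
  correction <- match.arg(correction)
  m <- lag_table_matrix(table, dependent)
  if (nrow(m) < 2L) stop("need at least 2 participants", call. = FALSE)
  k <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    d <- m[, cmp[1L]] - m[, cmp[2L]]
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
      degen <- TRUE
    } else {
      tval <- mean(d) / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tval), df = n - 1L)
      degen <- FALSE
    }
    data.frame(comparison = paste(cmp, collapse = " vs "),
               t = tval, df = n - 1L, p = p,
               p_corrected = min(1, p * k), degenerate = degen)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ratings_matrix <- function(ratings, question) {
  r <- ratings[ratings$question == question, , drop = FALSE]
  if (!nrow(r)) stop("no ratings for question ", question, call. = FALSE)
  wide <- stats::reshape(r[, c("participant", "condition", "rating")],
                         idvar = "participant", timevar = "condition",
                         direction = "wide")
  m <- as.matrix(wide[, -1L])
  colnames(m) <- sub("rating.", "", colnames(m), fixed = TRUE)
  rownames(m) <- wide$participant
  if (anyNA(m))
    stop("incomplete ratings: every participant needs all conditions",
         call. = FALSE)
  m
}

#' Friedman test on the questionnaire ratings
#'
#' Rank test across the four related condition samples of one question.
#' If every participant gives identical ratings across conditions the
#' statistic is degenerate; chi-squared 0 and p = 1 are returned with a
#' warning.
#'
#' @param ratings ratings table (see [generate_ratings()]).
#' @param question `"Q1"` or `"Q2"`.
#' @return list with `chi2`, `df`, `p`, `n`.
#' @export
friedman_test <- function(ratings, question = c("Q1", "Q2")) {
  question <- match.arg(question)
  m <- ratings_matrix(ratings, question)
  if (all(apply(m, 1L, function(r) length(unique(r)) == 1L))) {
    warning("degenerate input: all ratings tied within participants",
            call. = FALSE)
    return(list(chi2 = 0, df = ncol(m) - 1L, p = 1, n = nrow(m)))
  }
  ft <- stats::friedman.test(m)
  list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, n = nrow(m))
}

#' Pairwise Wilcoxon signed-rank tests on ratings
#'
#' Two-tailed signed-rank tests between condition pairs, reported as the
#' normal-approximation z with continuity correction and mid-rank tie
#' handling; zero differences are dropped (documented convention).
#' P-values are Bonferroni-corrected over the requested pairs.
#'
#' @param ratings ratings table.
#' @param question `"Q1"` or `"Q2"`.
#' @param pairs list of length-2 character vectors of condition names.
#' @param correction only `"bonferroni"`.
#' @return data frame: one row per pair with `z`, `n_effective`, `p`,
#'   `p_corrected`.
#' @export
wilcoxon_pairs <- function(ratings, question = c("Q1", "Q2"),
                           pairs = list(c("vh_incong", "vh_cong"),
                                        c("rh_incong", "rh_cong"),
                                        c("vh_cong", "rh_cong"),
                                        c("vh_incong", "rh_incong")),
                           correction = "bonferroni") {
  question <- match.arg(question)
  correction <- match.arg(correction)
  m <- ratings_matrix(ratings, question)
  k <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    d <- m[, pr[1L]] - m[, pr[2L]]
    d <- d[d != 0]
    n <- length(d)
    if (n < 2L)
      stop("fewer than 2 nonzero paired differences for ",
           paste(pr, collapse = " vs "), call. = FALSE)
    r <- rank(abs(d))
    w_pos <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5 * sign(w_pos - mu)
    z <- (w_pos - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(pr, collapse = " vs "), z = z,
               n_effective = n, p = p, p_corrected = min(1, p * k))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
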