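## Synthetic data-glove cohorts with the statistical structure the
## behavioural analysis assumes: participant- and trial-level lag noise,
## per-finger sensor gains, channel noise, and ordinal ratings.

#' Specify a synthetic behavioural cohort
#'
#' The `"study"` preset mirrors the behavioural design: 24 participants,
#' 4 conditions (VH/RH x cong/incong), 6 trials per condition (2 runs x
#' 3), 32 s trials of 0.5 Hz grasping sampled at 60 Hz, and a 500 ms
#' visual delay in incongruent trials.  Its condition lag means encode
#' the qualitative empirical pattern (instructed-modality lag small;
#' under incongruence the real hand leads strongly in the VH task and
#' lags slightly more in the RH task).  The `"null"` preset shares the
#' design but has identical lag means in all conditions (no effects).
#'
#' Condition lag means are the real-hand lag relative to the target, in
#' seconds; the virtual-hand lag follows by construction (real-hand lag
#' plus the visual delay under incongruence).
#'
#' @param preset `"study"` or `"null"`.
#' @param n_participants,trials_per_condition design sizes.
#' @param trial_duration seconds per trial.
#' @param f0 grasping frequency, Hz.
#' @param fs glove sampling rate, Hz.
#' @param visual_delay seconds of virtual-hand delay in incongruent trials.
#' @param condition_lag_means named numeric (vh_cong, rh_cong, vh_incong,
#'   rh_incong): real-hand lag means in seconds (defaults per preset).
#' @param between_subject_sd,within_trial_sd lag noise, seconds.
#' @param noise_sd channel noise as a fraction of channel amplitude.
#' @param amplitude_range sub-interval of `[0, 1]` spanned by the grasp.
#' @param seed integer RNG seed (determinism contract).
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(preset = c("study", "null"),
                        n_participants = 24L,
                        trials_per_condition = 6L,
                        trial_duration = 32,
                        f0 = 0.5, fs = 60,
                        visual_delay = 0.5,
                        condition_lag_means = NULL,
                        between_subject_sd = 0.05,
                        within_trial_sd = 0.03,
                        noise_sd = 0.02,
                        amplitude_range = c(0.15, 0.85),
                        seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(condition_lag_means)) {
    condition_lag_means <- if (preset == "study")
      c(vh_cong = 0.05, rh_cong = 0.05, vh_incong = -0.40, rh_incong = 0.08)
    else
      c(vh_cong = 0.05, rh_cong = 0.05, vh_incong = 0.05, rh_incong = 0.05)
  }
  need <- c("vh_cong", "rh_cong", "vh_incong", "rh_incong")
  if (!all(need %in% names(condition_lag_means)))
    stop("condition_lag_means must name ", paste(need, collapse = ", "),
         call. = FALSE)
  if (fs <= 2 * f0)
    stop("need fs > 2 * f0", call. = FALSE)
  period <- 1 / f0
  if (any(abs(condition_lag_means) > period / 2) ||
      abs(visual_delay) > period / 2)
    stop("lags and delay must lie within +/- half a period", call. = FALSE)
  if (length(amplitude_range) != 2L || any(amplitude_range < 0) ||
      any(amplitude_range > 1) || diff(amplitude_range) <= 0)
    stop("amplitude_range must be an increasing sub-interval of [0, 1]",
         call. = FALSE)
  structure(list(preset = preset,
                 n_participants = as.integer(n_participants),
                 trials_per_condition = as.integer(trials_per_condition),
                 trial_duration = trial_duration, f0 = f0, fs = fs,
                 visual_delay = visual_delay,
                 condition_lag_means = condition_lag_means,
                 between_subject_sd = between_subject_sd,
                 within_trial_sd = within_trial_sd,
                 noise_sd = noise_sd,
                 amplitude_range = amplitude_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec ('%s' preset)\n", x$preset))
  cat(sprintf("  %d participants x 4 conditions x %d trials, %g s at %g Hz, %g Hz grasping\n",
              x$n_participants, x$trials_per_condition, x$trial_duration,
              x$fs, x$f0))
  cat(sprintf("  visual delay %g s; lag means (s): %s\n", x$visual_delay,
              paste(sprintf("%s=%.2f", names(x$condition_lag_means),
                            x$condition_lag_means), collapse = ", ")))
  invisible(x)
}

#' Target size signal of the behavioural task
#'
#' Sinusoidal size modulation of the fixation dot: 12% size change at
#' `f0`, i.e. `size = 1 + 0.12 * (1 + sin(phase)) / 2` so the extrema
#' ratio is exactly 1.12 (modulation convention: minimum size 1).
#'
#' @param duration seconds.
#' @param f0 frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return data frame with `t` (seconds), `phase` (radians) and `size`.
#' @examples
#' tgt <- make_target(32, 0.5, 60)
#' nrow(tgt)                      # 1920 samples
#' max(tgt$size) / min(tgt$size)  # 1.12
#' @export
make_target <- function(duration, f0, fs) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  phase <- 2 * pi * f0 * t
  data.frame(t = t, phase = phase, size = 1 + 0.12 * (1 + sin(phase)) / 2)
}

## samples one trial's five glove channels for a given true lag
render_trial <- function(spec, gains, lag, target) {
  mid <- mean(spec$amplitude_range)
  amp <- diff(spec$amplitude_range) / 2
  grasp <- sin(target$phase - 2 * pi * spec$f0 * lag)
  ch <- vapply(seq_len(5L), function(j) {
    x <- mid + amp * gains[j] * grasp +
      stats::rnorm(length(grasp), 0, spec$noise_sd * amp)
    pmin(1, pmax(0, x))
  }, numeric(nrow(target)))
  colnames(ch) <- finger_cols()
  ch
}

#' Generate one synthetic participant
#'
#' Draws the participant's per-condition lags (normal around the
#' condition means), a per-finger sensor gain profile, and per-trial lag
#' jitter; renders each trial's five glove channels as rescaled, noisy
#' sinusoids.  Consumes the current RNG stream (callers seed it;
#' [generate_cohort()] does).
#'
#' @param spec a [cohort_spec()].
#' @param id participant identifier.
#' @return list with `trials` (long data frame of samples) and `truth`
#'   (per-trial true lags plus the participant's condition lags).
#' @export
generate_participant <- function(spec, id) {
  period <- 1 / spec$f0
  target <- make_target(spec$trial_duration, spec$f0, spec$fs)
  gains <- stats::runif(5L, 0.8, 1.2)
  conditions <- names(spec$condition_lag_means)
  p_lags <- stats::rnorm(length(conditions), spec$condition_lag_means,
                         spec$between_subject_sd)
  names(p_lags) <- conditions
  trials <- list()
  truth <- list()
  k <- spec$trials_per_condition
  for (cond in conditions) {
    instr <- toupper(sub("_.*", "", cond))
    congr <- sub(".*_", "", cond)
    for (j in seq_len(k)) {
      lag <- p_lags[cond] + stats::rnorm(1L, 0, spec$within_trial_sd)
      if (abs(lag) > period / 2)
        stop("drawn lag beyond +/- half a period for participant ", id,
             call. = FALSE)
      ch <- render_trial(spec, gains, lag, target)
      trials[[length(trials) + 1L]] <- data.frame(
        participant = id,
        run = if (j <= ceiling(k / 2)) 1L else 2L,
        trial = j, instruction = instr, congruence = congr,
        t = target$t, ch, target_phase = target$phase)
      truth[[length(truth) + 1L]] <- data.frame(
        participant = id, condition = cond, trial = j,
        lag_participant = unname(p_lags[cond]), lag_trial = unname(lag))
    }
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth))
}

#' Generate a full synthetic cohort
#'
#' Deterministic under `spec$seed`.  Returns the cohort in memory and,
#' when `dir` is given, also writes the cohort directory: one trial CSV
#' per participant, a JSON manifest of the design constants, the ratings
#' table, and the hidden-truth sidecar (`truth.csv`, clearly separated
#' from the analyzable data).
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param ratings also generate the ratings table (per the cohort
#'   spec's preset)?
#' @return list with `trials`, `truth`, `manifest`, `ratings` (or NULL)
#'   and `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL, ratings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  parts <- lapply(seq_len(spec$n_participants), function(i)
    generate_participant(spec, sprintf("p%02d", i)))
  trials <- do.call(rbind, lapply(parts, `[[`, "trials"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  manifest <- list(f0 = spec$f0, fs = spec$fs,
                   visual_delay = spec$visual_delay,
                   trial_duration = spec$trial_duration,
                   n_participants = spec$n_participants,
                   trials_per_condition = spec$trials_per_condition,
                   preset = spec$preset, seed = spec$seed,
                   channel_roles = list(f1 = "thumb", f2 = "index",
                                        f3 = "middle", f4 = "ring",
                                        f5 = "little"))
  rat <- if (ratings) generate_ratings(spec) else NULL
  if (!is.null(dir)) {
    write_cohort_dir(trials, manifest, dir)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    if (!is.null(rat))
      utils::write.csv(rat, file.path(dir, "ratings.csv"), row.names = FALSE)
  }
  list(trials = trials, truth = truth, manifest = manifest,
       ratings = rat, spec = spec)
}

#' Draw a participant x condition lag table directly (fast path)
#'
#' Samples the lag table the full pipeline would estimate, without
#' waveform rendering: per participant and condition, the mean of
#' `trials_per_condition` trial lags around the participant's condition
#' lag.  Used for many-cohort statistical calibration runs; the waveform
#' path is exercised by the parameter-recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (default: the spec's).
#' @return a `"lag_table"` data frame as from [aggregate_lags()].
#' @export
draw_lag_table <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  period <- 1 / spec$f0
  conditions <- names(spec$condition_lag_means)
  k <- spec$trials_per_condition
  rows <- lapply(seq_len(spec$n_participants), function(i) {
    p_lags <- stats::rnorm(length(conditions), spec$condition_lag_means,
                           spec$between_subject_sd)
    est <- p_lags + stats::rnorm(length(conditions), 0,
                                 spec$within_trial_sd / sqrt(k))
    data.frame(participant = sprintf("p%02d", i),
               instruction = toupper(sub("_.*", "", conditions)),
               congruence = sub(".*_", "", conditions),
               condition = conditions, n_trials = k,
               lag_real = est,
               lag_virtual = ifelse(sub(".*_", "", conditions) == "incong",
                                    {
                                      lv <- est + spec$visual_delay
                                      lv <- lv - period * round(lv / period)
                                      ifelse(lv <= -period / 2, lv + period, lv)
                                    }, est))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lag_table", "data.frame")
  out
}

#' Generate the questionnaire ratings table
#'
#' Ordinal 7-point ratings for the two post-experiment questions
#' (Q1 difficulty, Q2 attentional focus from real to virtual hand) from
#' a shifted-latent-Gaussian model: rating = round of a unit-variance
#' Gaussian around the condition's latent mean, clamped to 1..7.  The
#' `"study"` preset shifts Q1 up under incongruence (most for VH) and
#' splits Q2 by instructed modality; the `"null"` preset has a single
#' latent mean everywhere.
#'
#' @param spec a [cohort_spec()].
#' @param seed RNG seed (default derived from the spec's).
#' @return data frame with `participant`, `condition`, `question`,
#'   `rating` (integer 1..7).
#' @export
generate_ratings <- function(spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  mu <- if (spec$preset == "study") {
    list(Q1 = c(vh_cong = 3.0, rh_cong = 3.0,
                vh_incong = 5.0, rh_incong = 4.2),
         Q2 = c(vh_cong = 5.5, rh_cong = 2.5,
                vh_incong = 5.5, rh_incong = 2.5))
  } else {
    list(Q1 = c(vh_cong = 4, rh_cong = 4, vh_incong = 4, rh_incong = 4),
         Q2 = c(vh_cong = 4, rh_cong = 4, vh_incong = 4, rh_incong = 4))
  }
  conditions <- names(spec$condition_lag_means)
  rows <- expand.grid(participant = sprintf("p%02d",
                                            seq_len(spec$n_participants)),
                      condition = conditions, question = c("Q1", "Q2"),
                      stringsAsFactors = FALSE)
  latent <- stats::rnorm(nrow(rows),
                         mean = mapply(function(q, cond) mu[[q]][cond],
                                       rows$question, rows$condition),
                         sd = 1)
  rows$rating <- as.integer(pmin(7L, pmax(1L, round(latent))))
  rows
}
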