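## Behavioural preprocessing: finger averaging, normalization, per-trial
## lag estimation, and participant x condition aggregation.

finger_cols <- function() paste0("f", 1:5)

## the four non-thumb channels (f1 is the thumb by the channel-role
## convention recorded in every cohort manifest)
grasp_cols <- function() paste0("f", 2:5)

#' Average the four non-thumb finger channels of a glove trial
#'
#' The raw grasp signal of a trial is the arithmetic mean of the four
#' non-thumb finger flexion channels (`f2`..`f5`; `f1` is the thumb).
#' No further preprocessing is applied before lag estimation.
#'
#' @param trial data frame with one row per sample and finger channels
#'   `f1`..`f5` in `[0, 1]`.
#' @return numeric vector: the scalar grasp signal.
#' @examples
#' tr <- data.frame(f1 = 0, f2 = 0.2, f3 = 0.4, f4 = 0.6, f5 = 0.8)
#' preprocess_trial(tr)  # 0.5
#' @export
preprocess_trial <- function(trial) {
  need <- grasp_cols()
  if (!all(need %in% names(trial)))
    stop("trial must contain the four non-thumb finger channels ",
         paste(need, collapse = ", "), call. = FALSE)
  rowMeans(as.matrix(trial[, need]))
}

#' Normalize a movement trajectory for display
#'
#' Zero-mean, unit-peak-amplitude rescaling used for condition-average
#' display only; the lag estimator consumes the un-normalized average
#' (normalization cannot change phase).
#'
#' @param x numeric series.
#' @return normalized series.
#' @export
normalize_trajectory <- function(x) {
  x <- x - mean(x)
  peak <- max(abs(x))
  if (peak == 0) return(x)
  x / peak
}

## circular mean of lags (seconds) on the circle of period `period`
circular_mean_lag <- function(lags, period) {
  ang <- 2 * pi * lags / period
  m <- Arg(sum(exp(1i * ang)))
  lag <- m * period / (2 * pi)
  lag <- lag - period * round(lag / period)
  if (lag <= -period / 2) lag <- lag + period
  lag
}

#' Estimate the real-hand phase lag of one behavioural trial
#'
#' Averages the four non-thumb finger channels and estimates the phase
#' lag of the grasp signal relative to the target's oscillatory size
#' change with [cwt_phase_lag()].  Convention: hand opening maps to a
#' growing target, so the reference is `sin(target_phase)`.
#'
#' @param trial data frame with columns `f1`..`f5` and `target_phase`
#'   (radians).
#' @param f0 movement frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return lag in seconds (positive = hand behind target).
#' @export
trial_lag <- function(trial, f0, fs) {
  if (!"target_phase" %in% names(trial))
    stop("trial must contain a 'target_phase' column", call. = FALSE)
  grasp <- preprocess_trial(trial)
  reference <- sin(trial$target_phase)
  cwt_phase_lag(grasp, reference, f0 = f0, fs = fs)
}

#' Aggregate per-trial lags into a participant x condition lag table
#'
#' Computes the circular-mean real-hand lag per participant and condition
#' and derives the virtual-hand lag: in incongruent conditions the seen
#' hand is the felt hand delayed by the manifest's visual delay
#' (`lag_virtual = lag_real + visual_delay`, wrapped); in congruent
#' conditions the two are identical.
#'
#' @param trials long data frame of samples with identifier columns
#'   `participant`, `trial`, `instruction`, `congruence` plus `f1`..`f5`
#'   and `target_phase` (the cohort CSV dialect), or a list of per-trial
#'   data frames.
#' @param manifest cohort manifest list with `f0`, `fs`, `visual_delay`
#'   (see [read_manifest()]).
#' @return data frame of class `"lag_table"`: one row per participant x
#'   condition with `lag_real` and `lag_virtual` in seconds.  Missing
#'   participant x condition cells are flagged with `NA` and a warning.
#' @export
aggregate_lags <- function(trials, manifest) {
  if (is.data.frame(trials)) {
    key <- interaction(trials$participant, trials$instruction,
                       trials$congruence, trials$trial, drop = TRUE)
    trials <- split(trials, key)
  }
  f0 <- manifest$f0
  fs <- manifest$fs
  period <- 1 / f0
  rows <- lapply(trials, function(tr) {
    data.frame(participant = tr$participant[1L],
               instruction = tr$instruction[1L],
               congruence = tr$congruence[1L],
               lag = trial_lag(tr, f0, fs))
  })
  per_trial <- do.call(rbind, rows)
  participants <- sort(unique(per_trial$participant))
  design <- expand.grid(instruction = c("VH", "RH"),
                        congruence = c("cong", "incong"),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(participants, function(p) {
    do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      sel <- per_trial$participant == p &
        per_trial$instruction == design$instruction[i] &
        per_trial$congruence == design$congruence[i]
      lag_real <- if (any(sel))
        circular_mean_lag(per_trial$lag[sel], period) else NA_real_
      lag_virtual <- if (design$congruence[i] == "incong" &&
                         !is.na(lag_real)) {
        lv <- lag_real + manifest$visual_delay
        lv <- lv - period * round(lv / period)
        if (lv <= -period / 2) lv + period else lv
      } else lag_real
      data.frame(participant = p,
                 instruction = design$instruction[i],
                 congruence = design$congruence[i],
                 condition = paste0(tolower(design$instruction[i]), "_",
                                    design$congruence[i]),
                 n_trials = sum(sel),
                 lag_real = lag_real, lag_virtual = lag_virtual)
    }))
  }))
  if (anyNA(out$lag_real))
    warning("missing participant x condition cells flagged with NA; ",
            "they are excluded from statistics", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("lag_table", "data.frame")
  out
}

#' Write / read the behavioural cohort trial files
#'
#' Trials are stored as one tidy CSV per participant (one row per sample:
#' identifiers, `t`, `f1`..`f5`, `target_phase`) plus one JSON manifest
#' per cohort holding the sampling rate and design constants.
#'
#' @param trials long data frame of samples (cohort CSV dialect).
#' @param manifest manifest list.
#' @param dir cohort directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort_dir <- function(trials, manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  for (p in unique(trials$participant)) {
    utils::write.csv(trials[trials$participant == p, , drop = FALSE],
                     file.path(dir, sprintf("trials_%s.csv", p)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @export
read_cohort_dir <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- read_manifest(mpath)
  files <- sort(list.files(dir, pattern = "^trials_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    stop("no trial files in ", dir, call. = FALSE)
  trials <- do.call(rbind, lapply(files, function(f) {
    tr <- tryCatch(utils::read.csv(f),
                   error = function(e)
                     stop("malformed trial file '", f, "': ",
                          conditionMessage(e), call. = FALSE))
    need <- c("participant", "trial", "instruction", "congruence", "t",
              finger_cols(), "target_phase")
    if (!all(need %in% names(tr)))
      stop("malformed trial file '", f, "': missing columns ",
           paste(setdiff(need, names(tr)), collapse = ", "), call. = FALSE)
    tr
  }))
  list(trials = trials, manifest = manifest)
}

#' @rdname write_cohort_dir
#' @param file manifest path.
#' @export
write_manifest <- function(manifest, file) {
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_cohort_dir
#' @export
read_manifest <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}
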