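# Adaptive staircases, simulated observers, scoring and the stability screen.

#' Staircase configuration
#'
#' Transformed up-down track parameters. Presets for the two AFG paradigms:
#' [afg_fixed_staircase()] is the gap task's 1-up-1-down track starting at
#' +6 dB SNR (step 2 dB, then 0.5 dB after 3 reversals, stopping at 10
#' reversals); [afg_dynamic_staircase()] is the pattern task's 2-down-1-up
#' track starting at +12 dB (step 2 dB, then 0.5 dB after 7 reversals,
#' stopping at 22 reversals).
#'
#' @param rule `"1up1down"` or `"2down1up"`.
#' @param start_snr starting SNR (dB).
#' @param step_initial,step_final step sizes (dB); the step drops to
#'   `step_final` once `step_change_after` reversals have occurred.
#' @param step_change_after reversal count triggering the step change.
#' @param stop_after total reversals at which the track terminates.
#' @param snr_ceiling,snr_floor clamp bounds (dB).
#' @return A `staircase_config`.
#' @export
staircase_config <- function(rule = c("1up1down", "2down1up"), start_snr,
                             step_initial = 2, step_final = 0.5,
                             step_change_after, stop_after,
                             snr_ceiling = 20, snr_floor = -40) {
  rule <- match.arg(rule)
  stopifnot(step_final <= step_initial, stop_after > step_change_after,
            snr_floor < snr_ceiling,
            start_snr >= snr_floor, start_snr <= snr_ceiling)
  structure(list(rule = rule, start_snr = start_snr,
                 step_initial = step_initial, step_final = step_final,
                 step_change_after = step_change_after,
                 stop_after = stop_after,
                 snr_ceiling = snr_ceiling, snr_floor = snr_floor),
            class = "staircase_config")
}

#' @rdname staircase_config
#' @export
afg_fixed_staircase <- function() {
  staircase_config("1up1down", start_snr = 6, step_initial = 2,
                   step_final = 0.5, step_change_after = 3, stop_after = 10)
}

#' @rdname staircase_config
#' @export
afg_dynamic_staircase <- function() {
  staircase_config("2down1up", start_snr = 12, step_initial = 2,
                   step_final = 0.5, step_change_after = 7, stop_after = 22)
}

#' Initialize a staircase state
#'
#' @param cfg a [staircase_config()].
#' @return A `staircase_state` with the track at `start_snr`.
#' @export
new_staircase <- function(cfg) {
  stopifnot(inherits(cfg, "staircase_config"))
  structure(list(current_snr = cfg$start_snr, direction = "none",
                 consecutive_correct = 0L, reversal_snrs = numeric(),
                 trial_log = list(), finished = FALSE),
            class = "staircase_state")
}

#' Advance a staircase by one trial
#'
#' Implements the transformed up-down rules: under `1up1down` every correct
#' response lowers the SNR one step and every error raises it; under
#' `2down1up` the SNR lowers only after two consecutive correct responses
#' (the counter resets on each downward move) and rises after any error. A
#' reversal is logged (at the SNR of the just-completed trial) whenever the
#' movement direction flips; the first movement defines no reversal. The step
#' size switches to `step_final` once `step_change_after` reversals have been
#' logged, and the track finishes at `stop_after` reversals. SNR is clamped
#' to `[snr_floor, snr_ceiling]` without logging spurious reversals.
#'
#' @param state a `staircase_state`.
#' @param cfg the [staircase_config()].
#' @param correct logical response of the just-completed trial.
#' @return The updated `staircase_state`.
#' @export
staircase_step <- function(state, cfg, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (state$finished) stop("cannot step a finished staircase")
  snr_now <- state$current_snr
  move <- "none"
  if (cfg$rule == "1up1down") {
    move <- if (correct) "down" else "up"
  } else {                                   # 2down1up
    if (!correct) {
      move <- "up"
      state$consecutive_correct <- 0L
    } else {
      state$consecutive_correct <- state$consecutive_correct + 1L
      if (state$consecutive_correct >= 2L) {
        move <- "down"
        state$consecutive_correct <- 0L
      }
    }
  }
  reversal <- FALSE
  if (move != "none") {
    if (state$direction != "none" && move != state$direction) {
      state$reversal_snrs <- c(state$reversal_snrs, snr_now)
      reversal <- TRUE
    }
    step <- if (length(state$reversal_snrs) >= cfg$step_change_after)
      cfg$step_final else cfg$step_initial
    delta <- if (move == "down") -step else step
    state$current_snr <- clamp(snr_now + delta, cfg$snr_floor, cfg$snr_ceiling)
    state$direction <- move
  }
  state$trial_log[[length(state$trial_log) + 1L]] <-
    list(snr = snr_now, correct = correct, reversal = reversal)
  if (length(state$reversal_snrs) >= cfg$stop_after) state$finished <- TRUE
  state
}

#' Simulated psychometric observer
#'
#' A logistic psychometric function for a two-alternative forced-choice task:
#' `p(correct | snr) = guess + (1 - guess - lapse) * logistic((snr - threshold_db) / slope_db)`.
#'
#' @param threshold_db SNR at the logistic midpoint (dB).
#' @param slope_db logistic scale parameter (dB, > 0); smaller is steeper.
#' @param guess lower asymptote (0.5 for 2AFC).
#' @param lapse upper-asymptote deficit.
#' @return An `observer`.
#' @export
observer <- function(threshold_db, slope_db = 2, guess = 0.5, lapse = 0.02) {
  stopifnot(slope_db > 0, guess >= 0, guess < 1 - lapse, lapse >= 0)
  structure(list(threshold_db = threshold_db, slope_db = slope_db,
                 guess = guess, lapse = lapse), class = "observer")
}

#' @rdname observer
#' @param obs an `observer`.
#' @param snr SNR(s) in dB.
#' @return `observer_p_correct`: probability of a correct response.
#' @export
observer_p_correct <- function(obs, snr) {
  obs$guess + (1 - obs$guess - obs$lapse) *
    plogis((snr - obs$threshold_db) / obs$slope_db)
}

#' SNR at which an observer reaches a target proportion correct
#'
#' Inverts the observer's psychometric function; used to locate the 50% and
#' 70.7% convergence points of the 1-up-1-down and 2-down-1-up rules.
#'
#' @param obs an [observer()].
#' @param p target proportion correct (must lie between `guess` and
#'   `1 - lapse`).
#' @return SNR in dB.
#' @export
observer_snr_at <- function(obs, p) {
  stopifnot(p > obs$guess, p < 1 - obs$lapse)
  obs$threshold_db +
    obs$slope_db * qlogis((p - obs$guess) / (1 - obs$guess - obs$lapse))
}

#' Run one adaptive track with a simulated observer
#'
#' Repeatedly samples the observer's response as Bernoulli of its psychometric
#' function at the current SNR (optionally building the trial's stimulus via
#' `trial_factory`) and applies [staircase_step()] until the track finishes.
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param obs an [observer()].
#' @param cfg a [staircase_config()].
#' @param task `"gap"` or `"pattern"` (recorded in the result).
#' @param trial_factory optional `function(snr)` building the trial's stimuli
#'   (e.g. a gapped/ungapped pair or a [make_pattern_pair()]); its value is
#'   not used to decide correctness (observer difficulty is modelled on SNR
#'   only) but it consumes RNG identically to a full stimulus run.
#' @param max_trials safety bound.
#' @return A `run_result`: `score_db` (median of last six reversals),
#'   `reversal_snrs`, `stable` flag ([stability_check()]), `task`,
#'   `n_trials`, `trial_log`.
#' @export
run_track <- function(obs, cfg, task = c("gap", "pattern"),
                      trial_factory = NULL, max_trials = 1000) {
  task <- match.arg(task)
  state <- new_staircase(cfg)
  n <- 0L
  while (!state$finished && n < max_trials) {
    n <- n + 1L
    if (!is.null(trial_factory)) trial_factory(state$current_snr)
    p <- observer_p_correct(obs, state$current_snr)
    correct <- runif(1) < p
    state <- staircase_step(state, cfg, correct)
  }
  if (!state$finished)
    stop("staircase did not terminate within max_trials")
  structure(list(score_db = score_run(state$reversal_snrs),
                 reversal_snrs = state$reversal_snrs,
                 stable = stability_check(state$reversal_snrs),
                 task = task, n_trials = n, trial_log = state$trial_log),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s task: score %.2f dB SNR after %d trials (%d reversals)%s\n",
              x$task, x$score_db, x$n_trials, length(x$reversal_snrs),
              if (x$stable) "" else " [UNSTABLE]"))
  invisible(x)
}

#' Score a finished run
#'
#' The run score is the median SNR of the last six reversals; a task score
#' combining several runs is their arithmetic mean.
#'
#' @param reversal_snrs reversal SNRs of a finished track (>= 6).
#' @return Score in dB SNR.
#' @export
score_run <- function(reversal_snrs) {
  if (length(reversal_snrs) < 6) stop("need at least 6 reversals to score")
  median(tail(reversal_snrs, 6))
}

#' @rdname score_run
#' @param scores per-run scores (dB).
#' @export
combine_runs <- function(scores) mean(scores)

#' Stability screen on the last six reversals
#'
#' A run is stable if the spread (max minus min) of its last six reversal
#' SNRs is smaller than `tol_db`; unstable runs are excluded from analysis.
#'
#' @param reversal_snrs reversal SNRs (>= 6).
#' @param tol_db spread criterion in dB (default 5).
#' @return Logical flag.
#' @export
stability_check <- function(reversal_snrs, tol_db = 5) {
  if (length(reversal_snrs) < 6) stop("need at least 6 reversals")
  last6 <- tail(reversal_snrs, 6)
  (max(last6) - min(last6)) < tol_db
}
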