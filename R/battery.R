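# Session-level orchestration: configuration loading, the simulated test
# battery for one participant, and the cohort-level analysis report.

#' Load a run configuration from file or overrides
#'
#' Reads a YAML or JSON configuration (or takes a named list) and fills every
#' unset field with the battery defaults: 50 ms chords, 42-chord fixed
#' figures with a 6-chord gap, the 1-up-1-down (start +6 dB) and 2-down-1-up
#' (start +12 dB) staircases. Unknown keys are an error, as are invariant
#' violations.
#'
#' Recognized keys: `master_seed`, `output_dir`, `stimulus` (sub-keys of
#' [stim_config()]), `fixed_staircase` / `dynamic_staircase` (sub-keys of
#' [staircase_config()]), `observer` (sub-keys of [observer()] minus
#' threshold), `thresholds` (named: fixed, low, high).
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @param overrides named list merged on top of the file contents.
#' @return A `run_config` list with `stimulus`, `fixed_staircase`,
#'   `dynamic_staircase`, `master_seed`, `output_dir`, `thresholds`,
#'   `observer`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (is.list(path)) {
    raw <- path
  } else if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.list(raw)) stop("config file must parse to a mapping: ", path)
  }
  raw <- modifyList(raw, overrides)
  known <- c("master_seed", "output_dir", "stimulus", "fixed_staircase",
             "dynamic_staircase", "observer", "thresholds")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  check_sub <- function(x, fn, what) {
    x <- as.list(x)
    bad <- setdiff(names(x), names(formals(fn)))
    if (length(bad))
      stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
    x
  }
  stim <- do.call(stim_config, check_sub(raw$stimulus, stim_config, "stimulus"))
  fx <- modifyList(unclass(afg_fixed_staircase()),
                   check_sub(raw$fixed_staircase, staircase_config,
                             "fixed_staircase"))
  dy <- modifyList(unclass(afg_dynamic_staircase()),
                   check_sub(raw$dynamic_staircase, staircase_config,
                             "dynamic_staircase"))
  thr <- modifyList(list(fixed = -14.5, low = 9.0, high = 7.3),
                    as.list(raw$thresholds))
  obs <- modifyList(list(slope_db = 2, guess = 0.5, lapse = 0.02),
                    check_sub(raw$observer, observer, "observer"))
  structure(list(
    master_seed = if (is.null(raw$master_seed)) 1L else as.integer(raw$master_seed),
    output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
    stimulus = stim,
    fixed_staircase = do.call(staircase_config, fx),
    dynamic_staircase = do.call(staircase_config, dy),
    thresholds = thr, observer = obs), class = "run_config")
}

battery_observer <- function(cfg, threshold)
  observer(threshold, cfg$observer$slope_db, cfg$observer$guess,
           cfg$observer$lapse)

#' Simulate one participant through the AFG battery
#'
#' Runs a simulated observer through the three adaptive tasks: AFG-Fixed
#' (two 1-up-1-down runs whose scores are averaged) and the two dynamic
#' pattern tasks (AFG-Low, AFG-High; one 2-down-1-up run each), with the
#' dynamic task order counterbalanced by master-seed parity. Every run is
#' seeded by [derive_seed()] from the master seed, so the report is
#' end-to-end reproducible.
#'
#' @param cfg a [load_config()] result (or `load_config()` defaults).
#' @return A `battery_report` list: per-task scores (dB SNR), stability and
#'   exclusion flags, reversal lists, task order and all sub-seeds.
#' @export
#' @examples
#' rep1 <- run_battery(load_config(list(master_seed = 42)))
#' rep1$scores
run_battery <- function(cfg = load_config()) {
  stopifnot(inherits(cfg, "run_config"))
  ms <- cfg$master_seed
  run_one <- function(task, run_id, sc_cfg, threshold, task_name) {
    seed <- derive_seed(ms, task_name, run_id)
    set.seed(seed)
    res <- run_track(battery_observer(cfg, threshold), sc_cfg, task = task)
    list(seed = seed, score_db = res$score_db, stable = res$stable,
         n_trials = res$n_trials, reversal_snrs = res$reversal_snrs)
  }
  fixed_runs <- lapply(1:2, function(r)
    run_one("gap", r, cfg$fixed_staircase, cfg$thresholds$fixed, "afg_fixed"))
  dyn_order <- if (ms %% 2 == 0) c("low", "high") else c("high", "low")
  dyn <- lapply(dyn_order, function(v)
    run_one("pattern", 1, cfg$dynamic_staircase, cfg$thresholds[[v]],
            paste0("afg_", v)))
  names(dyn) <- dyn_order
  fixed_score <- combine_runs(vapply(fixed_runs, `[[`, 0, "score_db"))
  scores <- list(
    AFG_fixed = fixed_score,
    AFG_low = dyn[["low"]]$score_db,
    AFG_high = dyn[["high"]]$score_db)
  stable <- list(
    AFG_fixed = all(vapply(fixed_runs, `[[`, TRUE, "stable")),
    AFG_low = dyn[["low"]]$stable,
    AFG_high = dyn[["high"]]$stable)
  structure(list(master_seed = ms,
                 task_order = c("afg_dynamic_1" = dyn_order[1],
                                "afg_dynamic_2" = dyn_order[2]),
                 scores = scores, stable = stable,
                 excluded = !all(unlist(stable)),
                 fixed_runs = fixed_runs, dynamic_runs = dyn),
            class = "battery_report")
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("<battery_report> seed %d%s\n", x$master_seed,
              if (x$excluded) " [EXCLUDED: unstable run]" else ""))
  for (nm in names(x$scores))
    cat(sprintf("  %-10s %6.2f dB SNR%s\n", nm, x$scores[[nm]],
                if (x$stable[[nm]]) "" else " (unstable)"))
  invisible(x)
}

#' Serialize a battery report or analysis report to JSON
#'
#' Deterministic JSON (no rounding beyond full precision) so identical seeds
#' produce byte-identical artifacts.
#'
#' @param report a `battery_report` or any list.
#' @param path output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly if written to file.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Cohort-level analysis report
#'
#' The full statistical pipeline on a participant table: stability screen,
#' Spearman/Holm correlation matrix over the seven battery measures,
#' stepwise regressions predicting SiB and WiN, and the three SEM fits plus
#' the CFA, each summarized by its fit-index roster and standardized paths.
#'
#' @param cohort data.frame from [simulate_cohort()] or [read_cohort_csv()].
#' @param models which SEM models to fit (default all four).
#' @param bootstrap if `TRUE`, add a 100-replicate 95% subsample bootstrap
#'   of RMSEA for each SEM model.
#' @return A list with `n`, `n_excluded`, `correlations`, `stepwise`, `sem`.
#' @export
analyze_cohort <- function(cohort,
                           models = c("model1", "model2", "model3", "cfa"),
                           bootstrap = FALSE) {
  screened <- screen_cohort(cohort)
  cand <- c("age", "PTA", "AFG_fixed", "AFG_low", "AFG_high")
  sem <- lapply(models, function(m) {
    rep <- afg_sem_report(screened, m)
    out <- list(indices = rep$indices, paths = rep$paths,
                converged = rep$fit$converged)
    if (bootstrap) {
      bt <- bootstrap_rmsea(build_paper_models()[[m]], screened,
                            flip = "WiN", standardize = "WiN")
      out$rmsea_boot <- list(mean = mean(bt$rmsea), sd = sd(bt$rmsea),
                             n_failed = bt$n_failed)
    }
    out
  })
  names(sem) <- models
  list(n = nrow(screened), n_excluded = nrow(cohort) - nrow(screened),
       correlations = correlation_report(screened),
       stepwise = list(
         SiB = stepwise_fit(screened, "SiB", cand),
         WiN = stepwise_fit(screened, "WiN", cand)),
       sem = sem)
}
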