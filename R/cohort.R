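# Synthetic participant cohorts with the causal structure assumed by the
# SEM analysis layer: age -> hearing (PTA) -> figure-ground ability (AFG)
# -> speech-in-noise (SIN), with observed task scores as noisy indicators.

#' Cohort generator parameters
#'
#' Standardized path coefficients and loadings of the generating model.
#' Structure: `age` (Gaussian copula of a uniform age range) predicts `PTA`;
#' `age` and `PTA` predict a latent figure-ground ability `AFG`; the observed
#' AFG tasks load on it, with the two dynamic tasks additionally sharing a
#' correlated "dynamic-specific" component; latent speech-in-noise ability
#' `SIN` is predicted by `AFG`, `PTA`, `age` and (weakly) the shared dynamic
#' component; `SiB` and `WiN` load on `SIN`, `WiN` with an extra direct age
#' effect; `SSQ` is generated independently. The defaults are calibrated so
#' that at large n the simulated Spearman matrix reproduces the published
#' correlation structure of the 159-participant study (e.g. age-PTA 0.72,
#' WiN-age -0.73) to within about 0.03.
#'
#' Score conventions follow the battery: AFG and SiB thresholds in dB SNR
#' (higher = worse), WiN as proportion correct (higher = better), SSQ on a
#' 0-10 difficulty scale.
#'
#' @param n number of participants (>= 10).
#' @param age_range years, uniform.
#' @param b_age_pta,b_age_afg,b_pta_afg standardized structural paths into
#'   PTA and the latent AFG.
#' @param b_afg_sin,b_pta_sin,b_age_sin,b_dyn_sin standardized paths into the
#'   latent SIN (b_dyn_sin is the shared dynamic component's path).
#' @param l_fixed,l_low,l_high AFG indicator loadings.
#' @param l_dyn_low,l_dyn_high loadings of the shared dynamic component.
#' @param l_sib,l_win SIN indicator loadings.
#' @param b_age_win direct age effect on WiN (worse with age).
#' @param win_squash `c(intercept, slope)` of the logistic map from the
#'   standardized (higher = worse) WiN score to proportion correct.
#' @param scales named list of `c(mean, sd)` used to put standardized scores
#'   on task units (dB SNR / dB HL).
#' @param unstable_frac fraction of participants flagged as having an
#'   unstable (excludable) adaptive run.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n = 159, age_range = c(18, 79),
                          b_age_pta = 0.736,
                          b_age_afg = 0.322, b_pta_afg = 0.398,
                          b_afg_sin = 0.547, b_pta_sin = 0.385,
                          b_age_sin = 0.084, b_dyn_sin = 0.332,
                          l_fixed = 0.940, l_low = 0.592, l_high = 0.434,
                          l_dyn_low = 0.507, l_dyn_high = 0.674,
                          l_sib = 0.738, l_win = 0.517, b_age_win = 0.380,
                          win_squash = c(0.7644, 0.5113),
                          scales = list(PTA = c(13.51, 10.05),
                                        AFG_fixed = c(-14.542, 8.200),
                                        AFG_low = c(8.991, 10.897),
                                        AFG_high = c(7.252, 10.447),
                                        SiB = c(-0.880, 2.114),
                                        SSQ = c(4.5, 1.8)),
                          unstable_frac = 0.065) {
  stopifnot(n >= 10, age_range[1] < age_range[2],
            unstable_frac >= 0, unstable_frac < 1)
  p <- as.list(environment())
  paths <- c(p$b_age_pta, p$b_age_afg, p$b_pta_afg, p$b_afg_sin,
             p$b_pta_sin, p$b_age_sin, p$b_dyn_sin, p$b_age_win)
  stopifnot(all(abs(paths) < 1))
  structure(p, class = "cohort_params")
}

#' @rdname cohort_params
#' @details `cohort_defaults()` returns the calibrated default parameter set.
#' @export
cohort_defaults <- function() cohort_params()

# residual sd completing a standardized composite to unit variance
resid_sd <- function(explained) {
  if (explained > 1) stop("infeasible parameters: explained variance > 1")
  sqrt(1 - explained)
}

#' Simulate a synthetic participant cohort
#'
#' Draws `params$n` participants from the generating model described in
#' [cohort_params()]. All structural variables are standardized Gaussian;
#' observed scores are rescaled to task units, and WiN is mapped to
#' proportion correct through a monotone logistic squash (so rank-based
#' statistics are unaffected). Uses the session RNG; wrap in [set.seed()].
#'
#' @param params a [cohort_params()].
#' @return A data.frame with columns `id, age, PTA, AFG_fixed, AFG_low,
#'   AFG_high, WiN, SiB, SSQ, stable`.
#' @export
#' @examples
#' set.seed(1)
#' head(simulate_cohort(cohort_params(n = 20)))
simulate_cohort <- function(params = cohort_defaults()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n <- p$n
  zA <- rnorm(n)
  age <- qunif(pnorm(zA), p$age_range[1], p$age_range[2])
  zP <- p$b_age_pta * zA + resid_sd(p$b_age_pta^2) * rnorm(n)
  rAG <- p$b_age_afg + p$b_pta_afg * p$b_age_pta
  rPG <- p$b_pta_afg + p$b_age_afg * p$b_age_pta
  vG <- p$b_age_afg^2 + p$b_pta_afg^2 +
    2 * p$b_age_afg * p$b_pta_afg * p$b_age_pta
  zG <- p$b_age_afg * zA + p$b_pta_afg * zP + resid_sd(vG) * rnorm(n)
  zC <- rnorm(n)                              # shared dynamic component
  zFix <- p$l_fixed * zG + resid_sd(p$l_fixed^2) * rnorm(n)
  zLow <- p$l_low * zG + p$l_dyn_low * zC +
    resid_sd(p$l_low^2 + p$l_dyn_low^2) * rnorm(n)
  zHigh <- p$l_high * zG + p$l_dyn_high * zC +
    resid_sd(p$l_high^2 + p$l_dyn_high^2) * rnorm(n)
  cs <- c(p$b_afg_sin, p$b_pta_sin, p$b_age_sin)
  vS <- cs[1]^2 + cs[2]^2 + cs[3]^2 +
    2 * (cs[1] * cs[2] * rPG + cs[1] * cs[3] * rAG +
         cs[2] * cs[3] * p$b_age_pta) + p$b_dyn_sin^2
  zS <- cs[1] * zG + cs[2] * zP + cs[3] * zA + p$b_dyn_sin * zC +
    resid_sd(vS) * rnorm(n)
  rAS <- cs[1] * rAG + cs[2] * p$b_age_pta + cs[3]
  zSib <- p$l_sib * zS + resid_sd(p$l_sib^2) * rnorm(n)
  vW <- p$l_win^2 + p$b_age_win^2 + 2 * p$l_win * p$b_age_win * rAS
  zWin <- p$l_win * zS + p$b_age_win * zA + resid_sd(vW) * rnorm(n)
  sc <- function(z, key) p$scales[[key]][1] + p$scales[[key]][2] * z
  data.frame(
    id = seq_len(n),
    age = age,
    PTA = sc(zP, "PTA"),
    AFG_fixed = sc(zFix, "AFG_fixed"),
    AFG_low = sc(zLow, "AFG_low"),
    AFG_high = sc(zHigh, "AFG_high"),
    WiN = plogis(p$win_squash[1] - p$win_squash[2] * zWin),
    SiB = sc(zSib, "SiB"),
    SSQ = clamp(sc(rnorm(n), "SSQ"), 0, 10),
    stable = runif(n) >= p$unstable_frac)
}

#' Apply the stability exclusion screen to a cohort table
#'
#' Drops participants whose adaptive runs were flagged unstable (the +/-5 dB
#' spread criterion on the last six reversals), mirroring the study's data
#' quality exclusions.
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @return The screened data.frame.
#' @export
screen_cohort <- function(cohort) {
  if (!"stable" %in% names(cohort)) return(cohort)
  cohort[cohort$stable, setdiff(names(cohort), "stable"), drop = FALSE]
}

#' Read / write cohort CSV tables
#'
#' @param cohort data.frame from [simulate_cohort()].
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) read.csv(path)
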