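test_that("model syntax parses into latents, regressions and covariances", {
  m <- sem_model(c("F =~ x1 + x2 + x3", "y ~ F + z", "x2 ~~ x3"))
  expect_equal(m$latents$F, c("x1", "x2", "x3"))
  expect_equal(m$regressions, list(c("y", "F"), c("y", "z")))
  expect_equal(m$covariances, list(c("x2", "x3")))
  expect_error(sem_model("x1 ++ x2"), "parse")
})

test_that("the battery models have one fixed marker per latent and the right df", {
  mods <- build_paper_models()
  vars <- c("WiN", "SiB", "SSQ", "AFG_fixed", "AFG_low", "AFG_high",
            "PTA", "age")
  dfs <- c(model1 = 5, model2 = 5, model3 = 9, cfa = 7)
  for (nm in names(mods)) {
    sk <- afgtools:::sem_skeleton(mods[[nm]], vars)
    fixed <- sk$par[!sk$par$free & sk$par$mat == "A", ]
    # exactly one fixed-to-1 loading per latent
    expect_equal(sort(fixed$col), sort(sk$latents))
    expect_true(all(fixed$value == 1))
    p <- length(sk$obs)
    expect_equal(p * (p + 1) / 2 - sum(sk$par$free), unname(dfs[nm]),
                 info = nm)
  }
  # the combined model drops the self-report measure entirely
  sk3 <- afgtools:::sem_skeleton(mods$model3, vars)
  expect_false("SSQ" %in% sk3$obs)
})

test_that("a just-identified one-factor model matches its closed-form solution", {
  # 3 indicators, loadings (1, .8, .65), factor var 2, residuals (.5, .7, .9)
  Sigma <- matrix(c(2.5, 1.6, 1.3,
                    1.6, 1.98, 1.04,
                    1.3, 1.04, 1.745), 3, 3,
                  dimnames = list(NULL, c("x1", "x2", "x3")))
  d <- as.data.frame(mvr_exact(400, Sigma))
  fit <- sem_fit(sem_model("F =~ x1 + x2 + x3"), d)
  S <- fit$S
  # algebraic oracle from the three covariance equations
  psi <- S[1, 2] * S[1, 3] / S[2, 3]
  l2 <- S[2, 3] / S[1, 3]
  l3 <- S[2, 3] / S[1, 2]
  est <- setNames(fit$estimates$estimate, fit$estimates$label)
  expect_equal(unname(est["F=~x2"]), l2, tolerance = 1e-5)
  expect_equal(unname(est["F=~x3"]), l3, tolerance = 1e-5)
  expect_equal(unname(est["var(F)"]), psi, tolerance = 1e-4)
  expect_equal(unname(est["var(x1)"]), S[1, 1] - psi, tolerance = 1e-4)
  # saturated in moments: df = 0 and perfect fit
  expect_equal(fit$df, 0)
  expect_lt(fit$chi2, 1e-4)
  expect_equal(unname(fit$fit_indices["RMSEA"]), 0)
})

test_that("standardized loadings are recovered from simulated indicators", {
  lam <- c(0.8, 0.7, 0.6)
  set.seed(16)
  f <- rnorm(10000)
  d <- data.frame(x1 = lam[1] * f + sqrt(1 - lam[1]^2) * rnorm(10000),
                  x2 = lam[2] * f + sqrt(1 - lam[2]^2) * rnorm(10000),
                  x3 = lam[3] * f + sqrt(1 - lam[3]^2) * rnorm(10000))
  fit <- sem_fit(sem_model("F =~ x1 + x2 + x3"), d)
  std <- standardized_paths(fit)
  expect_equal(unname(std[c("F=~x1", "F=~x2", "F=~x3")]), lam,
               tolerance = 0.03)
})

test_that("a saturated path model has chi2 = 0 and df = 0", {
  set.seed(17)
  d <- as.data.frame(matrix(rnorm(300), 100, 3,
                            dimnames = list(NULL, c("y", "a", "b"))))
  fit <- sem_fit(sem_model(c("y ~ a + b", "a ~~ b")), d)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi2, 1e-5)
  expect_equal(unname(fit$fit_indices["CFI"]), 1)
  expect_true(is.na(fit$fit_indices["TLI"]))
})

test_that("fit indices match an independent longhand evaluation", {
  # toy 3-variable case evaluated spreadsheet-style
  S <- matrix(c(1.0, 0.52, 0.31,
                0.52, 1.3, 0.44,
                0.31, 0.44, 0.9), 3, 3)
  Sig <- matrix(c(1.02, 0.48, 0.33,
                  0.48, 1.27, 0.41,
                  0.31, 0.41, 0.93), 3, 3)
  Sig[1, 3] <- 0.33; Sig[3, 1] <- 0.33
  chi2 <- 12; df <- 5; chi2_b <- 100; df_b <- 6; n <- 101
  fi <- fit_indices(chi2, df, chi2_b, df_b, n, S, Sig)
  expect_equal(unname(fi["CFI"]), 1 - (12 - 5) / (100 - 6))
  expect_equal(unname(fi["TLI"]),
               ((100 / 6) - (12 / 5)) / ((100 / 6) - 1))
  expect_equal(unname(fi["RMSEA"]), sqrt((12 - 5) / (5 * 100)))
  acc <- 0
  for (i in 1:3) for (j in i:3)
    acc <- acc + ((S[i, j] - Sig[i, j]) / sqrt(S[i, i] * S[j, j]))^2
  expect_equal(unname(fi["SRMR"]), sqrt(acc / 6))

  # limits: chi2 = df gives RMSEA 0 and CFI 1; S = Sigma gives SRMR 0
  fi2 <- fit_indices(5, 5, 100, 6, 101, S, S)
  expect_equal(unname(fi2["RMSEA"]), 0)
  expect_equal(unname(fi2["CFI"]), 1)
  expect_equal(unname(fi2["SRMR"]), 0)
})

test_that("chi-squared is invariant to the choice of scaling indicator", {
  set.seed(18)
  d <- screen_cohort(simulate_cohort(cohort_params(n = 1500)))
  m <- build_paper_models()$model1
  f1 <- sem_fit(m, d, flip = "WiN", standardize = "WiN")
  f2 <- sem_fit(swap_scaling(m, "AFG", "AFG_low"), d, flip = "WiN",
                standardize = "WiN")
  f3 <- sem_fit(swap_scaling(m, "AFG", "AFG_high"), d, flip = "WiN",
                standardize = "WiN")
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-6)
  expect_equal(f3$chi2, f1$chi2, tolerance = 1e-6)
  expect_equal(f2$fit_indices, f1$fit_indices, tolerance = 1e-5)
})

test_that("negating a flip variable flips its paths and keeps the fit", {
  set.seed(19)
  d <- screen_cohort(simulate_cohort(cohort_params(n = 1500)))
  m <- build_paper_models()$model1
  f_raw <- sem_fit(m, d, standardize = "WiN")
  f_flip <- sem_fit(m, d, flip = "WiN", standardize = "WiN")
  expect_equal(f_flip$chi2, f_raw$chi2, tolerance = 1e-6)
  expect_equal(f_flip$fit_indices, f_raw$fit_indices, tolerance = 1e-5)
  sp_raw <- standardized_paths(f_raw)
  sp_flip <- standardized_paths(f_flip)
  win_paths <- grep("WiN~", names(sp_raw), value = TRUE, fixed = TRUE)
  expect_equal(sp_flip[win_paths], -sp_raw[win_paths], tolerance = 1e-4)
  other <- setdiff(names(sp_raw), win_paths)
  expect_equal(sp_flip[other], sp_raw[other], tolerance = 1e-4)
})

test_that("subsample bootstrap is degenerate at frac = 1 and seed-stable", {
  set.seed(20)
  d <- screen_cohort(simulate_cohort(cohort_params(n = 600)))
  m <- build_paper_models()$model1
  bt <- bootstrap_rmsea(m, d, frac = 1, reps = 4, flip = "WiN",
                        standardize = "WiN")
  expect_equal(length(bt$rmsea) + bt$n_failed, 4)
  expect_lt(diff(range(bt$rmsea)), 1e-10)

  run <- function() {
    set.seed(55)
    bootstrap_rmsea(m, d, frac = 0.95, reps = 5, flip = "WiN",
                    standardize = "WiN")$rmsea
  }
  expect_identical(run(), run())

  # confidence intervals follow mean +/- 1.96 sd of the replicates
  set.seed(56)
  bt2 <- bootstrap_rmsea(m, d, frac = 0.9, reps = 8, flip = "WiN",
                         standardize = "WiN")
  mu <- colMeans(bt2$paths); sdv <- apply(bt2$paths, 2, sd)
  expect_equal(bt2$ci$lower, unname(mu - 1.96 * sdv))
  expect_equal(bt2$ci$upper, unname(mu + 1.96 * sdv))
})

test_that("afg_sem_report mirrors the fit-index roster", {
  set.seed(21)
  d <- screen_cohort(simulate_cohort(cohort_params(n = 800)))
  rep <- afg_sem_report(d, "model1")
  expect_named(rep$indices, c("chi2", "df", "p", "CFI", "TLI", "RMSEA",
                              "SRMR", "adj_r2"))
  expect_true(rep$fit$converged)
  expect_gt(rep$indices["adj_r2"], 0)
  expect_true(all(c("AFG~age", "AFG~PTA", "WiN~AFG") %in% names(rep$paths)))
})
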