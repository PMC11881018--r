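# Maximum-likelihood structural equation modelling: lavaan-like model syntax,
# RAM parameterization, F_ML minimization, fit indices, subsample bootstrap.

#' Define a structural equation model
#'
#' Accepts a small lavaan-like syntax, one statement per element:
#' `"F =~ x1 + x2 + x3"` defines latent `F` with indicators `x1..x3` (the
#' first indicator is the scaling variable, its loading fixed to 1 -- Fixed
#' Marker identification); `"y ~ a + b"` regresses `y` on `a` and `b`;
#' `"u ~~ v"` frees the (residual) covariance of `u` and `v`. Variances of
#' all variables (residual variances for endogenous ones) are always free.
#'
#' @param syntax character vector of model statements.
#' @return A `sem_model` with parsed `latents`, `regressions`, `covariances`.
#' @export
#' @examples
#' sem_model(c("AFG =~ AFG_fixed + AFG_low + AFG_high",
#'             "WiN ~ AFG + PTA + age",
#'             "AFG ~ age + PTA",
#'             "AFG_low ~~ AFG_high", "age ~~ PTA"))
sem_model <- function(syntax) {
  trim <- function(s) gsub("^\\s+|\\s+$", "", s)
  latents <- list(); regressions <- list(); covariances <- list()
  for (line in syntax) {
    line <- trim(line)
    if (line == "" || startsWith(line, "#")) next
    if (grepl("=~", line, fixed = TRUE)) {
      pp <- trim(strsplit(line, "=~", fixed = TRUE)[[1]])
      inds <- trim(strsplit(pp[2], "+", fixed = TRUE)[[1]])
      latents[[pp[1]]] <- inds
    } else if (grepl("~~", line, fixed = TRUE)) {
      pp <- trim(strsplit(line, "~~", fixed = TRUE)[[1]])
      covariances[[length(covariances) + 1]] <- pp
    } else if (grepl("~", line, fixed = TRUE)) {
      pp <- trim(strsplit(line, "~", fixed = TRUE)[[1]])
      preds <- trim(strsplit(pp[2], "+", fixed = TRUE)[[1]])
      for (pr in preds)
        regressions[[length(regressions) + 1]] <- c(pp[1], pr)
    } else stop("cannot parse model statement: ", line)
  }
  if (length(latents))
    stopifnot(!anyDuplicated(names(latents)))
  structure(list(latents = latents, regressions = regressions,
                 covariances = covariances, syntax = syntax),
            class = "sem_model")
}

#' @export
print.sem_model <- function(x, ...) {
  cat("<sem_model>\n")
  for (s in x$syntax) cat(" ", s, "\n")
  invisible(x)
}

#' Swap the scaling (fixed-marker) indicator of a latent variable
#'
#' Rebuilds the model with `indicator` listed first for `latent`, making it
#' the scaling variable whose loading is fixed to 1. Model fit (chi-squared)
#' is invariant to this choice under maximum likelihood.
#'
#' @param model a [sem_model()].
#' @param latent latent variable name.
#' @param indicator indicator to promote to scaling variable.
#' @return A `sem_model`.
#' @export
swap_scaling <- function(model, latent, indicator) {
  inds <- model$latents[[latent]]
  stopifnot(!is.null(inds), indicator %in% inds)
  model$latents[[latent]] <- c(indicator, setdiff(inds, indicator))
  model$syntax <- vapply(model$syntax, function(s) {
    if (grepl(paste0("^\\s*", latent, "\\s*=~"), s))
      paste(latent, "=~", paste(model$latents[[latent]], collapse = " + "))
    else s
  }, "")
  model
}

# Build the parameter table and RAM skeleton for a model + observed data names.
sem_skeleton <- function(model, obs_vars) {
  latents <- names(model$latents)
  inds <- unique(unlist(model$latents))
  reg_vars <- unique(unlist(model$regressions))
  cov_vars <- unique(unlist(model$covariances))
  used <- unique(c(inds, reg_vars, cov_vars))
  obs <- intersect(obs_vars, setdiff(used, latents))
  missing <- setdiff(setdiff(used, latents), obs_vars)
  if (length(missing))
    stop("model variables not in data: ", paste(missing, collapse = ", "))
  all_vars <- c(obs, latents)
  nv <- length(all_vars)
  par <- NULL
  add <- function(mat, r, c, free, value, label)
    data.frame(mat = mat, row = r, col = c, free = free, value = value,
               label = label, stringsAsFactors = FALSE)
  # loadings: first indicator fixed to 1
  for (L in latents) {
    ii <- model$latents[[L]]
    par <- rbind(par, add("A", ii[1], L, FALSE, 1,
                          paste0(L, "=~", ii[1])))
    for (x in ii[-1])
      par <- rbind(par, add("A", x, L, TRUE, NA, paste0(L, "=~", x)))
  }
  for (rg in model$regressions)
    par <- rbind(par, add("A", rg[1], rg[2], TRUE, NA,
                          paste0(rg[1], "~", rg[2])))
  for (cv in model$covariances)
    par <- rbind(par, add("S", cv[1], cv[2], TRUE, NA,
                          paste0(cv[1], "~~", cv[2])))
  for (v in all_vars)
    par <- rbind(par, add("S", v, v, TRUE, NA, paste0("var(", v, ")")))
  # endogenous = indicator or regression outcome
  outcomes <- unique(vapply(model$regressions, `[`, "", 1))
  endo <- unique(c(inds, outcomes))
  # precomputed linear indices for fast matrix filling in the objective
  ri <- match(par$row, all_vars); ci <- match(par$col, all_vars)
  isA <- par$mat == "A"
  list(obs = obs, latents = latents, all_vars = all_vars, nv = nv,
       par = par, endo = endo, outcomes = outcomes,
       vals0 = par$value, free_idx = which(par$free),
       iA = (ci[isA] - 1L) * nv + ri[isA], whichA = which(isA),
       iS1 = (ci[!isA] - 1L) * nv + ri[!isA],
       iS2 = (ri[!isA] - 1L) * nv + ci[!isA], whichS = which(!isA),
       obs_idx = match(obs, all_vars))
}

# Fill RAM matrices A and S from a parameter vector
ram_matrices <- function(sk, theta) {
  vals <- sk$vals0
  vals[sk$free_idx] <- theta
  A <- S <- matrix(0, sk$nv, sk$nv, dimnames = list(sk$all_vars, sk$all_vars))
  A[sk$iA] <- vals[sk$whichA]
  S[sk$iS1] <- vals[sk$whichS]
  S[sk$iS2] <- vals[sk$whichS]
  list(A = A, S = S)
}

# Model-implied covariance of all variables (observed block via sk$obs)
implied_cov <- function(sk, theta) {
  m <- ram_matrices(sk, theta)
  Binv <- solve(diag(sk$nv) - m$A)
  Binv %*% m$S %*% t(Binv)
}

# ML discrepancy F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p
sem_objective <- function(sk, S_samp, const) {
  function(theta) {
    Sig <- tryCatch(implied_cov(sk, theta)[sk$obs, sk$obs],
                    error = function(e) NULL)
    if (is.null(Sig)) return(1e10)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S_samp) - const
  }
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, 0)
}

sem_start_values <- function(sk, S_samp) {
  start <- numeric(sum(sk$par$free))
  free <- which(sk$par$free)
  for (j in seq_along(free)) {
    p <- sk$par[free[j], ]
    if (p$mat == "A" && grepl("=~", p$label, fixed = TRUE)) {
      # loading start: regression of indicator on the scaling indicator
      L <- p$col
      scalev <- sk$par$row[sk$par$mat == "A" & sk$par$col == L & !sk$par$free][1]
      start[j] <- S_samp[p$row, scalev] / S_samp[scalev, scalev]
    } else if (p$mat == "A") {
      start[j] <- 0
    } else if (p$row == p$col) {
      v <- p$row
      if (v %in% sk$latents) {
        scalev <- sk$par$row[sk$par$mat == "A" & sk$par$col == v & !sk$par$free][1]
        start[j] <- 0.5 * S_samp[scalev, scalev]
      } else if (v %in% sk$endo) {
        start[j] <- 0.5 * S_samp[v, v]
      } else start[j] <- S_samp[v, v]
    } else {
      # exogenous observed pairs start at the sample covariance; residual
      # covariances start at zero (keeps the start inside the PD region)
      exo_pair <- !(p$row %in% c(sk$latents, sk$endo)) &&
        !(p$col %in% c(sk$latents, sk$endo))
      start[j] <- if (exo_pair) S_samp[p$row, p$col] else 0
    }
  }
  start
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F(theta) = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free parameters of the RAM-parameterized model, where `S` is the
#' sample covariance and `Sigma(theta)` the model-implied covariance.
#' `chi2 = (n - 1) * F_min`; standard errors come from the inverse observed
#' information; the standardized solution rescales estimates by the implied
#' standard deviations. Optimization uses `nlminb` with a BFGS polish and up
#' to five jittered restarts on non-convergence.
#'
#' @param model a [sem_model()].
#' @param data data.frame containing every observed model variable.
#' @param flip variables to negate before fitting (score-direction
#'   harmonization, e.g. proportion-correct measures among thresholds).
#' @param standardize variables to z-score before fitting (scale
#'   harmonization; affects unstandardized estimates only).
#' @param grad_tol gradient-norm tolerance for the converged flag (the
#'   optimizer itself runs to machine-level relative tolerance; this flag
#'   guards against plateau stops).
#' @param restarts maximum jittered restarts.
#' @return A `sem_fit` object: `estimates` table (estimate, SE, z, p,
#'   standardized), `chi2`, `df`, `p_value`, `fit_indices` (CFI, TLI, RMSEA,
#'   SRMR), `r2`/`adj_r2` per structural outcome, `converged`, `heywood`,
#'   `n`, plus the implied and sample covariances.
#' @export
sem_fit <- function(model, data, flip = character(), standardize = character(),
                    grad_tol = 1e-3, restarts = 5) {
  stopifnot(inherits(model, "sem_model"), is.data.frame(data))
  for (v in flip) data[[v]] <- -data[[v]]
  for (v in standardize) data[[v]] <- as.numeric(scale(data[[v]]))
  sk <- sem_skeleton(model, names(data))
  X <- as.matrix(data[sk$obs])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  p <- length(sk$obs)
  if (n <= p) stop("need more rows than observed variables")
  S_samp <- cov(X)
  n_free <- sum(sk$par$free)
  df <- p * (p + 1) / 2 - n_free
  if (df < 0) stop("model not identified: df < 0")
  const <- determinant(S_samp)$modulus[1] + p
  fml <- sem_objective(sk, S_samp, const)
  start <- sem_start_values(sk, S_samp)
  best <- NULL
  for (k in 0:restarts) {
    st <- if (k == 0) start else start * runif(length(start), 0.7, 1.3) +
      rnorm(length(start), 0, 0.05)
    o1 <- tryCatch(nlminb(st, fml, control = list(iter.max = 2000,
                                                  rel.tol = 1e-14)),
                   error = function(e) NULL)
    if (is.null(o1)) next
    o2 <- tryCatch(optim(o1$par, fml, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14)),
                   error = function(e) NULL)
    cand <- if (!is.null(o2) && o2$value <= o1$objective)
      list(par = o2$par, value = o2$value)
    else list(par = o1$par, value = o1$objective)
    gn <- sqrt(sum(num_grad(fml, cand$par)^2))
    cand$grad_norm <- gn
    if (is.null(best) || cand$value < best$value - 1e-12) best <- cand
    if (best$grad_norm < grad_tol) break
  }
  if (is.null(best)) stop("SEM optimization failed on all starts")
  theta <- best$par
  converged <- best$grad_norm < grad_tol
  if (!converged)
    warning(sprintf("possible non-convergence: gradient norm %.2e", best$grad_norm))
  F_min <- max(best$value, 0)
  chi2 <- (n - 1) * F_min
  # standard errors from the observed information ((n-1)/2 * Hessian of F)
  H <- tryCatch(optim(theta, fml, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1))$hessian,
                error = function(e) NULL)
  se <- rep(NA_real_, length(theta))
  if (!is.null(H)) {
    covt <- tryCatch(solve(H * (n - 1) / 2), error = function(e) NULL)
    if (!is.null(covt)) {
      dg <- diag(covt)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  Sig_all <- implied_cov(sk, theta)
  Sigma <- Sig_all[sk$obs, sk$obs]
  sds <- sqrt(pmax(diag(Sig_all), 0))
  names(sds) <- sk$all_vars
  m <- ram_matrices(sk, theta)
  vals <- sk$par$value
  vals[sk$par$free] <- theta
  std <- vapply(seq_len(nrow(sk$par)), function(k) {
    pp <- sk$par[k, ]
    if (pp$mat == "A") vals[k] * sds[pp$col] / sds[pp$row]
    else if (pp$row == pp$col) vals[k] / (sds[pp$row]^2)
    else vals[k] / (sds[pp$row] * sds[pp$col])
  }, 0)
  est <- data.frame(label = sk$par$label, mat = sk$par$mat,
                    row = sk$par$row, col = sk$par$col,
                    free = sk$par$free, estimate = vals,
                    se = NA_real_, std = std, stringsAsFactors = FALSE)
  est$se[est$free] <- se
  est$z <- est$estimate / est$se
  est$p <- 2 * pnorm(-abs(est$z))
  heywood <- any(vals[sk$par$mat == "S" & sk$par$row == sk$par$col] < 0)
  if (heywood) warning("Heywood case: negative variance estimate")
  # R^2 of structural outcomes
  r2 <- adj_r2 <- setNames(numeric(0), character(0))
  for (v in sk$outcomes) {
    tot <- Sig_all[v, v]
    res <- m$S[v, v]
    k_pred <- sum(vapply(model$regressions, function(rg) rg[1] == v, TRUE))
    r2v <- 1 - res / tot
    r2 <- c(r2, setNames(r2v, v))
    adj_r2 <- c(adj_r2, setNames(1 - (1 - r2v) * (n - 1) / (n - k_pred - 1), v))
  }
  # baseline (independence) model through the same machinery: free variances
  # only; its ML solution is the diagonal of S
  base_f <- log(prod(diag(S_samp))) + p - const
  chi2_b <- (n - 1) * max(base_f, 0)
  df_b <- p * (p - 1) / 2
  fi <- fit_indices(chi2, df, chi2_b, df_b, n, S_samp, Sigma)
  structure(list(model = model, estimates = est, chi2 = chi2, df = df,
                 p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA,
                 chi2_baseline = chi2_b, df_baseline = df_b,
                 fit_indices = fi, r2 = r2, adj_r2 = adj_r2,
                 converged = converged, heywood = heywood,
                 grad_norm = best$grad_norm, n = n, F_min = F_min,
                 S = S_samp, Sigma = Sigma, Sigma_all = Sig_all,
                 skeleton = sk, theta = theta),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<sem_fit> n = %d, chi2(%d) = %.3f, p = %s%s\n", x$n, x$df,
              x$chi2, format.pval(x$p_value, digits = 3),
              if (x$converged) "" else " [NOT CONVERGED]"))
  fi <- x$fit_indices
  cat(sprintf("  CFI %.3f | TLI %s | RMSEA %.3f | SRMR %.3f\n",
              fi["CFI"], ifelse(is.na(fi["TLI"]), "NA",
                                sprintf("%.3f", fi["TLI"])),
              fi["RMSEA"], fi["SRMR"]))
  if (length(x$adj_r2))
    cat("  adj R2:", paste(sprintf("%s = %.3f", names(x$adj_r2), x$adj_r2),
                           collapse = ", "), "\n")
  ev <- x$estimates[x$estimates$free | x$estimates$mat == "A", ]
  print(ev[, c("label", "estimate", "se", "std", "p")], digits = digits,
        row.names = FALSE)
  invisible(x)
}

#' Extract standardized path coefficients and loadings
#'
#' @param fit a [sem_fit()].
#' @return Named numeric vector of standardized estimates for all directed
#'   parameters (loadings and regressions).
#' @export
standardized_paths <- function(fit) {
  e <- fit$estimates[fit$estimates$mat == "A", ]
  setNames(e$std, e$label)
}

#' SEM fit indices
#'
#' CFI, TLI, RMSEA and SRMR from the fitted and baseline (independence)
#' chi-squared statistics:
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`;
#' `TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`;
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df * (n - 1)))`;
#' `SRMR` is the root mean square of the standardized covariance residuals
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)` over the `p(p+1)/2` unique moments.
#' With `df = 0` (saturated model) RMSEA is defined as 0 and TLI is `NA`.
#'
#' @param chi2,df fitted model chi-squared and degrees of freedom.
#' @param chi2_baseline,df_baseline independence-model values.
#' @param n sample size.
#' @param S,Sigma sample and implied covariance of the observed variables.
#' @return Named vector `c(CFI, TLI, RMSEA, SRMR)`.
#' @export
fit_indices <- function(chi2, df, chi2_baseline, df_baseline, n, S, Sigma) {
  d <- max(chi2 - df, 0)
  db <- max(chi2_baseline - df_baseline, 0)
  cfi <- 1 - (if (max(d, db) > 0) d / max(db, d) else 0)
  tli <- if (df > 0 && df_baseline > 0) {
    rb <- chi2_baseline / df_baseline
    ((rb - chi2 / df) / (rb - 1))
  } else NA_real_
  rmsea <- if (df > 0) sqrt(d / (df * (n - 1))) else 0
  sdm <- sqrt(diag(S))
  R <- (S - Sigma) / tcrossprod(sdm)
  srmr <- sqrt(mean(R[upper.tri(R, diag = TRUE)]^2))
  c(CFI = cfi, TLI = tli, RMSEA = rmsea, SRMR = srmr)
}

#' Subsample bootstrap of RMSEA and path estimates
#'
#' Refits the model on `reps` subsamples of `floor(frac * n)` rows drawn
#' without replacement, returning the RMSEA distribution and per-path
#' confidence intervals `mean +/- 1.96 * sd` of the bootstrapped standardized
#' estimates. Non-convergent replicates are excluded and counted.
#'
#' @param model a [sem_model()].
#' @param data data.frame.
#' @param frac subsample fraction in `(0, 1]` (default 0.95).
#' @param reps number of replicates (default 100).
#' @inheritParams sem_fit
#' @return List with `rmsea` (vector), `paths` (replicate x path matrix),
#'   `ci` (data.frame: mean, lower, upper) and `n_failed`.
#' @export
bootstrap_rmsea <- function(model, data, frac = 0.95, reps = 100,
                            flip = character(), standardize = character()) {
  stopifnot(frac > 0, frac <= 1, reps >= 1)
  n <- nrow(data)
  m <- floor(frac * n)
  rmsea <- numeric(0); paths <- NULL; failed <- 0L
  for (r in seq_len(reps)) {
    idx <- if (m == n) seq_len(n) else sample.int(n, m)
    ft <- tryCatch(
      suppressWarnings(sem_fit(model, data[idx, , drop = FALSE], flip = flip,
                               standardize = standardize)),
      error = function(e) NULL)
    if (is.null(ft) || !ft$converged) { failed <- failed + 1L; next }
    rmsea <- c(rmsea, unname(ft$fit_indices["RMSEA"]))
    paths <- rbind(paths, standardized_paths(ft))
  }
  ci <- NULL
  if (!is.null(paths)) {
    mu <- colMeans(paths); sdv <- apply(paths, 2, sd)
    ci <- data.frame(path = colnames(paths), mean = mu,
                     lower = mu - 1.96 * sdv, upper = mu + 1.96 * sdv,
                     row.names = NULL)
  }
  list(rmsea = rmsea, paths = paths, ci = ci, n_failed = failed)
}

#' The battery's SEM and CFA model specifications
#'
#' Four ready-made [sem_model()]s: `model1` regresses the word-in-noise score
#' (WiN) on latent figure-ground ability (AFG: indicators AFG_fixed
#' \[scaling\], AFG_low, AFG_high, with a low-high residual covariance), PTA
#' and age; `model2` does the same for the sentence-in-babble threshold
#' (SiB); `model3` combines WiN \[scaling\] and SiB as indicators of a latent
#' speech-in-noise ability (SIN) regressed on AFG, PTA and age; `cfa` is the
#' two-factor measurement model (SIN including SSQ, AFG) used to screen
#' indicator quality. All models let the exogenous age and PTA covary and
#' include age/PTA paths into AFG. When fitting, flip WiN so that higher
#' scores mean worse performance ([afg_sem_report()] does this).
#'
#' @return Named list of `sem_model` objects.
#' @export
build_paper_models <- function() {
  afg <- c("AFG =~ AFG_fixed + AFG_low + AFG_high",
           "AFG ~ age + PTA",
           "AFG_low ~~ AFG_high",
           "age ~~ PTA")
  list(
    model1 = sem_model(c(afg, "WiN ~ AFG + PTA + age")),
    model2 = sem_model(c(afg, "SiB ~ AFG + PTA + age")),
    model3 = sem_model(c("SIN =~ WiN + SiB",
                         afg, "SIN ~ AFG + PTA + age")),
    cfa = sem_model(c("SIN =~ WiN + SiB + SSQ",
                      "AFG =~ AFG_fixed + AFG_low + AFG_high",
                      "AFG_low ~~ AFG_high",
                      "SIN ~~ AFG")))
}

#' Fit one of the battery's models to a cohort and report fit-index table
#'
#' Convenience pipeline: z-scores WiN, multiplies it by -1 so that higher
#' scores indicate worse performance on every measure, fits the requested
#' model and returns the fit-index roster (chi2, p, RMSEA, CFI, TLI, SRMR,
#' adjusted R-squared of the speech outcome) plus the standardized path
#' table.
#'
#' @param cohort data.frame with the battery columns.
#' @param which `"model1"`, `"model2"`, `"model3"` or `"cfa"`.
#' @return List with `fit` (the [sem_fit()]), `indices` (named vector) and
#'   `paths` (standardized estimates).
#' @export
afg_sem_report <- function(cohort, which = c("model1", "model2", "model3",
                                             "cfa")) {
  which <- match.arg(which)
  model <- build_paper_models()[[which]]
  fit <- sem_fit(model, cohort, flip = "WiN", standardize = "WiN")
  out <- switch(which, model1 = "WiN", model2 = "SiB", model3 = "SIN",
                cfa = NULL)
  indices <- c(chi2 = fit$chi2, df = fit$df, p = fit$p_value,
               fit$fit_indices,
               adj_r2 = if (!is.null(out)) unname(fit$adj_r2[out]) else NA)
  list(fit = fit, indices = indices, paths = standardized_paths(fit))
}
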