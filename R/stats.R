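# Rank correlations, Holm-Bonferroni correction and stepwise regression --
# the univariate half of the analysis pipeline.

#' Spearman correlation matrix with p-values
#'
#' Rank-based correlations on pairwise-complete data (average ranks for
#' ties), with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on the pairwise sample size.
#' Constant columns yield `NA` entries with a warning.
#'
#' @param data data.frame of numeric scores.
#' @param vars columns to correlate (default: all numeric columns).
#' @return List with matrices `rho`, `p` and pairwise `n`.
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_cohort(cohort_params(n = 50))
#' sp <- spearman_matrix(d, c("age", "PTA", "WiN"))
#' round(sp$rho, 2)
spearman_matrix <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, TRUE)]
  x <- as.matrix(data[vars])
  if (nrow(x) < 3 || sum(stats::complete.cases(x)) < 3)
    stop("need at least 3 complete rows")
  k <- length(vars)
  rho <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    ok <- stats::complete.cases(x[, c(i, j)])
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n >= 3 && sd(x[ok, i]) > 0 && sd(x[ok, j]) > 0) {
      r <- cor(x[ok, i], x[ok, j], method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), n - 2)
    } else {
      warning(sprintf("undefined correlation for (%s, %s): constant column or n < 3",
                      vars[i], vars[j]))
    }
  }
  diag(nmat) <- colSums(!is.na(x))
  list(rho = rho, p = p, n = nmat)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th by `m - i + 1`, enforces
#' monotonicity and caps at 1. `m` defaults to the number of p-values but can
#' be set to the size of the full comparison family (e.g. 21 unique pairs for
#' a 7-variable correlation matrix).
#'
#' @param pvals p-values in `[0, 1]`.
#' @param m size of the comparison family (>= `length(pvals)`).
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.03, 0.04))
holm_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE), m >= length(pvals))
  stats::p.adjust(pvals, method = "holm", n = m)
}

#' Correlation report for an AFG cohort table
#'
#' Spearman matrix over the seven battery measures with Holm-Bonferroni
#' corrected p-values (family = 21 unique pairs).
#'
#' @param cohort data.frame with the battery score columns.
#' @param vars variable set (default: the seven battery measures).
#' @return List with `rho`, `p_raw`, `p_holm` matrices.
#' @export
correlation_report <- function(cohort,
                               vars = c("SiB", "WiN", "PTA", "age",
                                        "AFG_high", "AFG_low", "AFG_fixed")) {
  sp <- spearman_matrix(cohort, vars)
  ut <- upper.tri(sp$p)
  m <- sum(ut)
  p_holm <- sp$p
  p_holm[ut] <- holm_adjust(sp$p[ut], m = m)
  p_holm[lower.tri(p_holm)] <- t(p_holm)[lower.tri(p_holm)]
  list(rho = sp$rho, p_raw = sp$p, p_holm = p_holm, n = sp$n)
}

#' Stepwise (forward with backward elimination) regression
#'
#' SPSS-style stepwise OLS: at each step the candidate with the smallest
#' partial-F p-value enters if `p < p_enter` (ties broken by larger absolute
#' partial correlation); after each entry, included predictors with
#' `p > p_remove` are dropped. Reports per accepted step the model's adjusted
#' R-squared and the entering variable's standardized beta and p-value.
#'
#' @param data data.frame.
#' @param outcome response column name.
#' @param candidates candidate predictor names.
#' @param p_enter,p_remove entry / removal thresholds (defaults 0.05 / 0.10).
#' @return A `stepwise_result`: `steps` data.frame (variable, action,
#'   adj_r2, std_beta, p), `included` (final predictor set) and the final
#'   `lm` fit.
#' @export
stepwise_fit <- function(data, outcome, candidates,
                         p_enter = 0.05, p_remove = 0.10) {
  data <- data[stats::complete.cases(data[c(outcome, candidates)]),
               c(outcome, candidates)]
  n <- nrow(data)
  if (n <= length(candidates) + 2) stop("too few rows for stepwise selection")
  # drop collinear candidates up front
  X <- scale(as.matrix(data[candidates]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- candidates[-qrX$pivot[seq_len(qrX$rank)]]
    warning("dropping collinear candidate(s): ", paste(drop, collapse = ", "))
    candidates <- setdiff(candidates, drop)
  }
  zdata <- as.data.frame(scale(data))          # for standardized betas
  coef_p <- function(vars, v) {
    m <- lm(stats::reformulate(vars, outcome), data)
    s <- summary(m)$coefficients
    list(p = s[v, 4], t = abs(s[v, 3]), model = m)
  }
  included <- character()
  steps <- NULL
  repeat {
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    cand <- lapply(pool, function(v) coef_p(c(included, v), v))
    ps <- vapply(cand, `[[`, 0, "p")
    ts <- vapply(cand, `[[`, 0, "t")
    best <- order(ps, -ts)[1]
    if (ps[best] >= p_enter) break
    entered <- pool[best]
    included <- c(included, entered)
    zfit <- lm(stats::reformulate(included, outcome), zdata)
    fit <- lm(stats::reformulate(included, outcome), data)
    sm <- summary(fit)
    steps <- rbind(steps, data.frame(
      variable = entered, action = "enter",
      adj_r2 = sm$adj.r.squared,
      std_beta = coef(zfit)[entered],
      p = sm$coefficients[entered, 4], row.names = NULL))
    # backward pass
    repeat {
      if (length(included) < 2) break
      sm <- summary(lm(stats::reformulate(included, outcome), data))
      pv <- sm$coefficients[included, 4]
      worst <- names(which.max(pv))
      if (pv[worst] <= p_remove || worst == entered) break
      included <- setdiff(included, worst)
      sm2 <- summary(lm(stats::reformulate(included, outcome), data))
      steps <- rbind(steps, data.frame(
        variable = worst, action = "remove",
        adj_r2 = sm2$adj.r.squared, std_beta = NA_real_,
        p = pv[worst], row.names = NULL))
    }
  }
  final <- if (length(included))
    lm(stats::reformulate(included, outcome), data)
  else lm(stats::reformulate("1", outcome), data)
  structure(list(steps = steps, included = included, fit = final,
                 outcome = outcome, n = n),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> %s ~ %s (n = %d)\n", x$outcome,
              if (length(x$included)) paste(x$included, collapse = " + ")
              else "(empty model)", x$n))
  if (!is.null(x$steps)) print(x$steps, digits = 3)
  invisible(x)
}
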