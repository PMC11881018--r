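# Shared test fixtures, built in code.

# contour with known voiced/unvoiced structure
toy_contour <- function() {
  pitch_contour(c(rep(120, 10), rep(NA, 5), seq(100, 107, 1)), frame_rate = 100)
}

# multivariate normal draw with exact sample moments (oracle-style fixtures)
mvr_exact <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  x <- MASS::mvrnorm(n, mu = rep(0, ncol(Sigma)), Sigma = Sigma,
                     empirical = TRUE)
  colnames(x) <- colnames(Sigma)
  x
}

# quiet SEM fit (suppress possible Heywood warnings in stress cases)
fit_quiet <- function(...) suppressWarnings(sem_fit(...))
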