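# Shared fixtures and independent closed-form oracles for the test suite.
# The oracles are written directly from the textbook formulas (base-R mean/
# var/cov and the classical distribution functions) so they never share code
# with the model-fitting path they check.

toy_df <- function() data.frame(y1 = c(1, 2, 3, 4), y2 = c(2, 4, 5, 7))

# Classical paired t-test from first principles.
oracle_ttest <- function(y1, y2) {
  d <- y2 - y1
  n <- length(d)
  se <- sd(d) / sqrt(n)
  t <- mean(d) / se
  list(d = mean(d), se = se, t = t, df = n - 1,
       p = 2 * pt(-abs(t), n - 1))
}

# OLS regression of the difference score on baseline: the self-feedback path.
oracle_sfm <- function(y1, y2) {
  d <- y2 - y1
  n <- length(d)
  y1c <- y1 - mean(y1)
  gamma <- cov(y1c, d) / var(y1c)
  r2 <- cor(y1, d)^2
  psi <- var(d) * (1 - r2)
  se <- sqrt(psi / n)
  cr <- mean(d) / se
  list(gamma = gamma, alpha = mean(d), psi = psi, se = se, cr = cr,
       p = 2 * pnorm(-abs(cr)))
}

# Likelihood-ratio chi-square of the "change unrelated to baseline"
# constraint: -(n-1) log(1 - r^2) with r the baseline-difference correlation.
oracle_gamma0_chisq <- function(y1, y2) {
  r2 <- cor(y1, y2 - y1)^2
  -(length(y1) - 1) * log(1 - r2)
}

# Bivariate normal draw without using the package generator.
rbvn <- function(n, mu1 = 0, mu2 = 0, s1 = 1, s2 = 1, rho = 0.5) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(y1 = mu1 + s1 * z1, y2 = mu2 + s2 * z2)
}
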