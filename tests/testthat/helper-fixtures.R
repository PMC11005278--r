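# Shared fixtures and independent oracles used across test files.

# Minimal exposure-only configuration: no covariates, no spouse records,
# no missingness, so n_analytic == n_raw. Used where a criterion fixes
# only the sample size and the exposure/outcome truth.
minimal_config <- function(n_raw, beta4, seed,
                           p_fh = 0.1433, p_ht = 0.2698,
                           or_fh_ht = 1.5) {
  sim_config(n_raw = n_raw, p_fh = p_fh, p_ht = p_ht,
             or_fh_ht = or_fh_ht,
             beta = c("(Intercept)" = beta4[1], d01 = beta4[2],
                      d10 = beta4[3], d11 = beta4[4]),
             covariate_spec = list(), frac_under45 = 0,
             missing_rates = c(outcome_dx = 0), seed = seed)
}

# Unadjusted joint-exposure fit of a (complete) cohort table.
fit_joint <- function(tab, outcome = "outcome_dx", fh = "fh_any",
                      ht = "ht_self", weights = tab$weight) {
  je <- encode_joint_exposure(tab[[fh]], tab[[ht]])
  X <- cbind("(Intercept)" = 1, je$dummies)
  fit_weighted_logit(tab[[outcome]], X, weights)
}

# Independent GLM oracle: coefficients from stats::glm and a sandwich
# standard error built from glm's own unscaled covariance (bread) and the
# direct weighted-score outer product (meat), never touching the package's
# IRLS path.
glm_oracle <- function(y, X, w) {
  w_norm <- w / mean(w)
  dat <- data.frame(y = y)
  g <- stats::glm(y ~ X - 1, family = stats::quasibinomial(),
                  weights = w_norm, data = dat,
                  control = list(epsilon = 1e-14, maxit = 100))
  p <- g$fitted.values
  bread <- summary(g)$cov.unscaled  # glm's own (X'WX)^{-1}
  scores <- X * (w_norm * (y - p))
  meat <- crossprod(scores)
  list(coef = unname(g$coefficients),
       se_sandwich = unname(sqrt(diag(bread %*% meat %*% bread))))
}

# Independent 1-D root-bracketing oracle for the 2x2 joint distribution.
joint_cells_oracle <- function(p_a, p_b, or_ab) {
  f <- function(p11) {
    p10 <- p_a - p11; p01 <- p_b - p11; p00 <- 1 - p_a - p_b + p11
    p11 * p00 / (p10 * p01) - or_ab
  }
  lo <- max(0, p_a + p_b - 1) + 1e-12
  hi <- min(p_a, p_b) - 1e-12
  p11 <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  c(p00 = 1 - p_a - p_b + p11, p01 = p_b - p11, p10 = p_a - p11,
    p11 = p11)
}
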