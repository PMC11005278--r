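# RERI, AP, S point measures, delta-method and bootstrap intervals,
# classification.

# Published odds-ratio triples (or11, or10, or01) and the values their
# reports print; the internally inconsistent unadjusted section is kept
# out (see published_joint_ors()$consistent).
published_cases <- list(
  list(or = c(19.57, 3.55, 6.34), reri = 10.68, ap = 0.55, s = 2.35),
  list(or = c(24.73, 3.65, 7.58), reri = 14.50, ap = 0.59, s = 2.57),
  list(or = c(17.63, 4.00, 5.93), reri = 8.69, ap = 0.49, s = 2.09)
)

test_that("point measures reproduce the published worked examples", {
  for (cs in published_cases) {
    r <- reri(cs$or[1], cs$or[2], cs$or[3])
    ap <- attributable_proportion(r, cs$or[1])
    s <- synergy_index(cs$or[1], cs$or[2], cs$or[3])
    # printed RERI reflects unrounded coefficients in one section: 0.02 band
    expect_lt(abs(r - cs$reri), 0.02)
    expect_lt(abs(ap - cs$ap), 0.005)
    expect_lt(abs(s - cs$s), 0.01)
  }
  # frozen exact values from the printed inputs
  expect_equal(reri(19.57, 3.55, 6.34), 10.68, tolerance = 1e-12)
  expect_equal(reri(24.73, 3.65, 7.58), 14.50, tolerance = 1e-12)
  expect_error(reri(-1, 2, 2), "positive")
  expect_error(attributable_proportion(1, 0), "positive")
})

test_that("additivity null maps to RERI 0, AP 0, S 1", {
  or10 <- 3.2; or01 <- 2.5
  or11 <- or10 + or01 - 1
  expect_equal(reri(or11, or10, or01), 0, tolerance = 1e-12)
  expect_equal(attributable_proportion(0, or11), 0)
  expect_equal(as.numeric(synergy_index(or11, or10, or01)), 1,
               tolerance = 1e-12)
})

test_that("measure identities hold on random OR triples", {
  set.seed(20)
  for (i in 1:200) {
    or <- exp(rnorm(3, 0.5, 0.8))  # (or11, or10, or01)
    r <- reri(or[1], or[2], or[3])
    ap <- attributable_proportion(r, or[1])
    expect_equal(ap * or[1], r, tolerance = 1e-12)
    expect_equal(sign(r), sign(ap))
    s <- synergy_index(or[1], or[2], or[3])
    den <- (or[2] - 1) + (or[3] - 1)
    if (!is.na(s)) {
      expect_equal(r, (s - 1) * den, tolerance = 1e-9)
      if (den > 0) expect_equal(r > 0, s > 1)
    } else {
      expect_true(den <= 0 || or[1] <= 1)
    }
  }
})

test_that("undefined synergy index is flagged, not thrown", {
  s <- synergy_index(0.8, 0.9, 0.7)   # denominator < 0, or11 < 1
  expect_true(is.na(s))
  expect_true(attr(s, "undefined"))
})

test_that("delta-method gradients match central finite differences", {
  set.seed(21)
  measures <- list(
    reri_f = function(b) exp(b[3]) - exp(b[2]) - exp(b[1]) + 1,
    ap_f = function(b) (exp(b[3]) - exp(b[2]) - exp(b[1]) + 1) / exp(b[3]),
    lns_f = function(b) log(exp(b[3]) - 1) - log(exp(b[2]) + exp(b[1]) - 2)
  )
  for (i in 1:20) {
    b <- sort(rnorm(3, 1, 0.5))  # b01 < b10 < b11 keeps S defined
    A <- matrix(rnorm(9, 0, 0.1), 3, 3)
    cov3 <- crossprod(A) + diag(3) * 1e-4
    est <- delta_method_cis(b[1], b[2], b[3], cov3)
    h <- 1e-6
    num_grad <- function(f) {
      vapply(1:3, function(j) {
        e <- rep(0, 3); e[j] <- h
        (f(b + e) - f(b - e)) / (2 * h)
      }, 0)
    }
    z <- qnorm(0.975)
    g_reri <- num_grad(measures$reri_f)
    se_reri <- sqrt(drop(t(g_reri) %*% cov3 %*% g_reri))
    expect_equal(est$ci$reri[2] - est$ci$reri[1], 2 * z * se_reri,
                 tolerance = 1e-5)
    g_ap <- num_grad(measures$ap_f)
    se_ap <- sqrt(drop(t(g_ap) %*% cov3 %*% g_ap))
    expect_equal(est$ci$ap[2] - est$ci$ap[1], 2 * z * se_ap,
                 tolerance = 1e-5)
    g_lns <- num_grad(measures$lns_f)
    se_lns <- sqrt(drop(t(g_lns) %*% cov3 %*% g_lns))
    expect_equal(log(est$ci$s[2] / est$ci$s[1]), 2 * z * se_lns,
                 tolerance = 1e-5)
  }
})

test_that("zero covariance collapses intervals to the point estimates", {
  est <- delta_method_cis(log(6.34), log(3.55), log(19.57),
                          matrix(0, 3, 3))
  expect_equal(est$ci$reri, c(est$reri, est$reri))
  expect_equal(est$ci$ap, c(est$ap, est$ap))
  expect_equal(est$ci$s, c(est$s, est$s))
  expect_true(is.na(est$p$reri))
  expect_equal(est$reri, 10.68, tolerance = 1e-12)
  # measures from a fit equal measures from its printed-precision ORs
  # up to rounding of the inputs (oracle consistency)
  expect_equal(round(est$ap, 2), 0.55)
  expect_error(delta_method_cis(0, 0, 0, matrix(c(1, 2, 3, 4, 5, 6, 7, 8,
                                                  9), 3, 3)), "symmetric")
})

test_that("classification follows sign and CI-exclusion rules", {
  mk <- function(reri, ci_reri, s = 2, ci_s = c(1.5, 2.5)) {
    ap <- reri / 19
    structure(list(reri = reri, ap = ap, s = s,
                   ci = list(reri = ci_reri, ap = ci_reri / 19,
                             s = ci_s),
                   p = list(reri = 0.01, ap = 0.01, s = 0.01),
                   method = "delta", s_defined = TRUE, level = 0.95),
              class = "interaction_estimates")
  }
  est <- classify_interaction(mk(3.5, c(1.52, 5.47)))
  expect_equal(unname(est$classification[["reri"]]), "positive")
  expect_true(est$significant[["reri"]])

  est2 <- classify_interaction(mk(-0.5, c(-1.2, 0.2)))
  expect_equal(unname(est2$classification[["reri"]]), "negative")
  expect_false(est2$significant[["reri"]])

  est3 <- classify_interaction(mk(0.5, c(0.1, 0.9), s = 1,
                                  ci_s = c(0.8, 1.3)))
  expect_equal(unname(est3$classification[["s"]]), "none")
  expect_false(est3$significant[["s"]])
})

test_that("bootstrap is reproducible and guards degenerate inputs", {
  d <- generate_cohort(minimal_config(3000, c(-2.5, log(3), log(2.5),
                                              log(8)), seed = 22))
  spec <- list(outcome = "outcome_dx", fh = "fh_any", ht = "ht_self")
  b1 <- bootstrap_cis(d, spec, B = 200, seed = 5)
  b2 <- bootstrap_cis(d, spec, B = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_equal(b1$method, "bootstrap")
  expect_lte(b1$n_failed, 20)
  # point estimates are the full-data fit, not a bootstrap average
  f <- fit_joint(d)
  expect_equal(b1$reri, measures_from_fit(f)$reri, tolerance = 1e-10)

  d0 <- d; d0$outcome_dx <- 0L
  expect_error(bootstrap_cis(d0, spec, B = 200, seed = 5),
               "zero variance")
  expect_error(bootstrap_cis(d, spec, B = 100, seed = 5), "at least 200")
})
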