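# Exclusion flow, joint-exposure and covariate encoding, weighted
# prevalence.

test_that("exclusion flow matches hand-countable toys", {
  raw <- data.frame(
    age_years = c(40, 40, rep(50, 8)),
    outcome_dx = c(1, 0, NA, rep(0, 7)),
    bmi_cat = c("normal", "normal", "normal", NA, rep("normal", 6)),
    stringsAsFactors = FALSE)
  res <- apply_exclusions(raw, "outcome_dx", "bmi_cat")
  expect_equal(unclass(res$flow)[c("n_input", "n_under_45",
                                   "n_missing_outcome",
                                   "n_missing_covariates",
                                   "n_analytic")],
               list(n_input = 10L, n_under_45 = 2L,
                    n_missing_outcome = 1L, n_missing_covariates = 1L,
                    n_analytic = 6L))
  expect_equal(nrow(res$table), 6)

  # identity case: nothing to remove, rows unmodified
  clean <- data.frame(age_years = rep(60, 5), outcome_dx = rep(1, 5))
  res2 <- apply_exclusions(clean, "outcome_dx")
  expect_equal(res2$flow$n_analytic, 5)
  expect_equal(res2$flow$n_under_45 + res2$flow$n_missing_outcome +
                 res2$flow$n_missing_covariates, 0)
  expect_identical(res2$table, clean)

  expect_error(apply_exclusions(clean, "nope"), "unknown column")
})

test_that("exclusion counts match a brute-force row scan", {
  cfg <- sim_config(n_raw = 10000, seed = 31,
                    missing_rates = c(outcome_dx = 0.05, bmi_cat = 0.05,
                                      fh_any = 0.05))
  raw <- generate_cohort(cfg)
  req <- c("bmi_cat", "fh_any")
  res <- apply_exclusions(raw, "outcome_dx", req)

  # oracle: naive per-row predicate scan
  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    keep[i] <- raw$age_years[i] >= 45 && !is.na(raw$outcome_dx[i]) &&
      !is.na(raw$bmi_cat[i]) && !is.na(raw$fh_any[i])
  }
  expect_equal(res$flow$n_analytic, sum(keep))
  expect_equal(res$table$id, raw$id[keep])

  # total removed is order-independent, per-step counts are not
  res_swapped <- apply_exclusions(raw, "bmi_cat", c("outcome_dx", "fh_any"))
  expect_equal(res_swapped$flow$n_analytic, res$flow$n_analytic)
  expect_false(res_swapped$flow$n_missing_outcome ==
                 res$flow$n_missing_outcome)

  js <- jsonlite::fromJSON(flow_to_json(res$flow))
  expect_equal(js$n_analytic, res$flow$n_analytic)
})

test_that("joint-exposure encoding follows the 4-level contract", {
  je <- encode_joint_exposure(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(as.character(je$level),
               c("ref", "ht_only", "fh_only", "both"))
  expect_equal(unname(je$dummies),
               matrix(c(0, 1, 0, 0,
                        0, 0, 1, 0,
                        0, 0, 0, 1), 4, 3),
               ignore_attr = TRUE)
  expect_true(all(rowSums(je$dummies) %in% c(0, 1)))
  expect_error(encode_joint_exposure(NA, 1), "missing")
  expect_error(encode_joint_exposure(2, 1), "binary")

  # property: d11 = fh * ht on random draws
  set.seed(1)
  fh <- rbinom(500, 1, 0.3); ht <- rbinom(500, 1, 0.5)
  je2 <- encode_joint_exposure(fh, ht)
  expect_equal(je2$dummies[, "d11"], as.numeric(fh * ht))
  expect_equal(je2$dummies[, "d01"] + je2$dummies[, "d11"],
               as.numeric(ht))
})

test_that("covariate dummies are reference-coded and deterministic", {
  spec <- list(list(name = "grp", levels = c("a", "b", "c"),
                    probs = c(1, 1, 1) / 3, ref = "a"))
  tab <- data.frame(grp = c("a", "b", "c", "b", "a"),
                    stringsAsFactors = FALSE)
  X <- encode_covariates(tab, spec)
  expect_equal(colnames(X), c("grp_b", "grp_c"))
  expect_equal(unname(X),
               cbind(c(0, 1, 0, 1, 0), c(0, 0, 1, 0, 0)))

  # degenerate single-level covariate: zero columns
  spec1 <- list(list(name = "one", levels = "x", probs = 1, ref = "x"))
  X1 <- encode_covariates(data.frame(one = rep("x", 4)), spec1)
  expect_equal(ncol(X1), 0)
  expect_equal(nrow(X1), 4)

  expect_error(encode_covariates(data.frame(grp = c("a", "z")), spec),
               "unseen level.*z")
  expect_error(encode_covariates(data.frame(grp = c("a", NA)), spec),
               "missing")
})

test_that("BMI bins follow the WHO cut points", {
  expect_equal(bmi_category(c(17, 18.5, 24.9, 25, 31, NA)),
               c("underweight", "normal", "normal", "overweight_obese",
                 "overweight_obese", NA))
  expect_equal(any_difficulty(c(0, 0, 1), c(0, 0, 0)), c(0L, 0L, 1L))
})

test_that("weighted prevalence matches closed forms and a loop oracle", {
  d <- data.frame(y = c(1, 0, 1, 0), w = rep(2, 4))
  expect_equal(weighted_prevalence(d, "y", weights = "w")$est, 0.5)
  d2 <- data.frame(y = c(1, 0), w = c(3, 1))
  expect_equal(weighted_prevalence(d2, "y", weights = "w")$est, 0.75)

  # equal weights match the unweighted proportion to machine precision
  set.seed(2)
  d3 <- data.frame(y = rbinom(200, 1, 0.3), w = rep(5, 200))
  expect_equal(weighted_prevalence(d3, "y", weights = "w")$est,
               mean(d3$y), tolerance = 1e-15)

  # random grouped table vs explicit per-row accumulation
  set.seed(3)
  tab <- data.frame(y = rbinom(400, 1, 0.4),
                    g = sample(c("ref", "ht", "fh", "both"), 400, TRUE),
                    w = exp(rnorm(400, 0, 0.5)))
  got <- weighted_prevalence(tab, "y", by = "g", weights = "w")
  for (lv in unique(tab$g)) {
    num <- 0; den <- 0
    for (i in seq_len(400)) {
      if (tab$g[i] == lv) {
        num <- num + tab$w[i] * tab$y[i]; den <- den + tab$w[i]
      }
    }
    expect_equal(got$est[got$group == lv], num / den, tolerance = 1e-12)
  }
  expect_true(all(got$ci_low < got$est & got$est < got$ci_high))

  # empty group flagged undefined, not dropped
  f <- factor(rep("a", 4), levels = c("a", "b"))
  got2 <- weighted_prevalence(data.frame(y = c(1, 0, 1, 1),
                                         w = rep(1, 4)),
                              "y", by = f, weights = "w")
  expect_equal(nrow(got2), 2)
  expect_true(got2$undefined[got2$group == "b"])
  expect_error(weighted_prevalence(data.frame(y = c(1, NA), w = c(1, 1)),
                                   "y", weights = "w"), "missing")
})
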