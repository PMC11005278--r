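# Synthetic cohort generator: an ageing-survey-like population with two
# correlated binary exposures, categorical confounders, sampling weights,
# under-45 spouse records and injected missingness, with all generating
# parameters known so downstream inference is testable.

#' Default categorical covariate specification
#'
#' Eight categorical confounders whose level frequencies emulate the
#' background distribution of a nationally representative Indian ageing
#' survey (sex, education, residence, BMI category, smoking, physical
#' activity, ADL and IADL difficulty). Each entry carries the simulation
#' level probabilities and the reference level used for dummy coding.
#'
#' @return A list of covariate descriptors, each a list with elements
#'   `name`, `levels` (character), `probs` (simulation probabilities summing
#'   to 1) and `ref` (reference level).
#' @export
#' @examples
#' names(sapply(default_covariate_spec(), `[[`, "name"))
default_covariate_spec <- function() {
  list(
    list(name = "sex", levels = c("male", "female"),
         probs = c(0.459, 0.541), ref = "male"),
    list(name = "education",
         levels = c("none", "primary", "secondary", "higher"),
         probs = c(0.5045, 0.2343, 0.1628, 0.0984), ref = "none"),
    list(name = "residence", levels = c("rural", "urban"),
         probs = c(0.7012, 0.2988), ref = "rural"),
    list(name = "bmi_cat",
         levels = c("normal", "underweight", "overweight_obese"),
         probs = c(0.5157, 0.2134, 0.2709), ref = "normal"),
    list(name = "smoking", levels = c("never", "former", "current"),
         probs = c(0.8274, 0.0378, 0.1348), ref = "never"),
    list(name = "physical_activity", levels = c("active", "inactive"),
         probs = c(0.6578, 0.3422), ref = "active"),
    list(name = "adl", levels = c("no", "yes"),
         probs = c(0.8449, 0.1551), ref = "no"),
    list(name = "iadl", levels = c("no", "yes"),
         probs = c(0.6349, 0.3651), ref = "no")
  )
}

# Dummy-column names implied by a covariate spec: "<name>_<level>" for every
# non-reference level, in spec order.
covariate_dummy_names <- function(covariate_spec) {
  unlist(lapply(covariate_spec, function(cv) {
    lv <- setdiff(cv$levels, cv$ref)
    if (length(lv) == 0) character(0) else paste(cv$name, lv, sep = "_")
  }), use.names = FALSE)
}

# Default log-odds effects. Joint-exposure terms reproduce the unadjusted
# odds ratios of the motivating study's primary model (OR01 = 5.93 for
# hypertension only, OR10 = 4.00 for family history only, OR11 = 17.63 for
# both); covariate effects are modest values with the direction seen in that
# study's descriptive table. Unknown dummy names default to 0.
default_beta <- function(covariate_spec) {
  base <- c("(Intercept)" = -3.6,
            d01 = log(5.93), d10 = log(4.00), d11 = log(17.63))
  known <- c(sex_female = -0.05,
             education_primary = 0.45, education_secondary = 0.70,
             education_higher = 0.80,
             residence_urban = 0.80,
             bmi_cat_underweight = -1.00, bmi_cat_overweight_obese = 0.75,
             smoking_former = 0.05, smoking_current = -0.35,
             physical_activity_inactive = 0.15,
             adl_yes = 0.10, iadl_yes = 0.15)
  dn <- covariate_dummy_names(covariate_spec)
  cov_beta <- setNames(rep(0, length(dn)), dn)
  hit <- intersect(dn, names(known))
  cov_beta[hit] <- known[hit]
  c(base, cov_beta)
}

#' Simulation configuration for a synthetic ageing-survey cohort
#'
#' Bundles and validates every generator parameter. Defaults state a
#' realistic world: exposure prevalences 14.33% (family history of diabetes)
#' and 26.98% (hypertension), exposure co-occurrence odds ratio 1.5,
#' joint-exposure outcome effects matching the motivating study's unadjusted
#' odds ratios, 82.5% of outcome cases on medication, 10.2% under-45 spouse
#' records, log-normal sampling weights rescaled to mean 1, and small
#' missing-completely-at-random rates mirroring the study's exclusion flow.
#'
#' @param n_raw Number of records to generate before exclusions.
#' @param p_fh Marginal prevalence of family history of diabetes, in (0,1).
#' @param p_ht Marginal prevalence of hypertension, in (0,1).
#' @param or_fh_ht Odds ratio linking the two exposures (>= 0); margins are
#'   held fixed while this controls co-occurrence.
#' @param beta Named numeric vector of log-odds coefficients. Must contain
#'   exactly `"(Intercept)"`, `"d01"` (hypertension only), `"d10"` (family
#'   history only), `"d11"` (both) plus one entry per covariate dummy
#'   implied by `covariate_spec`. Default: [default_beta()].
#' @param covariate_spec List of categorical covariates (see
#'   [default_covariate_spec()]); may be `list()` for an exposure-only model.
#' @param frac_under45 Fraction of records given an age below 45 (spouse
#'   records), in \[0,1).
#' @param missing_rates Named vector of per-column missingness probabilities
#'   in \[0,1). Names must be cohort columns.
#' @param weight_meanlog,weight_sdlog Log-normal weight parameters; draws
#'   are rescaled to mean 1 so weights are strictly positive.
#' @param p_med_given_dx Probability that an outcome case is on medication
#'   (default 0.825, the treated share reported by the motivating study).
#' @param p_med_given_ht Probability that a hypertensive record is on
#'   antihypertensive medication (default 0.7216 = 12,072/16,731).
#' @param n_clusters Number of i.i.d. PSU-like cluster labels.
#' @param seed Integer RNG seed; the same config and seed reproduce the
#'   cohort exactly.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_raw = 100, seed = 7)
#' cfg$p_fh
sim_config <- function(n_raw = 60000L,
                       p_fh = 0.1433,
                       p_ht = 0.2698,
                       or_fh_ht = 1.5,
                       beta = NULL,
                       covariate_spec = default_covariate_spec(),
                       frac_under45 = 0.102,
                       missing_rates = c(outcome_dx = 0.003,
                                         fh_any = 0.006,
                                         bmi_cat = 0.0965,
                                         physical_activity = 0.0008,
                                         adl = 0.0018,
                                         iadl = 0.0027),
                       weight_meanlog = 0,
                       weight_sdlog = 0.5,
                       p_med_given_dx = 0.825,
                       p_med_given_ht = 0.7216,
                       n_clusters = 100L,
                       seed = 1L) {
  chk_prob <- function(x, field, open = TRUE) {
    bad <- !is.numeric(x) || any(!is.finite(x)) ||
      (open && any(x <= 0 | x >= 1)) || (!open && any(x < 0 | x >= 1))
    if (bad) stop("invalid probability in field '", field, "'", call. = FALSE)
  }
  if (!is.numeric(n_raw) || length(n_raw) != 1 || n_raw < 0 ||
      n_raw != floor(n_raw))
    stop("invalid field 'n_raw': need a nonnegative integer", call. = FALSE)
  chk_prob(p_fh, "p_fh"); chk_prob(p_ht, "p_ht")
  if (!is.numeric(or_fh_ht) || or_fh_ht < 0)
    stop("invalid field 'or_fh_ht': need a nonnegative real", call. = FALSE)
  chk_prob(frac_under45, "frac_under45", open = FALSE)
  chk_prob(p_med_given_dx, "p_med_given_dx")
  chk_prob(p_med_given_ht, "p_med_given_ht")
  if (length(missing_rates)) {
    chk_prob(missing_rates, "missing_rates", open = FALSE)
    if (is.null(names(missing_rates)) || any(names(missing_rates) == ""))
      stop("invalid field 'missing_rates': entries must be named",
           call. = FALSE)
  }
  if (!is.numeric(weight_sdlog) || weight_sdlog < 0)
    stop("invalid field 'weight_sdlog'", call. = FALSE)
  if (!is.numeric(n_clusters) || n_clusters < 1)
    stop("invalid field 'n_clusters'", call. = FALSE)
  for (cv in covariate_spec) {
    if (!all(c("name", "levels", "probs", "ref") %in% names(cv)))
      stop("invalid field 'covariate_spec': each covariate needs ",
           "name/levels/probs/ref", call. = FALSE)
    if (length(cv$levels) != length(cv$probs) ||
        abs(sum(cv$probs) - 1) > 1e-8 || any(cv$probs < 0))
      stop("invalid field 'covariate_spec': probabilities of '", cv$name,
           "' must be nonnegative and sum to 1", call. = FALSE)
    if (!cv$ref %in% cv$levels)
      stop("invalid field 'covariate_spec': reference level of '", cv$name,
           "' not among its levels", call. = FALSE)
  }
  # feasibility of the joint exposure distribution (errors early)
  solve_joint_distribution(p_fh, p_ht, or_fh_ht)
  if (is.null(beta)) beta <- default_beta(covariate_spec)
  need <- c("(Intercept)", "d01", "d10", "d11",
            covariate_dummy_names(covariate_spec))
  if (length(beta) != length(need) || !setequal(names(beta), need))
    stop("invalid field 'beta': coefficient names must be exactly {",
         paste(need, collapse = ", "), "}", call. = FALSE)
  beta <- beta[need]
  structure(list(n_raw = as.integer(n_raw), p_fh = p_fh, p_ht = p_ht,
                 or_fh_ht = or_fh_ht, beta = beta,
                 covariate_spec = covariate_spec,
                 frac_under45 = frac_under45,
                 missing_rates = missing_rates,
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 p_med_given_dx = p_med_given_dx,
                 p_med_given_ht = p_med_given_ht,
                 n_clusters = as.integer(n_clusters),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Joint distribution of two binary variables from margins and odds ratio
#'
#' Solves the quadratic in the co-occurrence cell p11 so that the 2x2 cell
#' probabilities reproduce the requested margins `p_a`, `p_b` and
#' cross-product ratio `or_ab`. With `or_ab = 0` the exposures are taken to
#' never co-occur (p11 = 0), which is infeasible when `p_a + p_b > 1`.
#'
#' @param p_a,p_b Marginal probabilities in (0,1).
#' @param or_ab Target odds ratio, >= 0.
#' @return Named numeric `c(p00, p01, p10, p11)` summing to 1, where the
#'   first index is variable A and the second variable B (so `p01` is
#'   B-only).
#' @export
#' @examples
#' solve_joint_distribution(0.5, 0.5, 1) # independence
solve_joint_distribution <- function(p_a, p_b, or_ab) {
  if (!is.numeric(p_a) || !is.numeric(p_b) || p_a <= 0 || p_a >= 1 ||
      p_b <= 0 || p_b >= 1)
    stop("margins must lie strictly in (0,1)", call. = FALSE)
  if (!is.numeric(or_ab) || !is.finite(or_ab) || or_ab < 0)
    stop("odds ratio must be a nonnegative real", call. = FALSE)
  if (or_ab == 0) {
    p11 <- 0
  } else if (abs(or_ab - 1) < 1e-12) {
    p11 <- p_a * p_b
  } else {
    k <- 1 + (p_a + p_b) * (or_ab - 1)
    disc <- k^2 - 4 * or_ab * (or_ab - 1) * p_a * p_b
    if (disc < 0)
      stop("margins incompatible with the requested odds ratio",
           call. = FALSE)
    p11 <- (k - sqrt(disc)) / (2 * (or_ab - 1))
  }
  cells <- c(p00 = 1 - p_a - p_b + p11, p01 = p_b - p11,
             p10 = p_a - p11, p11 = p11)
  if (any(cells < -1e-12))
    stop("margins incompatible with the requested odds ratio (cell ",
         names(cells)[which.min(cells)], " would be negative)",
         call. = FALSE)
  pmax(cells, 0)
}

# Conditional probabilities of a specific relative having the condition,
# given any family history; fixed generator constants derived from the
# relative-specific prevalences of the emulated survey (4.29/5.76/5.08/2.76%
# against 14.33% overall).
REL_COND <- c(father = 0.299, mother = 0.402, brother = 0.354, sister = 0.193)

cohort_schema <- function(covariate_spec) {
  c("id", "age_years",
    "fh_any", "fh_parental", "fh_father", "fh_mother",
    "fh_sibling", "fh_brother", "fh_sister",
    "ht_self", "ht_med", "outcome_dx", "outcome_dx_med",
    vapply(covariate_spec, `[[`, "", "name"),
    "weight", "cluster_id")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `config$n_raw` records in a fixed, documented column order (age,
#' joint exposure, family-history relatives, covariates, outcome, outcome
#' medication, hypertension medication, weights, clusters, then per-column
#' missingness), so the same config and seed give a byte-identical table.
#' All random draws use `runif`/`rnorm` with one variate per record per
#' column, making seeds portable across sessions.
#'
#' Structural invariants of the generated (pre-missingness) values:
#' medication flags are subsets of the corresponding disease flags, and any
#' specific relative with the condition implies the parental/sibling and
#' overall family-history flags.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame`, one row per respondent, with the columns listed
#'   in the configuration schema (exposures/outcomes as 0/1/NA integers,
#'   covariates as character, `weight` positive numeric, `cluster_id`
#'   character).
#' @export
#' @examples
#' head(generate_cohort(sim_config(n_raw = 50, seed = 1)))
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  n <- config$n_raw
  spec <- config$covariate_spec
  cols <- cohort_schema(spec)
  if (n == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  set.seed(config$seed)

  # 1. age: spouse records under 45, main respondents 45-95
  young <- runif(n) < config$frac_under45
  age_young <- 18L + as.integer(floor(runif(n) * 27))   # 18..44
  age_old <- 45L + as.integer(floor(runif(n) * 51))     # 45..95
  age <- ifelse(young, age_young, age_old)

  # 2. joint exposure from the solved 2x2 cell distribution
  cells <- solve_joint_distribution(config$p_fh, config$p_ht,
                                    config$or_fh_ht)
  u <- runif(n)
  cell <- findInterval(u, cumsum(cells)[-4]) + 1L  # 1=00 2=01 3=10 4=11
  fh <- as.integer(cell >= 3L)
  ht <- as.integer(cell == 2L | cell == 4L)

  # 3. specific relatives, conditional on any family history
  rel <- sapply(REL_COND, function(p) as.integer(runif(n) < p))
  u_fix <- runif(n)
  rel[fh == 0L, ] <- 0L
  none <- fh == 1L & rowSums(rel) == 0L
  if (any(none)) {
    pick <- findInterval(u_fix[none],
                         cumsum(REL_COND / sum(REL_COND))[-4]) + 1L
    rel[cbind(which(none), pick)] <- 1L
  }
  fh_father <- rel[, "father"]; fh_mother <- rel[, "mother"]
  fh_brother <- rel[, "brother"]; fh_sister <- rel[, "sister"]
  fh_parental <- as.integer(fh_father | fh_mother)
  fh_sibling <- as.integer(fh_brother | fh_sister)

  # 4. covariates, in spec order
  cov_df <- list()
  for (cv in spec) {
    ucv <- runif(n)
    idx <- findInterval(ucv, cumsum(cv$probs)[-length(cv$probs)]) + 1L
    cov_df[[cv$name]] <- cv$levels[idx]
  }

  # 5. outcome from the logistic model
  beta <- config$beta
  lp <- rep(beta[["(Intercept)"]], n) +
    beta[["d01"]] * (ht == 1L & fh == 0L) +
    beta[["d10"]] * (fh == 1L & ht == 0L) +
    beta[["d11"]] * (fh == 1L & ht == 1L)
  for (cv in spec) {
    for (lv in setdiff(cv$levels, cv$ref)) {
      bname <- paste(cv$name, lv, sep = "_")
      lp <- lp + beta[[bname]] * (cov_df[[cv$name]] == lv)
    }
  }
  dx <- as.integer(runif(n) < plogis(lp))

  # 6./7. medication thinning (subset invariants hold by construction)
  dx_med <- as.integer(dx == 1L & runif(n) < config$p_med_given_dx)
  ht_med <- as.integer(ht == 1L & runif(n) < config$p_med_given_ht)

  # 8. weights: log-normal, rescaled to mean 1 (strictly positive)
  w <- exp(rnorm(n, config$weight_meanlog, config$weight_sdlog))
  w <- w / mean(w)

  # 9. clusters: i.i.d. labels
  cl <- sprintf("c%03d", sample.int(config$n_clusters, n, replace = TRUE))

  out <- data.frame(id = seq_len(n), age_years = age,
                    fh_any = fh, fh_parental = fh_parental,
                    fh_father = fh_father, fh_mother = fh_mother,
                    fh_sibling = fh_sibling, fh_brother = fh_brother,
                    fh_sister = fh_sister,
                    ht_self = ht, ht_med = ht_med,
                    outcome_dx = dx, outcome_dx_med = dx_med,
                    stringsAsFactors = FALSE)
  for (cv in spec) out[[cv$name]] <- cov_df[[cv$name]]
  out$weight <- w
  out$cluster_id <- cl

  # 10. missingness, MCAR, in the order the rates are stored
  for (colname in names(config$missing_rates)) {
    rate <- config$missing_rates[[colname]]
    if (!colname %in% names(out))
      stop("missing_rates names a column absent from the cohort: '",
           colname, "'", call. = FALSE)
    if (rate > 0) out[[colname]][runif(n) < rate] <- NA
  }
  out[cols]
}

#' Write / read a cohort as CSV with a JSON provenance sidecar
#'
#' `write_cohort()` writes the table as plain CSV and, when a config is
#' supplied, a `<path>.provenance.json` sidecar echoing the seed and all
#' generator parameters. `read_cohort()` reads the CSV back with the
#' schema's column types.
#'
#' @param table A cohort `data.frame`.
#' @param path CSV file path.
#' @param config Optional [sim_config()] echoed into the sidecar.
#' @return `write_cohort()` the path, invisibly; `read_cohort()` the table.
#' @export
write_cohort <- function(table, path, config = NULL) {
  write.csv(table, path, row.names = FALSE, quote = TRUE)
  if (!is.null(config)) {
    side <- list(seed = config$seed, n_raw = config$n_raw,
                 parameters = unclass(config))
    jsonlite::write_json(side, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
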