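# Exclusion flow, joint-exposure and covariate recoding, and weighted
# prevalence estimation.

exclusion_flow <- function(n_input, n_under_45, n_missing_outcome,
                           n_missing_covariates) {
  flow <- list(n_input = n_input, n_under_45 = n_under_45,
               n_missing_outcome = n_missing_outcome,
               n_missing_covariates = n_missing_covariates,
               n_analytic = n_input - n_under_45 - n_missing_outcome -
                 n_missing_covariates)
  stopifnot(all(unlist(flow) >= 0))
  structure(flow, class = "exclusion_flow")
}

#' @export
format.exclusion_flow <- function(x, ...) {
  paste0(
    "Study sample flow\n",
    sprintf("  records in input ............. %d\n", x$n_input),
    sprintf("  removed: age below cutoff .... %d\n", x$n_under_45),
    sprintf("  removed: missing outcome ..... %d\n", x$n_missing_outcome),
    sprintf("  removed: incomplete covariates %d\n",
            x$n_missing_covariates),
    sprintf("  analytic sample .............. %d", x$n_analytic))
}

#' @export
print.exclusion_flow <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Apply the complete-case exclusion flow
#'
#' Removes rows in a fixed, documented order: (1) age below `age_min`
#' (spouse records), (2) missing outcome, (3) missing value in any required
#' covariate column. The per-step counts depend on this order and are part
#' of the contract; the total removed does not.
#'
#' @param raw A cohort `data.frame`.
#' @param outcome_col Name of the outcome column.
#' @param required_cols Character vector of columns that must be complete.
#' @param age_col Name of the age column (default `"age_years"`).
#' @param age_min Minimum age retained (default 45).
#' @return A list with `table` (the analytic rows, unmodified) and `flow`
#'   (an `exclusion_flow` with counts per step).
#' @export
#' @examples
#' d <- generate_cohort(sim_config(n_raw = 500, seed = 2))
#' apply_exclusions(d, "outcome_dx", c("bmi_cat", "fh_any"))$flow
apply_exclusions <- function(raw, outcome_col, required_cols = character(),
                             age_col = "age_years", age_min = 45) {
  missing_cols <- setdiff(c(outcome_col, required_cols, age_col),
                          names(raw))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  under <- !is.na(raw[[age_col]]) & raw[[age_col]] < age_min
  t1 <- raw[!under, , drop = FALSE]
  miss_out <- is.na(t1[[outcome_col]])
  t2 <- t1[!miss_out, , drop = FALSE]
  if (length(required_cols)) {
    miss_cov <- !complete.cases(t2[, required_cols, drop = FALSE])
  } else {
    miss_cov <- rep(FALSE, nrow(t2))
  }
  analytic <- t2[!miss_cov, , drop = FALSE]
  list(table = analytic,
       flow = exclusion_flow(nrow(raw), sum(under), sum(miss_out),
                             sum(miss_cov)))
}

#' Serialize an exclusion flow to JSON
#' @param flow An `exclusion_flow`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
flow_to_json <- function(flow, path = NULL) {
  js <- jsonlite::toJSON(unclass(flow), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Encode the 4-level joint exposure
#'
#' Maps two binary exposures to the joint-exposure factor
#' \{ref(0,0), ht_only(0,1), fh_only(1,0), both(1,1)\} and its three dummy
#' indicators `d01`, `d10`, `d11` (reference: doubly unexposed). Missing
#' inputs are an error: exclusions must run first.
#'
#' @param fh,ht Binary (0/1) vectors of equal length.
#' @return A list with `level` (factor) and `dummies` (numeric matrix with
#'   columns `d01`, `d10`, `d11`); on every row `d01+d10+d11` is 0 or 1.
#' @export
#' @examples
#' encode_joint_exposure(c(0, 1), c(1, 1))$level
encode_joint_exposure <- function(fh, ht) {
  if (length(fh) != length(ht))
    stop("fh and ht must have equal length", call. = FALSE)
  if (anyNA(fh) || anyNA(ht))
    stop("missing exposure values: apply exclusions before encoding",
         call. = FALSE)
  if (!all(fh %in% c(0, 1)) || !all(ht %in% c(0, 1)))
    stop("exposures must be binary 0/1", call. = FALSE)
  lev <- c("ref", "ht_only", "fh_only", "both")[1L + ht + 2L * fh]
  level <- factor(lev, levels = c("ref", "ht_only", "fh_only", "both"))
  dummies <- cbind(d01 = as.numeric(fh == 0 & ht == 1),
                   d10 = as.numeric(fh == 1 & ht == 0),
                   d11 = as.numeric(fh == 1 & ht == 1))
  list(level = level, dummies = dummies)
}

#' WHO body-mass-index category
#'
#' Bins numeric BMI at the WHO cut points, with overweight and obesity
#' combined: underweight below 18.5, normal 18.5 to below 25, otherwise
#' overweight/obese.
#'
#' @param bmi Numeric vector (kg/m^2).
#' @return Character vector of categories (`NA` preserved).
#' @export
#' @examples
#' bmi_category(c(17, 24.9, 25))
bmi_category <- function(bmi) {
  out <- ifelse(bmi < 18.5, "underweight",
                ifelse(bmi < 25, "normal", "overweight_obese"))
  out[is.na(bmi)] <- NA_character_
  out
}

#' Collapse item-level difficulty indicators to an any-difficulty binary
#'
#' @param ... Binary 0/1 vectors (e.g. one per ADL or IADL item).
#' @return Integer 0/1 vector: 1 when any item is 1.
#' @export
any_difficulty <- function(...) {
  items <- cbind(...)
  as.integer(rowSums(items) > 0)
}

#' Reference-coded covariate dummy matrix
#'
#' Builds the design columns for categorical covariates with deterministic
#' column order (spec order, then level order), one indicator per
#' non-reference level named `<covariate>_<level>`. Covariates must be
#' complete (post-exclusion); a value outside the declared levels is an
#' error naming the level.
#'
#' @param table Cohort `data.frame`.
#' @param spec Covariate specification as in [default_covariate_spec()]
#'   (`probs` not needed here).
#' @return Numeric matrix with `nrow(table)` rows; zero columns when every
#'   covariate has a single level.
#' @export
encode_covariates <- function(table, spec) {
  n <- nrow(table)
  cols <- list()
  for (cv in spec) {
    x <- table[[cv$name]]
    if (is.null(x))
      stop("unknown covariate column: ", cv$name, call. = FALSE)
    if (anyNA(x))
      stop("covariate '", cv$name, "' has missing values: apply ",
           "exclusions before encoding", call. = FALSE)
    unseen <- setdiff(unique(x), cv$levels)
    if (length(unseen))
      stop("covariate '", cv$name, "' has unseen level(s): ",
           paste(unseen, collapse = ", "), call. = FALSE)
    for (lv in setdiff(cv$levels, cv$ref))
      cols[[paste(cv$name, lv, sep = "_")]] <- as.numeric(x == lv)
  }
  if (length(cols) == 0)
    return(matrix(numeric(0), nrow = n, ncol = 0))
  do.call(cbind, cols)
}

#' Survey-weighted prevalence with logit-scale confidence intervals
#'
#' Per-group weighted proportion sum(w*y)/sum(w) with a normal interval on
#' the logit scale, using the Kish effective sample size
#' (sum w)^2 / sum(w^2) in the variance. With all weights equal the point
#' estimate is the unweighted proportion. Empty groups and boundary
#' estimates (0 or 1) are returned flagged `undefined` rather than dropped.
#'
#' @param table Cohort `data.frame`.
#' @param outcome Name of a binary 0/1 outcome column (no missing values).
#' @param by Optional: name of a grouping column, or a factor/vector of
#'   length `nrow(table)` (e.g. the `level` element of
#'   [encode_joint_exposure()]). `NULL` estimates a single overall group.
#' @param weights Name of the positive weight column (default `"weight"`).
#' @param level Confidence level (default 0.95).
#' @return `data.frame` with columns `group`, `n`, `n_eff`, `est`,
#'   `ci_low`, `ci_high`, `undefined`.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 0, 1, 0), w = c(1, 1, 1, 1))
#' weighted_prevalence(d, "y", weights = "w")$est
weighted_prevalence <- function(table, outcome, by = NULL,
                                weights = "weight", level = 0.95) {
  y <- table[[outcome]]
  if (is.null(y)) stop("unknown column: ", outcome, call. = FALSE)
  w <- table[[weights]]
  if (is.null(w)) stop("unknown column: ", weights, call. = FALSE)
  if (anyNA(y) || anyNA(w))
    stop("missing values in outcome or weights", call. = FALSE)
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  g <- if (is.null(by)) {
    factor(rep("all", nrow(table)))
  } else if (is.character(by) && length(by) == 1 && by %in% names(table)) {
    factor(table[[by]])
  } else {
    if (length(by) != nrow(table))
      stop("grouping vector length does not match the table", call. = FALSE)
    if (!is.factor(by)) by <- factor(by)
    by
  }
  z <- qnorm(1 - (1 - level) / 2)
  res <- lapply(levels(g), function(lv) {
    i <- which(g == lv)
    if (length(i) == 0)
      return(data.frame(group = lv, n = 0L, n_eff = NA_real_,
                        est = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, undefined = TRUE))
    wi <- w[i]; yi <- y[i]
    est <- sum(wi * yi) / sum(wi)
    n_eff <- sum(wi)^2 / sum(wi^2)
    if (est <= 0 || est >= 1)
      return(data.frame(group = lv, n = length(i), n_eff = n_eff,
                        est = est, ci_low = NA_real_, ci_high = NA_real_,
                        undefined = TRUE))
    se_logit <- sqrt(1 / (n_eff * est * (1 - est)))
    data.frame(group = lv, n = length(i), n_eff = n_eff, est = est,
               ci_low = plogis(qlogis(est) - z * se_logit),
               ci_high = plogis(qlogis(est) + z * se_logit),
               undefined = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
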