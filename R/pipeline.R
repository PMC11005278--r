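# Study pipeline: exclusions, descriptive tables, per-exposure odds
# ratios, and the 2x2 grid of joint-exposure interaction models
# (two outcome definitions x two hypertension definitions, unadjusted and
# adjusted).

#' Analysis plan for the full study pipeline
#'
#' @param outcome_defs Named character pair of outcome columns: self-report
#'   and on-medication definitions.
#' @param exposure_defs Named character pair of hypertension columns:
#'   self-report and on-medication definitions (the on-medication exposure
#'   is coded against the full sample).
#' @param fh_var Family-history column used for the joint-exposure models.
#' @param fh_vars Family-history columns reported in the per-exposure
#'   odds-ratio table.
#' @param adjustment_spec Covariate specification (as in
#'   [default_covariate_spec()]) defining the adjusted models; may be
#'   `list()` for no adjustment.
#' @param weight,cluster Weight column name and optional cluster column.
#' @param ci_level Confidence level.
#' @param ci_method `"delta"` (default) or `"bootstrap"`.
#' @param boot_B Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param weighted Apply sampling weights (default `TRUE`); `FALSE` fits
#'   all models with unit weights.
#' @param age_min Minimum age retained by the exclusion flow.
#' @param seed Seed used by stochastic stages (bootstrap).
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(outcome_defs = c(self = "outcome_dx",
                                           med = "outcome_dx_med"),
                          exposure_defs = c(self = "ht_self",
                                            med = "ht_med"),
                          fh_var = "fh_any",
                          fh_vars = c("fh_any", "fh_parental", "fh_father",
                                      "fh_mother", "fh_sibling",
                                      "fh_brother", "fh_sister"),
                          adjustment_spec = default_covariate_spec(),
                          weight = "weight", cluster = NULL,
                          ci_level = 0.95,
                          ci_method = c("delta", "bootstrap"),
                          boot_B = 500L, weighted = TRUE, age_min = 45,
                          seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (length(outcome_defs) != 2 || length(exposure_defs) != 2)
    stop("outcome_defs and exposure_defs must each name two columns",
         call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie in (0,1)", call. = FALSE)
  structure(list(outcome_defs = outcome_defs,
                 exposure_defs = exposure_defs, fh_var = fh_var,
                 fh_vars = fh_vars, adjustment_spec = adjustment_spec,
                 weight = weight, cluster = cluster, ci_level = ci_level,
                 ci_method = ci_method, boot_B = as.integer(boot_B),
                 weighted = weighted, age_min = age_min,
                 seed = as.integer(seed)),
            class = "analysis_plan")
}

# Fit one joint-exposure model cell; returns list(fit, ors, measures) or a
# flagged placeholder carrying the stage error.
fit_cell <- function(table, outcome, exposure, plan, adjusted) {
  tryCatch({
    je <- encode_joint_exposure(table[[plan$fh_var]], table[[exposure]])
    Xc <- if (adjusted && length(plan$adjustment_spec))
      encode_covariates(table, plan$adjustment_spec)
    else matrix(numeric(0), nrow = nrow(table), ncol = 0)
    X <- cbind("(Intercept)" = 1, je$dummies, Xc)
    w <- if (plan$weighted) table[[plan$weight]] else rep(1, nrow(table))
    cl <- if (!is.null(plan$cluster)) table[[plan$cluster]] else NULL
    fit <- fit_weighted_logit(table[[outcome]], X, w, cluster = cl)
    measures <- if (plan$ci_method == "bootstrap") {
      spec <- list(outcome = outcome, fh = plan$fh_var, ht = exposure,
                   covariate_spec = if (adjusted) plan$adjustment_spec,
                   weight = plan$weight, cluster = plan$cluster)
      bootstrap_cis(table, spec, B = plan$boot_B, level = plan$ci_level,
                    seed = plan$seed)
    } else {
      measures_from_fit(fit, level = plan$ci_level)
    }
    list(ok = TRUE, fit = fit,
         ors = odds_ratios(fit, level = plan$ci_level),
         measures = measures)
  }, error = function(e) {
    list(ok = FALSE, error = conditionMessage(e))
  })
}

#' Run the full study analysis
#'
#' Applies the exclusion flow, then produces (a) the flow report, (b) a
#' weighted prevalence listing of the primary outcome by each exposure
#' variable, (c) joint-exposure prevalence blocks with a chi-square test of
#' association, (d) per-exposure odds-ratio listings (unadjusted and
#' adjusted) for hypertension and each family-history variable, and (e)
#' the interaction grid: 2 outcome definitions x 2 hypertension
#' definitions x \{unadjusted, adjusted\}, each with joint-exposure odds
#' ratios and RERI/AP/S estimates. A failed model cell is kept as a flagged
#' placeholder and the run continues.
#'
#' @param data Cohort `data.frame` (pre-exclusion).
#' @param plan An [analysis_plan()].
#' @return An object of class `study_report`.
#' @export
#' @examples
#' d <- generate_cohort(sim_config(n_raw = 4000, seed = 3))
#' rep <- run_study(d, analysis_plan())
#' rep$flow
run_study <- function(data, plan) {
  if (!inherits(plan, "analysis_plan"))
    stop("plan must be an analysis_plan", call. = FALSE)
  cov_names <- vapply(plan$adjustment_spec, `[[`, "", "name")
  needed <- unique(c(plan$outcome_defs, plan$exposure_defs, plan$fh_vars,
                     plan$fh_var, cov_names, plan$weight, plan$cluster))
  absent <- setdiff(needed, names(data))
  if (length(absent))
    stop("stage 'schema': data lacks column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  primary_outcome <- plan$outcome_defs[[1]]
  required <- setdiff(needed, c(primary_outcome, plan$weight,
                                plan$cluster))
  excl <- apply_exclusions(data, primary_outcome, required,
                           age_min = plan$age_min)
  tab <- excl$table

  # (b) primary-outcome prevalence by each exposure variable
  prev_vars <- c(plan$exposure_defs, plan$fh_vars)
  table1 <- do.call(rbind, lapply(unname(prev_vars), function(v) {
    pr <- weighted_prevalence(tab, primary_outcome, by = v,
                              weights = plan$weight,
                              level = plan$ci_level)
    cbind(variable = v, pr)
  }))

  # (c) joint-exposure prevalence + chi-square, per outcome x exposure
  table2 <- list()
  for (oname in names(plan$outcome_defs)) {
    for (ename in names(plan$exposure_defs)) {
      outcome <- plan$outcome_defs[[oname]]
      exposure <- plan$exposure_defs[[ename]]
      je <- encode_joint_exposure(tab[[plan$fh_var]], tab[[exposure]])
      pr <- weighted_prevalence(tab, outcome, by = je$level,
                                weights = plan$weight,
                                level = plan$ci_level)
      chi <- chi_square_joint(tab, outcome, je$level)
      table2[[paste(oname, ename, sep = ".")]] <-
        list(outcome = outcome, exposure = exposure, prevalence = pr,
             chi_square = chi)
    }
  }

  # (d) per-exposure odds ratios, unadjusted and adjusted
  or_vars <- c(setNames(plan$exposure_defs[[1]], "hypertension"),
               setNames(plan$fh_vars, plan$fh_vars))
  table3 <- list()
  for (vn in names(or_vars)) {
    v <- or_vars[[vn]]
    table3[[vn]] <- lapply(c(unadjusted = FALSE, adjusted = TRUE),
                           function(adj) {
      tryCatch({
        Xc <- if (adj && length(plan$adjustment_spec))
          encode_covariates(tab, plan$adjustment_spec)
        else matrix(numeric(0), nrow = nrow(tab), ncol = 0)
        keep <- !is.na(tab[[v]])
        X <- cbind("(Intercept)" = 1,
                   exposure = as.numeric(tab[[v]][keep]), Xc[keep, ,
                                                             drop = FALSE])
        w <- if (plan$weighted) tab[[plan$weight]][keep]
        else rep(1, sum(keep))
        fit <- fit_weighted_logit(tab[[primary_outcome]][keep], X, w)
        ors <- odds_ratios(fit, level = plan$ci_level)
        ors[ors$term == "exposure", ]
      }, error = function(e) conditionMessage(e))
    })
  }

  # (e) interaction grid: 4 cells x {unadjusted, adjusted}
  grid <- list()
  for (oname in names(plan$outcome_defs)) {
    for (ename in names(plan$exposure_defs)) {
      for (model in c("unadjusted", "adjusted")) {
        cell_id <- paste(oname, ename, model, sep = ".")
        cell_tab <- tab[!is.na(tab[[plan$exposure_defs[[ename]]]]) &
                          !is.na(tab[[plan$outcome_defs[[oname]]]]), ,
                        drop = FALSE]
        grid[[cell_id]] <- c(
          list(outcome = plan$outcome_defs[[oname]],
               exposure = plan$exposure_defs[[ename]], model = model),
          fit_cell(cell_tab, plan$outcome_defs[[oname]],
                   plan$exposure_defs[[ename]], plan,
                   adjusted = model == "adjusted"))
      }
    }
  }

  structure(list(flow = excl$flow, table1 = table1, table2 = table2,
                 table3 = table3, grid = grid, plan = plan,
                 n_analytic = nrow(tab)),
            class = "study_report")
}

#' Pearson chi-square test of outcome by joint-exposure group
#'
#' Plain Pearson statistic on the unweighted group-by-outcome contingency
#' table (no survey design correction), degrees of freedom
#' `(groups - 1) x (outcome levels - 1)`. A zero expected count flags the
#' test invalid rather than erroring.
#'
#' @param table Cohort `data.frame`.
#' @param outcome Binary outcome column name.
#' @param group Grouping column name or vector/factor of groups.
#' @return List with `statistic`, `df`, `p`, `valid`, `observed`.
#' @export
chi_square_joint <- function(table, outcome, group) {
  y <- table[[outcome]]
  if (is.null(y)) stop("unknown column: ", outcome, call. = FALSE)
  g <- if (is.character(group) && length(group) == 1) {
    if (!group %in% names(table))
      stop("unknown column: ", group, call. = FALSE)
    factor(table[[group]])
  } else {
    if (!is.factor(group)) group <- factor(group)
    group
  }
  g <- droplevels(g)
  if (nlevels(g) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  O <- table(g, factor(y, levels = c(0, 1)))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  if (any(E == 0))
    return(list(statistic = NA_real_, df = df, p = NA_real_,
                valid = FALSE, observed = O))
  stat <- sum((O - E)^2 / E)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       valid = TRUE, observed = O)
}

#' @export
print.study_report <- function(x, ...) {
  cat(format(x$flow), "\n\n")
  cat("Interaction grid:", length(x$grid), "model cells (",
      sum(vapply(x$grid, function(c) isTRUE(c$ok), TRUE)), "fitted )\n")
  for (id in names(x$grid)) {
    cell <- x$grid[[id]]
    if (isTRUE(cell$ok)) {
      m <- cell$measures
      cat(sprintf("  %-22s RERI %s\n", id,
                  fmt_measure_cell(m$reri, m$p$reri, m$ci$reri)))
    } else {
      cat(sprintf("  %-22s [failed: %s]\n", id, cell$error))
    }
  }
  invisible(x)
}
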