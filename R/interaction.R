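# Additive-scale interaction measures from a joint-exposure logistic fit:
# relative excess risk due to interaction (RERI), attributable proportion
# (AP) and synergy index (S), with delta-method and bootstrap confidence
# intervals.
#
# Conventions. OR01 is the odds ratio for exposure-B-only (here:
# hypertension only), OR10 for exposure-A-only (family history only), OR11
# for both, each against the doubly unexposed reference. Under exact
# additivity of excess risks RERI = 0, AP = 0 and S = 1.

#' Relative excess risk due to interaction
#'
#' `RERI = OR11 - OR10 - OR01 + 1`; zero under additivity, positive for
#' super-additive (synergistic) interaction.
#'
#' @param or11,or10,or01 Positive odds ratios for both exposures, exposure
#'   A only, and exposure B only, each versus the doubly unexposed.
#' @return Numeric RERI.
#' @export
#' @examples
#' reri(19.57, 3.55, 6.34)  # 10.68
reri <- function(or11, or10, or01) {
  if (any(c(or11, or10, or01) <= 0))
    stop("odds ratios must be strictly positive", call. = FALSE)
  or11 - or10 - or01 + 1
}

#' Attributable proportion due to interaction
#'
#' `AP = RERI / OR11`: the share of the doubly-exposed group's effect
#' attributable to interaction. Reported canonically as a fraction (some
#' reports multiply by 100).
#'
#' @param reri Numeric RERI value.
#' @param or11 Positive odds ratio for the doubly exposed.
#' @return Numeric AP.
#' @export
#' @examples
#' attributable_proportion(10.68, 19.57)  # 0.546
attributable_proportion <- function(reri, or11) {
  if (any(or11 <= 0))
    stop("or11 must be strictly positive", call. = FALSE)
  reri / or11
}

#' Synergy index
#'
#' `S = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1))`: the ratio of the combined
#' excess effect to the sum of the single-exposure excess effects; 1 under
#' additivity. The denominator is the sum of the two excess odds ratios.
#' When the denominator is not positive or `OR11 <= 1` the index is not a
#' meaningful ratio of excess risks and `NA` is returned with attribute
#' `undefined = TRUE` (no exception).
#'
#' @inheritParams reri
#' @return Positive numeric, or flagged `NA` when undefined.
#' @export
#' @examples
#' synergy_index(19.57, 3.55, 6.34)  # 2.35
synergy_index <- function(or11, or10, or01) {
  if (any(c(or11, or10, or01) <= 0))
    stop("odds ratios must be strictly positive", call. = FALSE)
  den <- (or10 - 1) + (or01 - 1)
  if (den <= 0 || or11 <= 1)
    return(structure(NA_real_, undefined = TRUE))
  (or11 - 1) / den
}

new_interaction_estimates <- function(est, ci, p, method, s_defined,
                                      source, level, extra = list()) {
  obj <- c(list(reri = est[["reri"]], ap = est[["ap"]], s = est[["s"]],
                ci = ci, p = p, method = method, s_defined = s_defined,
                source = source, level = level), extra)
  obj <- classify_interaction(structure(obj, class =
                                          "interaction_estimates"))
  obj
}

#' Delta-method confidence intervals for RERI, AP and S
#'
#' First-order propagation of the covariance of the three joint-exposure
#' log-odds coefficients. RERI and AP get Wald intervals on their natural
#' scale (the RERI gradient in `(b01, b10, b11)` is
#' `(-e^b01, -e^b10, e^b11)`); S gets a Wald interval on
#' `ln S = ln(e^b11 - 1) - ln(e^b10 + e^b01 - 2)`, exponentiated back.
#' P-values are two-sided from the corresponding z statistics (for S on the
#' log scale against `ln S = 0`). A zero variance collapses the interval to
#' the point estimate with `p = NA` (degenerate, flagged).
#'
#' @param b01,b10,b11 Log-odds coefficients of the `d01`, `d10`, `d11`
#'   joint-exposure dummies.
#' @param cov3 Symmetric positive semi-definite 3x3 covariance of
#'   `(b01, b10, b11)`.
#' @param level Confidence level (default 0.95).
#' @return An `interaction_estimates` object: point estimates, per-measure
#'   CIs and p-values, sign classifications and the source coefficients.
#' @export
#' @examples
#' delta_method_cis(log(6.34), log(3.55), log(19.57), diag(3) * 0.01)
delta_method_cis <- function(b01, b10, b11, cov3, level = 0.95) {
  cov3 <- as.matrix(cov3)
  if (!all(dim(cov3) == c(3, 3)) || any(abs(cov3 - t(cov3)) > 1e-8))
    stop("cov3 must be a symmetric 3x3 matrix", call. = FALSE)
  if (any(eigen(cov3, symmetric = TRUE, only.values = TRUE)$values <
          -1e-8))
    stop("cov3 must be positive semi-definite", call. = FALSE)
  or01 <- exp(b01); or10 <- exp(b10); or11 <- exp(b11)
  est_reri <- reri(or11, or10, or01)
  est_ap <- attributable_proportion(est_reri, or11)
  est_s <- synergy_index(or11, or10, or01)
  s_defined <- !isTRUE(attr(est_s, "undefined"))
  z <- qnorm(1 - (1 - level) / 2)

  wald <- function(estimate, grad) {
    v <- drop(t(grad) %*% cov3 %*% grad)
    se <- sqrt(max(v, 0))
    list(se = se, ci = c(estimate - z * se, estimate + z * se),
         p = if (se > 0) 2 * pnorm(-abs(estimate / se)) else NA_real_)
  }
  g_reri <- c(-or01, -or10, or11)
  w_reri <- wald(est_reri, g_reri)
  # AP = 1 - e^(b10-b11) - e^(b01-b11) + e^(-b11)
  g_ap <- c(-exp(b01 - b11),
            -exp(b10 - b11),
            exp(b10 - b11) + exp(b01 - b11) - exp(-b11))
  w_ap <- wald(est_ap, g_ap)
  if (s_defined) {
    den <- or10 + or01 - 2
    g_lns <- c(-or01 / den, -or10 / den, or11 / (or11 - 1))
    w_lns <- wald(log(est_s), g_lns)
    ci_s <- exp(w_lns$ci)
    p_s <- w_lns$p
  } else {
    ci_s <- c(NA_real_, NA_real_)
    p_s <- NA_real_
  }
  new_interaction_estimates(
    est = c(reri = est_reri, ap = est_ap, s = as.numeric(est_s)),
    ci = list(reri = w_reri$ci, ap = w_ap$ci, s = ci_s),
    p = list(reri = w_reri$p, ap = w_ap$p, s = p_s),
    method = "delta", s_defined = s_defined,
    source = list(beta = c(b01 = b01, b10 = b10, b11 = b11),
                  or = c(or01 = or01, or10 = or10, or11 = or11),
                  cov3 = cov3),
    level = level)
}

#' Interaction measures from a fitted joint-exposure model
#'
#' Extracts the `d01`, `d10`, `d11` coefficients and their 3x3
#' sub-covariance from a [fit_weighted_logit()] fit and applies
#' [delta_method_cis()].
#'
#' @param fit A `wlogit_fit` whose design contains the joint-exposure
#'   dummies `d01`, `d10`, `d11`.
#' @param cov_choice `"sandwich"` (default) or `"model"`.
#' @param level Confidence level.
#' @return An `interaction_estimates` object.
#' @export
measures_from_fit <- function(fit, cov_choice = c("sandwich", "model"),
                              level = 0.95) {
  cov_choice <- match.arg(cov_choice)
  need <- c("d01", "d10", "d11")
  if (!all(need %in% names(fit$coef)))
    stop("fit does not contain the joint-exposure dummies d01/d10/d11",
         call. = FALSE)
  V <- if (cov_choice == "sandwich") fit$cov_sandwich else fit$cov_model
  delta_method_cis(fit$coef[["d01"]], fit$coef[["d10"]],
                   fit$coef[["d11"]], V[need, need], level = level)
}

#' Bootstrap percentile confidence intervals for RERI, AP and S
#'
#' Nonparametric row resampling (cluster resampling when a cluster column
#' is named), refitting the joint-exposure model per replicate, percentile
#' intervals per measure. Replicates whose fit fails or whose S is
#' undefined are counted and reported; a failure fraction above 10% is a
#' reliability error. P-values use the symmetric percentile convention
#' `2 min(P(rep <= null), P(rep >= null))`.
#'
#' @param table Analytic cohort `data.frame` (complete rows).
#' @param model_spec List naming the model: `outcome`, `fh`, `ht`,
#'   optionally `covariate_spec` (as in [default_covariate_spec()]),
#'   `weight` (default `"weight"`), `cluster` (optional column name).
#' @param B Number of replicates, >= 200 (default 500).
#' @param level Confidence level.
#' @param seed Integer seed; the same seed reproduces the intervals.
#' @return An `interaction_estimates` object with `method = "bootstrap"`,
#'   plus `n_failed` and `n_s_undefined` replicate counts.
#' @export
bootstrap_cis <- function(table, model_spec, B = 500L, level = 0.95,
                          seed = 1L) {
  if (B < 200) stop("B must be at least 200", call. = FALSE)
  spec <- model_spec
  y_full <- table[[model_spec$outcome]]
  if (length(unique(y_full)) < 2)
    stop("bootstrap unreliable: outcome has zero variance", call. = FALSE)
  if (is.null(spec$weight)) spec$weight <- "weight"
  build <- function(d) {
    je <- encode_joint_exposure(d[[spec$fh]], d[[spec$ht]])
    Xc <- if (!is.null(spec$covariate_spec))
      encode_covariates(d, spec$covariate_spec)
    else matrix(numeric(0), nrow = nrow(d), ncol = 0)
    X <- cbind("(Intercept)" = 1, je$dummies, Xc)
    list(y = d[[spec$outcome]], X = X, w = d[[spec$weight]])
  }
  full <- build(table)
  fit <- fit_weighted_logit(full$y, full$X, full$w)
  point <- measures_from_fit(fit, level = level)

  set.seed(seed)
  n <- nrow(table)
  cl <- if (!is.null(spec$cluster)) table[[spec$cluster]] else NULL
  cl_levels <- if (!is.null(cl)) unique(cl) else NULL
  reps <- matrix(NA_real_, nrow = B, ncol = 3,
                 dimnames = list(NULL, c("reri", "ap", "s")))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- if (is.null(cl)) {
      sample.int(n, n, replace = TRUE)
    } else {
      picked <- sample(cl_levels, length(cl_levels), replace = TRUE)
      unlist(lapply(picked, function(g) which(cl == g)), use.names = FALSE)
    }
    d <- table[idx, , drop = FALSE]
    res <- tryCatch({
      bi <- build(d)
      f <- fit_weighted_logit(bi$y, bi$X, bi$w)
      or <- exp(f$coef[c("d01", "d10", "d11")])
      r <- reri(or[["d11"]], or[["d10"]], or[["d01"]])
      s <- synergy_index(or[["d11"]], or[["d10"]], or[["d01"]])
      c(r, attributable_proportion(r, or[["d11"]]), as.numeric(s))
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else reps[b, ] <- res
  }
  if (n_failed / B > 0.1)
    stop("bootstrap unreliable: ", n_failed, " of ", B,
         " replicate fits failed", call. = FALSE)
  n_s_undef <- sum(is.na(reps[, "s"]) ) - n_failed
  alpha <- (1 - level) / 2
  qs <- function(x) unname(quantile(x, c(alpha, 1 - alpha), na.rm = TRUE))
  boot_p <- function(x, null) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    min(1, 2 * min(mean(x <= null), mean(x >= null)))
  }
  new_interaction_estimates(
    est = c(reri = point$reri, ap = point$ap, s = point$s),
    ci = list(reri = qs(reps[, "reri"]), ap = qs(reps[, "ap"]),
              s = qs(reps[, "s"])),
    p = list(reri = boot_p(reps[, "reri"], 0),
             ap = boot_p(reps[, "ap"], 0),
             s = boot_p(reps[, "s"], 1)),
    method = "bootstrap", s_defined = point$s_defined,
    source = point$source, level = level,
    extra = list(B = B, n_failed = n_failed,
                 n_s_undefined = max(n_s_undef, 0L), seed = seed))
}

#' Sign classification of interaction measures
#'
#' RERI and AP are classified against 0, S against 1 (`positive`, `none`,
#' `negative`); values within 1e-12 of the null display as `none`. A
#' companion `significant` flag marks whether the confidence interval
#' excludes the null value.
#'
#' @param est An `interaction_estimates` object.
#' @return The object with `classification` and `significant` elements
#'   filled (each named by measure).
#' @export
classify_interaction <- function(est) {
  cls <- function(value, null) {
    if (is.na(value) || abs(value - null) < 1e-12) "none"
    else if (value > null) "positive" else "negative"
  }
  sig <- function(ci, null) {
    if (anyNA(ci)) NA else (ci[1] > null || ci[2] < null)
  }
  est$classification <- c(reri = cls(est$reri, 0), ap = cls(est$ap, 0),
                          s = cls(est$s, 1))
  est$significant <- c(reri = sig(est$ci$reri, 0), ap = sig(est$ci$ap, 0),
                       s = sig(est$ci$s, 1))
  est
}

fmt_measure_cell <- function(value, p, ci) {
  if (is.na(value)) return("undefined")
  p_txt <- if (is.na(p)) "p=NA" else formatC(p, format = "f", digits = 3)
  sprintf("%s; %s (%s %s)",
          formatC(value, format = "f", digits = 2), p_txt,
          formatC(ci[1], format = "f", digits = 2),
          formatC(ci[2], format = "f", digits = 2))
}

#' @export
print.interaction_estimates <- function(x, ...) {
  cat("Additive-interaction measures (", x$method, " CIs, level ",
      x$level, ")\n", sep = "")
  cat("  RERI ", fmt_measure_cell(x$reri, x$p$reri, x$ci$reri),
      " [", x$classification[["reri"]], "]\n", sep = "")
  cat("  AP   ", fmt_measure_cell(x$ap, x$p$ap, x$ci$ap),
      " [", x$classification[["ap"]], "]\n", sep = "")
  cat("  S    ", fmt_measure_cell(x$s, x$p$s, x$ci$s),
      " [", x$classification[["s"]], "]\n", sep = "")
  invisible(x)
}

#' Serialize interaction estimates to JSON
#' @param est An `interaction_estimates` object.
#' @param path Optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
interaction_to_json <- function(est, path = NULL) {
  obj <- list(reri = est$reri, ap = est$ap, s = est$s,
              ci = est$ci, p = est$p, method = est$method,
              level = est$level, s_defined = est$s_defined,
              classification = as.list(est$classification),
              significant = as.list(est$significant),
              source = list(beta = as.list(est$source$beta),
                            or = as.list(est$source$or),
                            cov3 = unname(est$source$cov3)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
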