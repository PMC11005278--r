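# Survey-weighted logistic regression by IRLS, with model-based and
# sandwich (optionally cluster-robust) covariance.
#
# Weights are treated as sampling (probability) weights: point estimates
# maximize the weighted log-likelihood sum_i w_i [y_i log p_i +
# (1-y_i) log(1-p_i)]. Weights are normalized internally to mean 1, which
# makes both the point estimates and the sandwich covariance invariant to
# rescaling all weights by a constant.

weighted_deviance <- function(y, p, w) {
  # -2 * weighted log-likelihood, guarding 0*log(0)
  ll <- w * (ifelse(y == 1, log(p), log1p(-p)))
  -2 * sum(ll)
}

#' Fit a weighted logistic regression by IRLS
#'
#' Maximizes the weighted binomial log-likelihood by iteratively reweighted
#' least squares with step-halving (the deviance is non-increasing across
#' iterations). Convergence when the maximum absolute weighted score falls
#' below `tol_score` or the relative deviance change below `tol_dev`. Any
#' coefficient exceeding 30 in absolute value on the logit scale triggers a
#' separation error naming the column rather than returning a sham
#' estimate.
#'
#' Two covariance estimates are returned: `cov_model`, the inverse weighted
#' Fisher information, and `cov_sandwich`, the robust estimator using
#' per-observation (or per-cluster summed) weighted score outer products.
#' With each row its own cluster the cluster-robust estimate equals the
#' heteroskedasticity-robust one (no small-sample correction is applied).
#'
#' @param y Binary 0/1 response vector, no missing values.
#' @param X Design matrix including an intercept column; column names are
#'   used for coefficient names.
#' @param w Positive weights (default all 1).
#' @param cluster Optional cluster labels for cluster-robust covariance.
#' @param max_iter Maximum IRLS iterations (default 50).
#' @param tol_score,tol_dev Convergence tolerances (defaults 1e-8, 1e-10).
#' @return An object of class `wlogit_fit`: list with `coef`, `cov_model`,
#'   `cov_sandwich`, `converged`, `n_iter`, `deviance`, `column_names`,
#'   `n`, `max_score`.
#' @export
#' @examples
#' y <- c(rep(1, 25), rep(0, 75))
#' f <- fit_weighted_logit(y, matrix(1, 100, 1,
#'                         dimnames = list(NULL, "(Intercept)")))
#' f$coef  # log(0.25/0.75)
fit_weighted_logit <- function(y, X, w = rep(1, length(y)), cluster = NULL,
                               max_iter = 50L, tol_score = 1e-8,
                               tol_dev = 1e-10) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[
      seq_len(ncol(X))]
  n <- length(y)
  if (nrow(X) != n || length(w) != n)
    stop("rows of y, X and w must agree", call. = FALSE)
  if (anyNA(y) || anyNA(X) || anyNA(w))
    stop("missing values are not allowed in the fit", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (!is.null(cluster) && length(cluster) != n)
    stop("cluster labels must match the number of rows", call. = FALSE)

  w <- w / mean(w)  # normalization convention (see module header)
  p_cols <- ncol(X)
  beta <- rep(0, p_cols)
  p <- plogis(drop(X %*% beta))
  dev <- weighted_deviance(y, p, w)
  converged <- FALSE
  iter <- 0L
  max_score <- Inf
  dev_trace <- dev

  while (iter < max_iter) {
    iter <- iter + 1L
    score <- drop(crossprod(X, w * (y - p)))
    max_score <- max(abs(score))
    if (max_score < tol_score) { converged <- TRUE; break }
    info <- crossprod(X, X * (w * p * (1 - p)))
    delta <- tryCatch(solve(info, score), error = function(e)
      stop("singular information matrix: check the design for collinearity",
           call. = FALSE))
    # step-halving line search: deviance must not increase
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      p_new <- plogis(drop(X %*% beta_new))
      dev_new <- weighted_deviance(y, p_new, w)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      step <- step / 2
      if (step < 1e-10)
        stop("step-halving failed to decrease the deviance", call. = FALSE)
    }
    if (any(abs(beta_new) > 30)) {
      worst <- colnames(X)[which.max(abs(beta_new))]
      stop("separation detected: coefficient for '", worst,
           "' diverged beyond 30 on the logit scale", call. = FALSE)
    }
    rel_change <- abs(dev - dev_new) / (abs(dev) + 1e-10)
    beta <- beta_new; p <- p_new; dev <- dev_new
    dev_trace <- c(dev_trace, dev)
    if (rel_change < tol_dev) {
      max_score <- max(abs(drop(crossprod(X, w * (y - p)))))
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("IRLS did not converge in ", max_iter, " iterations (max |score| ",
         format(max_score), ")", call. = FALSE)

  info <- crossprod(X, X * (w * p * (1 - p)))
  cov_model <- solve(info)
  scores <- X * (w * (y - p))
  if (!is.null(cluster))
    scores <- rowsum(scores, group = cluster, reorder = FALSE)
  meat <- crossprod(scores)
  cov_sandwich <- cov_model %*% meat %*% cov_model
  dimnames(cov_model) <- dimnames(cov_sandwich) <-
    list(colnames(X), colnames(X))

  structure(list(coef = setNames(drop(beta), colnames(X)),
                 cov_model = cov_model,
                 cov_sandwich = (cov_sandwich + t(cov_sandwich)) / 2,
                 converged = converged, n_iter = iter, deviance = dev,
                 column_names = colnames(X), n = n,
                 max_score = max_score, deviance_trace = dev_trace),
            class = "wlogit_fit")
}

#' @export
print.wlogit_fit <- function(x, ...) {
  cat("Weighted logistic fit:", x$n, "rows,", length(x$coef),
      "coefficients\n")
  cat("  converged in", x$n_iter, "iterations; deviance",
      format(x$deviance, digits = 8), "\n")
  se <- sqrt(diag(x$cov_sandwich))
  print(cbind(coef = x$coef, se_sandwich = se))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals from a fitted model
#'
#' @param fit A `wlogit_fit`.
#' @param cov_choice `"sandwich"` (default; appropriate under sampling
#'   weights) or `"model"`.
#' @param level Confidence level in (0,1).
#' @return `data.frame` with columns `term`, `or`, `ci_low`, `ci_high`,
#'   `p`, `se_log`; a zero standard error yields a degenerate interval with
#'   `p = NA`.
#' @export
odds_ratios <- function(fit, cov_choice = c("sandwich", "model"),
                        level = 0.95) {
  cov_choice <- match.arg(cov_choice)
  if (!isTRUE(fit$converged))
    stop("fit did not converge", call. = FALSE)
  V <- if (cov_choice == "sandwich") fit$cov_sandwich else fit$cov_model
  if (is.null(V)) stop("requested covariance not available", call. = FALSE)
  se <- sqrt(pmax(diag(V), 0))
  z <- qnorm(1 - (1 - level) / 2)
  p <- ifelse(se > 0, 2 * pnorm(-abs(fit$coef / se)), NA_real_)
  data.frame(term = names(fit$coef), or = exp(fit$coef),
             ci_low = exp(fit$coef - z * se),
             ci_high = exp(fit$coef + z * se),
             p = p, se_log = se, row.names = NULL)
}

#' Serialize a fit to JSON for audit
#' @param fit A `wlogit_fit`.
#' @param path Optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(coef = as.list(fit$coef),
              cov_model = unname(fit$cov_model),
              cov_sandwich = unname(fit$cov_sandwich),
              converged = fit$converged, n_iter = fit$n_iter,
              deviance = fit$deviance, column_names = fit$column_names,
              n = fit$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
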