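# Deterministic report rendering: study-style text tables, TSV and JSON.

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise (NA-safe).
#'
#' @param p Numeric p-value vector.
#' @return Character vector of star strings.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# Odds-ratio display cell, e.g. "2.47*** (2.11 2.89)"
fmt_or_cell <- function(or, lo, hi, p) {
  sprintf("%s%s (%s %s)", formatC(or, format = "f", digits = 2),
          p_stars(p), formatC(lo, format = "f", digits = 2),
          formatC(hi, format = "f", digits = 2))
}

render_grid_text <- function(report) {
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))
  for (id in names(report$grid)) {
    cell <- report$grid[[id]]
    push("[%s] outcome=%s exposure=%s model=%s", id, cell$outcome,
         cell$exposure, cell$model)
    if (!isTRUE(cell$ok)) {
      push("  -- model failed: %s --", cell$error)
      next
    }
    ors <- cell$ors
    push("  joint exposure   ref: Ref.")
    for (term in c("d01", "d10", "d11")) {
      r <- ors[ors$term == term, ]
      push("  joint exposure  %s: %s", term,
           fmt_or_cell(r$or, r$ci_low, r$ci_high, r$p))
    }
    m <- cell$measures
    push("  RERI %s", fmt_measure_cell(m$reri, m$p$reri, m$ci$reri))
    push("  AP   %s", fmt_measure_cell(m$ap, m$p$ap, m$ci$ap))
    push("  S    %s", fmt_measure_cell(m$s, m$p$s, m$ci$s))
  }
  out
}

render_text <- function(report) {
  out <- c("Study report", "============", "", format(report$flow), "")
  out <- c(out, "Weighted prevalence of the primary outcome", "")
  t1 <- report$table1
  for (i in seq_len(nrow(t1))) {
    r <- t1[i, ]
    cell <- if (r$undefined) "undefined"
    else sprintf("%s (%s,%s)",
                 formatC(100 * r$est, format = "f", digits = 1),
                 formatC(100 * r$ci_low, format = "f", digits = 1),
                 formatC(100 * r$ci_high, format = "f", digits = 1))
    out <- c(out, sprintf("  %-16s %-10s n=%-6d %s", r$variable,
                          as.character(r$group), r$n, cell))
  }
  out <- c(out, "", "Joint-exposure prevalence and chi-square", "")
  for (id in names(report$table2)) {
    blk <- report$table2[[id]]
    chi_txt <- if (blk$chi_square$valid)
      sprintf("chi2=%s df=%d p=%s",
              formatC(blk$chi_square$statistic, format = "f", digits = 2),
              blk$chi_square$df,
              formatC(blk$chi_square$p, format = "g", digits = 3))
    else "chi2 invalid (zero expected count)"
    out <- c(out, sprintf("[%s] outcome=%s exposure=%s  %s", id,
                          blk$outcome, blk$exposure, chi_txt))
    pr <- blk$prevalence
    for (i in seq_len(nrow(pr))) {
      r <- pr[i, ]
      cell <- if (r$undefined) "undefined"
      else sprintf("%s (%s,%s)",
                   formatC(100 * r$est, format = "f", digits = 1),
                   formatC(100 * r$ci_low, format = "f", digits = 1),
                   formatC(100 * r$ci_high, format = "f", digits = 1))
      out <- c(out, sprintf("  %-8s n=%-6d %s", as.character(r$group),
                            r$n, cell))
    }
  }
  out <- c(out, "", "Per-exposure odds ratios (primary outcome)", "")
  for (vn in names(report$table3)) {
    rowtxt <- vapply(c("unadjusted", "adjusted"), function(m) {
      r <- report$table3[[vn]][[m]]
      if (is.character(r)) sprintf("[failed: %s]", r)
      else fmt_or_cell(r$or, r$ci_low, r$ci_high, r$p)
    }, "")
    out <- c(out, sprintf("  %-14s UOR %s   AOR %s", vn, rowtxt[1],
                          rowtxt[2]))
  }
  out <- c(out, "", "Additive interaction grid", "",
           render_grid_text(report))
  paste(out, collapse = "\n")
}

render_tsv <- function(report) {
  rows <- list("cell\tmodel\tmeasure\tvalue\tp\tci_low\tci_high\tclass")
  for (id in names(report$grid)) {
    cell <- report$grid[[id]]
    key <- paste(cell$outcome, cell$exposure, sep = "~")
    if (!isTRUE(cell$ok)) {
      rows[[length(rows) + 1]] <-
        sprintf("%s\t%s\tERROR\t%s\tNA\tNA\tNA\tNA", key, cell$model,
                cell$error)
      next
    }
    m <- cell$measures
    for (meas in c("reri", "ap", "s")) {
      v <- m[[meas]]; p <- m$p[[meas]]; ci <- m$ci[[meas]]
      rows[[length(rows) + 1]] <- sprintf(
        "%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s", key, cell$model, toupper(meas),
        formatC(v, format = "f", digits = 6),
        ifelse(is.na(p), "NA", formatC(p, format = "g", digits = 6)),
        ifelse(is.na(ci[1]), "NA", formatC(ci[1], format = "f",
                                           digits = 6)),
        ifelse(is.na(ci[2]), "NA", formatC(ci[2], format = "f",
                                           digits = 6)),
        m$classification[[meas]])
    }
  }
  paste(unlist(rows), collapse = "\n")
}

render_json <- function(report) {
  grid <- lapply(report$grid, function(cell) {
    if (!isTRUE(cell$ok))
      return(list(outcome = cell$outcome, exposure = cell$exposure,
                  model = cell$model, ok = FALSE, error = cell$error))
    m <- cell$measures
    list(outcome = cell$outcome, exposure = cell$exposure,
         model = cell$model, ok = TRUE,
         odds_ratios = cell$ors,
         measures = list(reri = m$reri, ap = m$ap, s = m$s,
                         ci = m$ci, p = m$p,
                         classification = as.list(m$classification),
                         significant = as.list(m$significant)))
  })
  obj <- list(flow = unclass(report$flow), n_analytic = report$n_analytic,
              prevalence = report$table1, grid = grid)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                na = "null", dataframe = "rows"))
}

#' Render a study report
#'
#' Deterministic byte output: the same report renders to identical bytes.
#' Table cells follow the display conventions of the motivating study
#' (odds ratios and S to 2 decimals, significance stars `***`/`**`/`*` for
#' p below 0.001/0.01/0.05, measure cells as `estimate; p (low high)`).
#'
#' @param report A `study_report` from [run_study()].
#' @param fmt One of `"text"`, `"tsv"`, `"json"`.
#' @param path Optional output file path.
#' @return The rendered string, invisibly when written to `path`.
#' @export
render_report <- function(report, fmt = c("text", "tsv", "json"),
                          path = NULL) {
  if (!inherits(report, "study_report"))
    stop("report must be a study_report", call. = FALSE)
  if (length(fmt) != 1 && !identical(fmt, c("text", "tsv", "json")))
    fmt <- fmt[1]
  fmt <- match.arg(fmt)
  out <- switch(fmt, text = render_text(report), tsv = render_tsv(report),
                json = render_json(report))
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Published joint-exposure odds-ratio grid used in worked examples
#'
#' The 2x2 grid (two diabetes definitions x two hypertension definitions)
#' of joint-exposure odds ratios transcribed from a published
#' population-based analysis of family history of diabetes and
#' hypertension among Indian adults aged 45 and above, together with the
#' additive-interaction values that study printed. `or01` is the
#' hypertension-only OR, `or10` the family-history-only OR, `or11` the
#' doubly exposed OR. The unadjusted section `2A` is known to be internally
#' inconsistent in the source (its printed measures do not follow from its
#' printed ORs) and is excluded from worked-example checks.
#'
#' @return `data.frame` with columns `section`, `outcome`, `exposure`,
#'   `model`, `or01`, `or10`, `or11`, `reri_printed`, `ap_printed`,
#'   `s_printed`, `consistent`.
#' @export
#' @examples
#' subset(published_joint_ors(), model == "unadjusted")
published_joint_ors <- function() {
  path <- system.file("extdata", "published_joint_ors.csv",
                      package = "addinter")
  read.csv(path, stringsAsFactors = FALSE)
}
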