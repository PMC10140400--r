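# Association screening between survey variables and burnout status:
# uncorrected Pearson chi-squared for categorical variables, Wilcoxon
# rank-sum (normal approximation, tie-corrected, continuity-corrected) for
# numeric ones. No multiple-testing correction is applied.

#' Pearson chi-squared test of independence for a levels x burnout table
#'
#' Computes the uncorrected Pearson statistic sum (O - E)^2 / E with
#' expected counts from the margins and an upper-tail p-value on
#' (r-1)(c-1) degrees of freedom. No continuity correction is applied for
#' 2x2 tables: that is the convention under which the recomputable
#' published p-values of the reference cohort are reproduced. Expected
#' counts below 5 trigger a warning, not an error.
#'
#' @param counts r x c matrix of nonnegative counts (r >= 2 levels,
#'   typically c = 2 burnout groups).
#' @param variable variable name carried into the result.
#' @return object of class `burnout_test` with fields `variable`,
#'   `test_name`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' # high blood pressure, reference cohort: p rounds to 0.09
#' chi_squared_test(cohort_contingency("high_blood_pressure"))$p_value
chi_squared_test <- function(counts, variable = "") {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be nonnegative with a positive grand total")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0)) {
    lev <- rownames(counts)[which(rs == 0)[1]]
    stop("empty level (zero row margin): ",
         if (is.null(lev)) which(rs == 0)[1] else lev)
  }
  if (any(cs == 0)) {
    grp <- colnames(counts)[which(cs == 0)[1]]
    stop("empty group (zero column margin): ",
         if (is.null(grp)) which(cs == 0)[1] else grp)
  }
  expected <- outer(rs, cs) / sum(counts)
  if (any(expected < 5))
    warning("expected count below 5 for '", variable,
            "': chi-squared approximation may be inaccurate")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(variable = variable, test_name = "chi_squared",
         statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value)),
    class = "burnout_test"
  )
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The default path uses
#' the normal approximation with tie-corrected variance and continuity
#' correction (appropriate at cohort scale); `exact = TRUE` switches to the
#' exact distribution (small untied samples only).
#'
#' @param x,y numeric samples (both nonempty).
#' @param variable variable name carried into the result.
#' @param exact use the exact null distribution instead of the normal
#'   approximation.
#' @return object of class `burnout_test`; `statistic` is the Mann-Whitney
#'   form (rank sum of `x` minus its minimum possible value).
#' @export
wilcoxon_rank_sum <- function(x, y, variable = "", exact = FALSE) {
  if (!length(x) || !length(y))
    stop("both samples must be nonempty")
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  structure(
    list(variable = variable, test_name = "wilcoxon",
         statistic = unname(res$statistic), df = NA_integer_,
         p_value = unname(res$p.value)),
    class = "burnout_test"
  )
}

#' @export
print.burnout_test <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g%s, p = %.4g\n",
              if (nzchar(x$variable)) x$variable else "(unnamed)",
              x$test_name, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %d", x$df),
              x$p_value))
  invisible(x)
}

burnout_contingency <- function(tab, variable, spec, burnout_col) {
  lev <- spec$levels
  status <- factor(tab[[burnout_col]], levels = c("low", "high"))
  x <- factor(tab[[variable]], levels = lev)
  counts <- base::table(x, status)
  m <- matrix(as.integer(counts), nrow = length(lev),
              dimnames = list(lev, c("low", "high")))
  # unobserved levels carry no information; drop rather than error
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Screen survey variables for association with burnout
#'
#' Runs the appropriate test per variable kind (chi-squared for categorical,
#' Wilcoxon rank-sum for numeric) against the burnout label and selects
#' variables with p below `alpha`, grouped into the four variable
#' categories. Ordering follows the schema; no multiplicity adjustment.
#'
#' @param table a `survey_table` with burnout labels.
#' @param schema a [survey_schema()].
#' @param alpha significance threshold (default 0.05).
#' @return object of class `burnout_screen`: list with `results` (one row
#'   per tested variable: variable, category, test, statistic, df, p_value,
#'   significant), `selected` (named list of significant variable names per
#'   category) and `alpha`.
#' @export
screen_variables <- function(table, schema, alpha = 0.05) {
  bcol <- schema$burnout_label_name
  if (!bcol %in% names(table))
    stop("burnout labels ('", bcol, "') missing from table")
  vars <- intersect(names(schema$variables), names(table))
  rows <- list()
  for (v in vars) {
    spec <- schema$variables[[v]]
    res <- if (spec$kind == "numeric") {
      x <- as.numeric(table[[v]][table[[bcol]] == "low"])
      y <- as.numeric(table[[v]][table[[bcol]] == "high"])
      wilcoxon_rank_sum(x, y, variable = v)
    } else {
      chi_squared_test(burnout_contingency(table, v, spec, bcol), variable = v)
    }
    rows[[v]] <- data.frame(
      variable = v, category = spec$category, test = res$test_name,
      statistic = res$statistic, df = res$df, p_value = res$p_value,
      significant = res$p_value < alpha, stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  categories <- c("demographic", "work_related", "health", "lifestyle")
  selected <- lapply(setNames(categories, categories), function(cat)
    results$variable[results$category == cat & results$significant])
  structure(list(results = results, selected = selected, alpha = alpha),
            class = "burnout_screen")
}

#' @export
print.burnout_screen <- function(x, ...) {
  cat("burnout_screen: ", sum(x$results$significant), "/",
      nrow(x$results), " variables significant at alpha = ", x$alpha,
      "\n", sep = "")
  for (cat_ in names(x$selected))
    if (length(x$selected[[cat_]]))
      cat("  ", cat_, ": ", paste(x$selected[[cat_]], collapse = ", "),
          "\n", sep = "")
  invisible(x)
}

#' Cohort characteristics report by burnout group
#'
#' Builds the standard descriptive table of an occupational-burnout cohort:
#' per-level counts with within-group percentages for categorical
#' variables, median (IQR) for numeric variables, and the per-variable test
#' p-value, split by burnout group.
#'
#' @param table a `survey_table` with burnout labels.
#' @param schema a [survey_schema()].
#' @return data.frame of class `table1_report` with columns `category`,
#'   `variable`, `level`, `overall`, `low`, `high` (formatted cells) and
#'   `p_value` (numeric, repeated per variable).
#' @export
table1_report <- function(table, schema) {
  bcol <- schema$burnout_label_name
  if (!bcol %in% names(table))
    stop("burnout labels ('", bcol, "') missing from table")
  scr <- screen_variables(table, schema, alpha = 0.05)
  pvals <- setNames(scr$results$p_value, scr$results$variable)
  status <- table[[bcol]]
  fmt_count <- function(k, n) sprintf("%d (%.1f)", k, if (n > 0) 100 * k / n else 0 * k)
  fmt_med <- function(x) {
    q <- stats::quantile(as.numeric(x), c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  rows <- list()
  for (v in intersect(names(schema$variables), names(table))) {
    spec <- schema$variables[[v]]
    if (spec$kind == "numeric") {
      rows[[v]] <- data.frame(
        category = spec$category, variable = spec$label, level = "",
        overall = fmt_med(table[[v]]),
        low = fmt_med(table[[v]][status == "low"]),
        high = fmt_med(table[[v]][status == "high"]),
        p_value = unname(pvals[v]), stringsAsFactors = FALSE
      )
    } else {
      k_all <- vapply(spec$levels, function(l) sum(table[[v]] == l), 0L)
      k_low <- vapply(spec$levels, function(l)
        sum(table[[v]] == l & status == "low"), 0L)
      k_high <- vapply(spec$levels, function(l)
        sum(table[[v]] == l & status == "high"), 0L)
      rows[[v]] <- data.frame(
        category = spec$category, variable = spec$label, level = spec$levels,
        overall = fmt_count(k_all, nrow(table)),
        low = fmt_count(k_low, sum(status == "low")),
        high = fmt_count(k_high, sum(status == "high")),
        p_value = unname(pvals[v]), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("table1_report", "data.frame")
  out
}

#' Write a cohort report as TSV or Markdown
#'
#' @param report a [table1_report()] result.
#' @param path output path.
#' @param format `"tsv"` or `"markdown"`.
#' @export
write_report <- function(report, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    fmt_p <- function(p) ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))
    lines <- c(
      "| Category | Variable | Level | Overall | Low | High | p |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s | %s | %s |",
              report$category, report$variable, report$level,
              report$overall, report$low, report$high, fmt_p(report$p_value))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
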