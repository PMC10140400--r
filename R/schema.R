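#' Define a survey variable
#'
#' A variable specification carries everything the simulator and encoder
#' need: measurement kind, level set (for categorical kinds), admissible
#' range and a generating location/scale (for numeric kinds), and default
#' marginal level probabilities.
#'
#' @param name variable id (unique within a schema).
#' @param category one of `"demographic"`, `"work_related"`, `"health"`,
#'   `"lifestyle"`.
#' @param kind one of `"numeric"`, `"ordinal"`, `"nominal"`, `"binary"`.
#' @param levels ordered character vector of level labels (>= 2 for
#'   categorical kinds; ignored for numeric).
#' @param range numeric `c(min, max)` for numeric variables (min < max).
#' @param probs default marginal level probabilities (categorical kinds);
#'   recycled to uniform when omitted.
#' @param mean,sd generating location and scale for numeric variables
#'   (truncated-normal simulation within `range`).
#' @param label human-readable display name used in reports.
#' @return object of class `variable_spec`.
#' @export
variable_spec <- function(name, category, kind, levels = character(),
                          range = NULL, probs = NULL,
                          mean = NULL, sd = NULL, label = name) {
  categories <- c("demographic", "work_related", "health", "lifestyle")
  kinds <- c("numeric", "ordinal", "nominal", "binary")
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("variable name must be a non-empty string")
  category <- match.arg(category, categories)
  kind <- match.arg(kind, kinds)
  if (kind == "numeric") {
    if (is.null(range) || length(range) != 2 || !(range[1] < range[2]))
      stop("numeric variable '", name, "' needs range c(min, max) with min < max")
    if (is.null(mean)) mean <- sum(range) / 2
    if (is.null(sd)) sd <- diff(range) / 6
    levels <- character()
    probs <- NULL
  } else {
    if (length(levels) < 2)
      stop("categorical variable '", name, "' needs >= 2 levels")
    if (kind == "binary" && length(levels) != 2)
      stop("binary variable '", name, "' needs exactly 2 levels")
    if (anyDuplicated(levels))
      stop("duplicate levels in variable '", name, "'")
    if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
    if (length(probs) != length(levels) || any(probs < 0) || sum(probs) <= 0)
      stop("probs for '", name, "' must be nonnegative, one per level")
    probs <- probs / sum(probs)
    range <- NULL
  }
  structure(
    list(name = name, category = category, kind = kind, levels = levels,
         range = range, probs = probs, mean = mean, sd = sd, label = label),
    class = "variable_spec"
  )
}

#' Assemble a survey schema
#'
#' @param variables list of [variable_spec()] objects with unique names.
#' @param burnout_label_name name of the burnout status column.
#' @return object of class `survey_schema`.
#' @export
survey_schema <- function(variables, burnout_label_name = "burnout") {
  if (!length(variables) || !all(vapply(variables, inherits, TRUE, "variable_spec")))
    stop("variables must be a non-empty list of variable_spec objects")
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (burnout_label_name %in% nms)
    stop("burnout label name collides with a variable name")
  names(variables) <- nms
  structure(list(variables = variables, burnout_label_name = burnout_label_name),
            class = "survey_schema")
}

#' @export
print.survey_schema <- function(x, ...) {
  cats <- vapply(x$variables, `[[`, "", "category")
  cat("survey_schema:", length(x$variables), "variables (",
      paste(sprintf("%s: %d", names(table(cats)), as.integer(table(cats))),
            collapse = ", "),
      "); burnout label:", x$burnout_label_name, "\n")
  invisible(x)
}

schema_variable <- function(schema, name) {
  v <- schema$variables[[name]]
  if (is.null(v)) stop("unknown schema variable: ", name)
  v
}

#' Default airport-cohort survey schema
#'
#' Schema mirroring the reference occupational-health cohort: age and
#' weekly walking time as numeric variables, plus 32 categorical variables
#' across the demographic, work-related, health and lifestyle categories.
#' Marginal level probabilities are set from the pooled (low + high) group
#' counts of [cohort_reference()].
#'
#' @return a [survey_schema()].
#' @export
#' @examples
#' sch <- default_schema()
#' length(sch$variables[["position"]]$levels)  # 5 position types
default_schema <- function() {
  ref <- cohort_reference()
  vars <- list()
  for (i in seq_len(nrow(ref$numeric))) {
    r <- ref$numeric[i, ]
    # location/scale chosen so the truncated normal roughly matches the
    # published median and IQR of the pooled cohort
    vars[[r$variable]] <- variable_spec(
      r$variable, r$category, "numeric", range = c(r$min, r$max),
      mean = r$median_low, sd = (r$q3_low - r$q1_low) / 1.35, label = r$label
    )
  }
  for (v in unique(ref$categorical$variable)) {
    rows <- ref$categorical[ref$categorical$variable == v, ]
    total <- rows$low + rows$high
    vars[[v]] <- variable_spec(
      v, rows$category[1], rows$kind[1], levels = rows$level,
      probs = total / sum(total), label = rows$label[1]
    )
  }
  survey_schema(vars)
}

#' Burnout effect sizes estimated from the reference cohort
#'
#' Converts the reference cohort's group-level distributions into the
#' effect-size parameterisation of [simulation_config()]: per-level
#' log-odds shifts `log p_high(level) - log p_low(level)` for categorical
#' variables (zero-count levels are smoothed by adding 0.5), and location
#' shifts in units of the variable range (difference of group medians over
#' range width) for numeric variables. Simulating with these effects yields
#' synthetic cohorts with burnout-group contrasts of realistic magnitude.
#'
#' @param schema a [survey_schema()]; only variables present in both the
#'   schema and the reference table receive an effect.
#' @return named list of numeric effect vectors/scalars.
#' @export
cohort_effect_sizes <- function(schema = default_schema()) {
  ref <- cohort_reference()
  eff <- list()
  for (v in names(schema$variables)) {
    spec <- schema$variables[[v]]
    if (spec$kind == "numeric") {
      r <- ref$numeric[ref$numeric$variable == v, ]
      if (nrow(r) == 1)
        eff[[v]] <- (r$median_high - r$median_low) / (r$max - r$min)
    } else {
      rows <- ref$categorical[ref$categorical$variable == v, ]
      if (nrow(rows) == length(spec$levels)) {
        p_low <- (rows$low + 0.5) / sum(rows$low + 0.5)
        p_high <- (rows$high + 0.5) / sum(rows$high + 0.5)
        e <- log(p_high) - log(p_low)
        names(e) <- rows$level
        eff[[v]] <- e
      }
    }
  }
  eff
}

#' Simulation settings for a synthetic survey cohort
#'
#' @param n_respondents number of respondents (>= 2).
#' @param burnout_prevalence probability of high burnout status; defaults to
#'   the reference cohort prevalence 728/5794.
#' @param effect_sizes named list of burnout effects: for a categorical
#'   variable, a per-level log-odds shift vector (added to the log of the
#'   marginal level probabilities for high-burnout respondents, then
#'   renormalised; zero means exact null); for a numeric variable, a scalar
#'   location shift expressed as a fraction of the variable range.
#' @param seed integer RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_respondents,
                              burnout_prevalence = 728 / 5794,
                              effect_sizes = list(), seed = 1L) {
  if (!is.numeric(n_respondents) || n_respondents < 2)
    stop("n_respondents must be >= 2")
  if (!is.numeric(burnout_prevalence) ||
      burnout_prevalence <= 0 || burnout_prevalence >= 1)
    stop("burnout_prevalence must lie in (0, 1)")
  if (length(effect_sizes) && is.null(names(effect_sizes)))
    stop("effect_sizes must be a named list")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  structure(
    list(n_respondents = as.integer(n_respondents),
         burnout_prevalence = burnout_prevalence,
         effect_sizes = effect_sizes, seed = as.integer(seed)),
    class = "simulation_config"
  )
}
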