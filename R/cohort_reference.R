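#' Reference descriptive statistics for the motivating airport-staff cohort
#'
#' Published descriptive statistics of the cross-sectional occupational-health
#' survey of a large Chinese airport company (November 2021) that motivates
#' this package: 6,689 questionnaires returned, 5,794 valid respondents, of
#' whom 728 were scored at high burnout risk on the MBI-GS. Per-level
#' respondent counts are reported separately for the low- and high-burnout
#' groups; numeric variables (age, weekly walking time) are summarised as
#' median and interquartile range.
#'
#' The printed table contains a few internal inconsistencies in its
#' "Overall" column (e.g. the professional-grade 6-8 row and the
#' "relatively healthy" row disagree with the sum of the two group counts);
#' the group-level counts are self-consistent (each group column sums to its
#' group size) and are therefore treated as authoritative everywhere in this
#' package.
#'
#' @return A list with components:
#'   \describe{
#'     \item{categorical}{data.frame with columns `variable`, `label`,
#'       `category`, `kind`, `level`, `low`, `high` — respondent counts per
#'       level in the low/high burnout groups.}
#'     \item{numeric}{data.frame with columns `variable`, `label`,
#'       `category`, `min`, `max`, and the published medians / quartiles per
#'       group (`median_low`, `q1_low`, `q3_low`, `median_high`, `q1_high`,
#'       `q3_high`).}
#'     \item{n_low, n_high, n_total}{group and total sizes (5,066 / 728 /
#'       5,794).}
#'     \item{n_returned}{questionnaires returned before validity
#'       exclusions (6,689).}
#'   }
#' @export
#' @examples
#' ref <- cohort_reference()
#' ref$n_high / ref$n_total     # high-burnout prevalence ~ 0.126
cohort_reference <- function() {
  cat_row <- function(variable, label, category, kind, levels, low, high) {
    stopifnot(length(levels) == length(low), length(low) == length(high))
    data.frame(
      variable = variable, label = label, category = category, kind = kind,
      level = levels, low = low, high = high, stringsAsFactors = FALSE
    )
  }
  categorical <- rbind(
    cat_row("sex", "Sex", "demographic", "binary",
            c("Female", "Male"), c(1882L, 3184L), c(293L, 435L)),
    cat_row("marital_status", "Marital status", "demographic", "nominal",
            c("Married", "Unmarried", "Widowed", "Divorced"),
            c(2987L, 1946L, 15L, 118L), c(384L, 317L, 3L, 24L)),
    cat_row("education", "Education background", "demographic", "ordinal",
            c("High school", "College", "University", "Graduate"),
            c(1127L, 2359L, 1440L, 140L), c(126L, 369L, 221L, 12L)),
    cat_row("position", "Type of position", "work_related", "nominal",
            c("Management", "Profession", "Aviation Technology",
              "General Technology", "Assistant"),
            c(352L, 1039L, 1588L, 842L, 1245L),
            c(42L, 153L, 275L, 105L, 153L)),
    cat_row("professional_grade", "Professional grade", "work_related", "ordinal",
            c("6-8", "9-10", "11-13", "14-15", "16-18", "19 or above", "others"),
            c(1353L, 1858L, 1084L, 328L, 300L, 124L, 19L),
            c(166L, 308L, 150L, 42L, 41L, 20L, 1L)),
    cat_row("self_rated_health", "Self-rated health status", "health", "ordinal",
            c("Healthy", "Relatively healthy", "Sub-health", "Unhealthy"),
            c(1093L, 2107L, 1605L, 261L), c(109L, 201L, 325L, 93L)),
    cat_row("hospital_admission", "Hospital admission in the last 3 years",
            "health", "ordinal",
            c("Two or more times", "Once", "Never"),
            c(144L, 577L, 4345L), c(38L, 77L, 613L)),
    cat_row("arthritis", "Arthritis", "health", "binary",
            c("Yes", "No"), c(936L, 4130L), c(189L, 539L)),
    cat_row("high_blood_pressure", "High blood pressure", "health", "binary",
            c("Yes", "No"), c(389L, 4677L), c(69L, 659L)),
    cat_row("cardiovascular", "Cardiovascular diseases", "health", "binary",
            c("Yes", "No"), c(66L, 5000L), c(25L, 703L)),
    cat_row("high_blood_lipid", "High blood lipid", "health", "binary",
            c("Yes", "No"), c(412L, 4654L), c(94L, 634L)),
    cat_row("breast_diseases", "Breast diseases", "health", "binary",
            c("Yes", "No"), c(226L, 4840L), c(57L, 671L)),
    cat_row("overweight", "Overweight", "health", "binary",
            c("Yes", "No"), c(858L, 4208L), c(143L, 585L)),
    cat_row("other_chronic", "Other chronic diseases", "health", "binary",
            c("Yes", "No"), c(651L, 4415L), c(153L, 575L)),
    cat_row("breakfast", "Breakfast frequency", "lifestyle", "ordinal",
            c("Almost everyday", "3 days or more per week",
              "Less than 1 day per week"),
            c(2868L, 1821L, 377L), c(322L, 302L, 104L)),
    cat_row("smoked_food", "Smoked food consumption", "lifestyle", "ordinal",
            c("Often", "Sometimes", "Almost never"),
            c(360L, 3443L, 1263L), c(71L, 482L, 175L)),
    cat_row("dairy", "Dairy consumption", "lifestyle", "nominal",
            c("< 200 ML/day", "200-300 ML/day", "> 400 ML/day", "Almost never"),
            c(2261L, 976L, 158L, 1671L), c(329L, 96L, 20L, 283L)),
    cat_row("salt_tool", "Salt-limiting tool usage", "lifestyle", "ordinal",
            c("Almost never", "Sometimes", "Often", "Always"),
            c(3329L, 885L, 370L, 482L), c(524L, 100L, 41L, 63L)),
    cat_row("taste_change", "Change of taste", "lifestyle", "nominal",
            c("Salty", "Light", "No change"),
            c(539L, 1273L, 3254L), c(99L, 188L, 441L)),
    cat_row("oil_tool", "Oil-limiting tool usage", "lifestyle", "ordinal",
            c("Almost never", "Sometimes", "Often", "Always"),
            c(3637L, 726L, 332L, 371L), c(572L, 77L, 36L, 43L)),
    cat_row("oil_change", "Change of oil consumption", "lifestyle", "nominal",
            c("More", "Less", "No change"),
            c(395L, 1189L, 3482L), c(74L, 149L, 505L)),
    cat_row("vegetables", "Vegetable consumption", "lifestyle", "nominal",
            c("Almost never", "1-3 times/week", "4-6 times/week", "1 time/day",
              "2 times/day", "3 times/day", "Do not remember"),
            c(379L, 1094L, 977L, 858L, 779L, 132L, 847L),
            c(63L, 172L, 111L, 103L, 97L, 18L, 164L)),
    cat_row("pedometer", "Pedometer (step counter) usage", "lifestyle", "ordinal",
            c("Often", "Sometimes", "Never"),
            c(1435L, 1333L, 2298L), c(180L, 159L, 389L)),
    cat_row("weight_status", "Weight status", "lifestyle", "nominal",
            c("Underweight", "Normal", "Overweight", "Do not know"),
            c(663L, 1939L, 2061L, 403L), c(115L, 253L, 287L, 73L)),
    cat_row("smoking", "Smoking (in the past year)", "lifestyle", "ordinal",
            c("Everyday", "Sometimes", "Never"),
            c(973L, 682L, 3411L), c(155L, 78L, 495L)),
    cat_row("various_food", "Consumed various types of food (in the past year)",
            "lifestyle", "binary",
            c("Yes", "No"), c(3629L, 1437L), c(466L, 262L)),
    cat_row("fresh_fruit_veg", "Fresh fruit and vegetable consumption (in the past year)",
            "lifestyle", "binary",
            c("Enough", "Not enough"), c(2701L, 2365L), c(326L, 402L)),
    cat_row("oily_food", "Oily food consumption (in the past year)",
            "lifestyle", "binary",
            c("Often", "Not often"), c(1174L, 3892L), c(198L, 530L)),
    cat_row("exercise", "Physical exercise participation (in the past year)",
            "lifestyle", "binary",
            c("Often", "Not often"), c(2400L, 2666L), c(257L, 471L)),
    cat_row("limit_salt", "Limit salt consumption", "lifestyle", "binary",
            c("Yes", "No"), c(3239L, 1827L), c(394L, 334L)),
    cat_row("limit_oil", "Limit oil consumption", "lifestyle", "binary",
            c("Yes", "No"), c(2543L, 2523L), c(312L, 416L)),
    cat_row("keep_weight", "Keep weight", "lifestyle", "binary",
            c("Yes", "No"), c(2702L, 2364L), c(307L, 421L))
  )
  numeric <- data.frame(
    variable = c("age", "walk_time"),
    label = c("Age (years)", "Walk time (min/week)"),
    category = c("demographic", "lifestyle"),
    min = c(18, 0), max = c(60, 600),
    median_low = c(33, 76.5), q1_low = c(25, 60), q3_low = c(41, 180),
    median_high = c(31, 80), q1_high = c(25, 60), q3_high = c(39, 264),
    stringsAsFactors = FALSE
  )
  list(categorical = categorical, numeric = numeric,
       n_low = 5066L, n_high = 728L, n_total = 5794L, n_returned = 6689L)
}

#' Burnout-by-level contingency table for a reference cohort variable
#'
#' Builds the levels x {low, high} count matrix for one categorical variable
#' of [cohort_reference()], in the form consumed by [chi_squared_test()].
#'
#' @param variable variable id (see `cohort_reference()$categorical$variable`).
#' @return integer matrix, rows = variable levels, columns `low`, `high`.
#' @export
#' @examples
#' cohort_contingency("high_blood_pressure")
cohort_contingency <- function(variable) {
  ref <- cohort_reference()$categorical
  rows <- ref[ref$variable == variable, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("unknown reference variable: ", variable)
  m <- cbind(low = rows$low, high = rows$high)
  rownames(m) <- rows$level
  m
}
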