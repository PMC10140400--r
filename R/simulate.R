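# Synthetic cohort generator. Categorical variables are drawn from their
# schema marginals, tilted on the log-odds scale for high-burnout
# respondents; numeric variables from a range-truncated normal with a
# location shift proportional to the range. Zero effects give an exact null.

rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic survey cohort
#'
#' Draws `n_respondents` rows: a Bernoulli burnout status at the configured
#' prevalence, then each schema variable from its marginal distribution,
#' shifted for high-burnout respondents according to
#' `config$effect_sizes`. Runs are reproducible for a fixed seed.
#'
#' @param schema a [survey_schema()].
#' @param config a [simulation_config()]; its `effect_sizes` may only
#'   reference schema variables.
#' @return a `survey_table`: data.frame with `respondent_id`, one column per
#'   schema variable, and the burnout label column (`"low"`/`"high"`).
#' @export
#' @examples
#' tab <- generate_survey(default_schema(), simulation_config(200, seed = 7))
#' table(tab$burnout)
generate_survey <- function(schema, config) {
  stopifnot(inherits(schema, "survey_schema"),
            inherits(config, "simulation_config"))
  unknown <- setdiff(names(config$effect_sizes), names(schema$variables))
  if (length(unknown))
    stop("effect_sizes reference unknown variables: ",
         paste(unknown, collapse = ", "))
  n <- config$n_respondents
  set.seed(config$seed)
  status <- ifelse(stats::runif(n) < config$burnout_prevalence, "high", "low")
  hi <- status == "high"
  out <- list(respondent_id = sprintf("R%05d", seq_len(n)))
  for (v in names(schema$variables)) {
    spec <- schema$variables[[v]]
    eff <- config$effect_sizes[[v]]
    if (spec$kind == "numeric") {
      shift <- if (is.null(eff)) 0 else eff[1] * diff(spec$range)
      mu <- ifelse(hi, spec$mean + shift, spec$mean)
      x <- rtruncnorm(n, mu, spec$sd, spec$range[1], spec$range[2])
      out[[v]] <- round(x, 1)
    } else {
      L <- length(spec$levels)
      if (is.null(eff)) eff <- rep(0, L)
      if (length(eff) != L)
        stop("effect for '", v, "' must have one entry per level (", L, ")")
      p_high <- spec$probs * exp(eff)
      p_high <- p_high / sum(p_high)
      x <- character(n)
      if (any(!hi))
        x[!hi] <- sample(spec$levels, sum(!hi), replace = TRUE, prob = spec$probs)
      if (any(hi))
        x[hi] <- sample(spec$levels, sum(hi), replace = TRUE, prob = p_high)
      out[[v]] <- x
    }
  }
  out[[schema$burnout_label_name]] <- status
  res <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  class(res) <- c("survey_table", "data.frame")
  res
}

#' Generate synthetic MBI-GS item responses
#'
#' Draws 16 item scores on the 0-6 scale per respondent so that scoring with
#' the same critical boundaries recovers the generating burnout label with
#' high probability: high-burnout respondents receive exhaustion and
#' cynicism subscale means `separation` points above the boundaries and a
#' professional-efficacy mean whose reversed score (6 - mean) also sits
#' above its boundary; low-burnout respondents the mirror image.
#'
#' @param n number of respondents (0 gives an empty 16-column table).
#' @param burnout_status character vector of length `n` (`"low"`/`"high"`).
#' @param seed integer RNG seed.
#' @param boundaries critical boundaries `c(exhaustion, cynicism, efficacy)`
#'   on the 0-6 subscale-mean scale (efficacy compared after reversal).
#' @param separation distance of the generating subscale means from the
#'   boundaries, in scale points.
#' @param subject_sd between-respondent SD of subscale means.
#' @param item_sd within-subscale item SD around the respondent mean.
#' @return data.frame of 16 integer columns `mbi_01` .. `mbi_16` (items 1-5
#'   exhaustion, 6-10 cynicism, 11-16 professional efficacy).
#' @export
generate_mbi_items <- function(n, burnout_status, seed = 1L,
                               boundaries = c(3, 3, 3), separation = 1.5,
                               subject_sd = 0.7, item_sd = 0.8) {
  if (n != length(burnout_status))
    stop("burnout_status must have length n")
  cols <- sprintf("mbi_%02d", 1:16)
  if (n == 0) {
    out <- as.data.frame(matrix(integer(), 0, 16, dimnames = list(NULL, cols)))
    return(out)
  }
  stopifnot(all(burnout_status %in% c("low", "high")), length(boundaries) == 3)
  set.seed(as.integer(seed))
  hi <- burnout_status == "high"
  clamp <- function(x) pmin(6, pmax(0, x))
  # generating subscale-mean targets (efficacy on the raw, unreversed scale)
  mu_exh <- clamp(ifelse(hi, boundaries[1] + separation, boundaries[1] - separation))
  mu_cyn <- clamp(ifelse(hi, boundaries[2] + separation, boundaries[2] - separation))
  mu_eff <- clamp(ifelse(hi, 6 - (boundaries[3] + separation),
                             6 - (boundaries[3] - separation)))
  subj <- function(mu) clamp(stats::rnorm(n, mu, subject_sd))
  m <- cbind(matrix(rep(subj(mu_exh), 5), n, 5),
             matrix(rep(subj(mu_cyn), 5), n, 5),
             matrix(rep(subj(mu_eff), 6), n, 6))
  items <- matrix(as.integer(clamp(round(m + stats::rnorm(n * 16, 0, item_sd)))),
                  n, 16, dimnames = list(NULL, cols))
  as.data.frame(items)
}
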