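# Survey table I/O, MBI-GS scoring, and [0,1] feature encoding.

#' @rdname read_survey
#' @export
write_survey <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a survey table
#'
#' CSV with a header row, one respondent per row. On read, the table must
#' carry either a burnout label column or the 16 MBI item columns
#' (`mbi_01` .. `mbi_16`); respondent ids must be unique; categorical cells
#' must be valid levels of their schema variable; missing cells are
#' rejected.
#'
#' @param path file path.
#' @param table a `survey_table` (or plain data.frame) to write.
#' @param schema a [survey_schema()] used to validate categorical levels.
#' @return `read_survey`: a validated `survey_table`.
#' @export
read_survey <- function(path, schema = default_schema()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0)
    stop("survey file is empty: ", path)
  if (!"respondent_id" %in% names(tab))
    stop("survey file lacks a respondent_id column")
  dup <- duplicated(tab$respondent_id)
  if (any(dup))
    stop("duplicate respondent ids: ",
         paste(unique(tab$respondent_id[dup]), collapse = ", "))
  mbi_cols <- sprintf("mbi_%02d", 1:16)
  has_mbi <- all(mbi_cols %in% names(tab))
  if (!schema$burnout_label_name %in% names(tab) && !has_mbi)
    stop("survey file has neither a '", schema$burnout_label_name,
         "' column nor the 16 MBI item columns")
  for (v in intersect(names(schema$variables), names(tab))) {
    spec <- schema$variables[[v]]
    if (any(is.na(tab[[v]])))
      stop("missing values in column '", v, "' (row ",
           which(is.na(tab[[v]]))[1], ")")
    if (spec$kind != "numeric") {
      bad <- !(tab[[v]] %in% spec$levels)
      if (any(bad))
        stop("invalid level '", tab[[v]][which(bad)[1]], "' in column '", v,
             "' (row ", which(bad)[1], ")")
    }
  }
  class(tab) <- c("survey_table", "data.frame")
  tab
}

mbi_subscale_items <- list(exhaustion = 1:5, cynicism = 6:10, efficacy = 11:16)

#' Score the MBI-GS
#'
#' Computes the three subscale means (emotional exhaustion, cynicism,
#' professional efficacy) from 16 item scores on the 0-6 scale and applies
#' the critical-boundary rule: a respondent is labelled high burnout iff two
#' or more subscale scores strictly exceed their boundaries. Professional
#' efficacy is compared after reversal (6 - mean) when `efficacy_reversed`
#' is on, so that a *low* efficacy contributes to burnout.
#'
#' @param items numeric vector of 16 item scores in \{0..6\} (items 1-5
#'   exhaustion, 6-10 cynicism, 11-16 efficacy).
#' @param boundaries critical boundaries `c(exhaustion, cynicism, efficacy)`.
#' @param efficacy_reversed compare `6 - efficacy_mean` against the third
#'   boundary (default) rather than the raw mean.
#' @return object of class `mbi_profile` with the three subscale means, the
#'   boundaries, and the `label` (`"low"`/`"high"`).
#' @export
#' @examples
#' score_mbi(c(rep(6, 10), rep(0, 6)), boundaries = c(3, 3, 3))$label  # "high"
score_mbi <- function(items, boundaries = c(3, 3, 3), efficacy_reversed = TRUE) {
  if (length(items) != 16)
    stop("exactly 16 MBI item scores are required")
  if (any(is.na(items)) || any(items < 0 | items > 6))
    stop("MBI item scores must lie in {0..6}")
  if (length(boundaries) != 3)
    stop("boundaries must have length 3")
  means <- vapply(mbi_subscale_items, function(ix) mean(items[ix]), 0)
  eff_score <- if (efficacy_reversed) 6 - means[["efficacy"]] else means[["efficacy"]]
  exceed <- c(means[["exhaustion"]] > boundaries[1],
              means[["cynicism"]] > boundaries[2],
              eff_score > boundaries[3])
  structure(
    list(exhaustion_mean = means[["exhaustion"]],
         cynicism_mean = means[["cynicism"]],
         efficacy_mean = means[["efficacy"]],
         boundaries = boundaries,
         efficacy_reversed = efficacy_reversed,
         n_exceedances = sum(exceed),
         label = if (sum(exceed) >= 2) "high" else "low"),
    class = "mbi_profile"
  )
}

#' Score an MBI item table
#'
#' Row-wise [score_mbi()] over a table of 16 item columns.
#'
#' @param items data.frame or matrix with columns `mbi_01` .. `mbi_16`.
#' @inheritParams score_mbi
#' @return data.frame with subscale means and the burnout label per row.
#' @export
score_mbi_table <- function(items, boundaries = c(3, 3, 3),
                            efficacy_reversed = TRUE) {
  cols <- sprintf("mbi_%02d", 1:16)
  if (!all(cols %in% colnames(items)))
    stop("item table must contain columns mbi_01 .. mbi_16")
  m <- as.matrix(items[, cols])
  if (nrow(m) && (any(is.na(m)) || any(m < 0 | m > 6)))
    stop("MBI item scores must lie in {0..6}")
  exh <- rowMeans(m[, mbi_subscale_items$exhaustion, drop = FALSE])
  cyn <- rowMeans(m[, mbi_subscale_items$cynicism, drop = FALSE])
  eff <- rowMeans(m[, mbi_subscale_items$efficacy, drop = FALSE])
  eff_score <- if (efficacy_reversed) 6 - eff else eff
  n_exc <- (exh > boundaries[1]) + (cyn > boundaries[2]) +
    (eff_score > boundaries[3])
  data.frame(exhaustion_mean = exh, cynicism_mean = cyn, efficacy_mean = eff,
             label = ifelse(n_exc >= 2, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Encode respondents as [0,1] feature vectors
#'
#' Builds the standardized feature matrix whose rows are the respondents'
#' attribute vectors: numeric variables are min-max scaled to [0,1] using
#' the observed range; ordinal variables map level index to equally spaced
#' values 0, 1/(L-1), ..., 1; nominal and binary variables become one-hot
#' indicator columns. Constant columns carry no similarity information and
#' are dropped with a warning.
#'
#' @param table a `survey_table`.
#' @param schema a [survey_schema()].
#' @param selected character vector of variable names to encode; defaults
#'   to every schema variable present in the table.
#' @return object of class `feature_matrix`: list with `values` (N x n
#'   matrix, entries in [0,1]), `row_ids`, `column_names`.
#' @export
#' @examples
#' tab <- generate_survey(default_schema(), simulation_config(50, seed = 1))
#' F <- encode_features(tab, default_schema())
#' range(F$values)
encode_features <- function(table, schema, selected = NULL) {
  if (is.null(selected))
    selected <- intersect(names(schema$variables), names(table))
  if (!length(selected))
    stop("no variables selected for encoding")
  missing_vars <- setdiff(selected, names(schema$variables))
  if (length(missing_vars))
    stop("selected variables not in schema: ", paste(missing_vars, collapse = ", "))
  missing_cols <- setdiff(selected, names(table))
  if (length(missing_cols))
    stop("selected variables not in table: ", paste(missing_cols, collapse = ", "))
  n <- nrow(table)
  blocks <- list()
  for (v in selected) {
    spec <- schema$variables[[v]]
    x <- table[[v]]
    if (spec$kind == "numeric") {
      x <- as.numeric(x)
      rng <- range(x)
      if (diff(rng) == 0) {
        warning("dropping constant column '", v, "'")
        next
      }
      blocks[[v]] <- matrix((x - rng[1]) / diff(rng), ncol = 1,
                            dimnames = list(NULL, v))
    } else if (spec$kind == "ordinal") {
      idx <- match(x, spec$levels)
      col <- (idx - 1) / (length(spec$levels) - 1)
      if (length(unique(col)) < 2) {
        warning("dropping constant column '", v, "'")
        next
      }
      blocks[[v]] <- matrix(col, ncol = 1, dimnames = list(NULL, v))
    } else {
      m <- vapply(spec$levels, function(l) as.numeric(x == l), numeric(n))
      if (n == 1) m <- matrix(m, nrow = 1)
      colnames(m) <- paste0(v, "=", spec$levels)
      keep <- apply(m, 2, function(col) length(unique(col)) > 1)
      if (!any(keep)) {
        warning("dropping constant column '", v, "'")
        next
      }
      if (!all(keep))
        warning("dropping constant one-hot levels of '", v, "': ",
                paste(colnames(m)[!keep], collapse = ", "))
      blocks[[v]] <- m[, keep, drop = FALSE]
    }
  }
  if (!length(blocks))
    stop("all selected columns are constant: empty feature space")
  values <- do.call(cbind, blocks)
  structure(
    list(values = values,
         row_ids = if ("respondent_id" %in% names(table))
           table$respondent_id else as.character(seq_len(n)),
         column_names = colnames(values)),
    class = "feature_matrix"
  )
}

#' Write a feature matrix as TSV
#'
#' @param features a `feature_matrix`.
#' @param path output path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(respondent_id = features$row_ids,
                   features$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
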