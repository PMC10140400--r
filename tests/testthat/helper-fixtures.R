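# Shared fixtures, all generated in code.

# schema of null variables with non-extreme level probabilities, suitable
# for calibration checks of the association screen
make_null_schema <- function(n_vars = 40) {
  kinds <- rep(c("binary", "ordinal", "nominal", "numeric"), length.out = n_vars)
  cats <- rep(c("demographic", "work_related", "health", "lifestyle"),
              length.out = n_vars)
  vars <- lapply(seq_len(n_vars), function(i) {
    kind <- kinds[i]
    name <- sprintf("v%02d", i)
    if (kind == "numeric")
      variable_spec(name, cats[i], "numeric", range = c(0, 10))
    else {
      L <- switch(kind, binary = 2, ordinal = 3 + i %% 2, nominal = 3 + i %% 3)
      probs <- 0.5 + seq_len(L)  # mild imbalance, all levels common
      variable_spec(name, cats[i], kind,
                    levels = paste0("l", seq_len(L)), probs = probs / sum(probs))
    }
  })
  survey_schema(vars)
}

# small schema covering all four kinds and categories
make_tiny_schema <- function() {
  survey_schema(list(
    variable_spec("age", "demographic", "numeric", range = c(20, 60)),
    variable_spec("grade", "work_related", "ordinal",
                  levels = c("junior", "mid", "senior"),
                  probs = c(0.5, 0.3, 0.2)),
    variable_spec("disease", "health", "binary", levels = c("Yes", "No"),
                  probs = c(0.2, 0.8)),
    variable_spec("diet", "lifestyle", "nominal",
                  levels = c("a", "b", "c", "d"))
  ))
}

make_feature_matrix <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("R%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  structure(list(values = values, row_ids = ids,
                 column_names = colnames(values)),
            class = "feature_matrix")
}

# network built directly from an edge list (i < j index pairs)
make_network <- function(status, edges = matrix(integer(), 0, 2), ids = NULL) {
  n <- length(status)
  if (is.null(ids)) ids <- sprintf("N%03d", seq_len(n))
  burnoutnet:::new_network(ids, status, edges, n)
}

# Pearson chi-squared statistic, written independently of the package
chisq_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
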