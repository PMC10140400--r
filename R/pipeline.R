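# End-to-end orchestration: simulate (or read) -> score -> screen ->
# infer network -> fit ERGMs -> report. One root seed is split into
# per-stage seeds so stages are independently reproducible.

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a plain list. Required: a `seed` and
#' either `simulate` settings (`n`, optional `prevalence`, `effects`) or an
#' `input` CSV path. Exactly one of `threshold` / `target_avg_degree` may
#' be set; when neither is, the threshold defaults to 0.7799 (the value
#' used in the motivating cohort study). Other defaults:
#' `screen_alpha = 0.05`, `feature_mode = "significant"`,
#' `ergm_method = "exact"`.
#'
#' @param config file path or list.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  if (is.null(config$seed))
    stop("config field 'seed' is required")
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config field 'seed' must be a single integer")
  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("config must set exactly one of 'simulate' and 'input'")
  if (has_sim && is.null(config$simulate$n))
    stop("config field 'simulate$n' is required")
  if (!is.null(config$threshold) && !is.null(config$target_avg_degree))
    stop("config fields 'threshold' and 'target_avg_degree' are mutually exclusive")
  if (is.null(config$threshold) && is.null(config$target_avg_degree))
    config$threshold <- 0.7799
  if (is.null(config$screen_alpha)) config$screen_alpha <- 0.05
  if (config$screen_alpha <= 0 || config$screen_alpha > 1)
    stop("config field 'screen_alpha' must lie in (0, 1]")
  config$feature_mode <- match.arg(config$feature_mode %||% "significant",
                                   c("significant", "all"))
  config$ergm_method <- match.arg(config$ergm_method %||% "exact",
                                  c("exact", "mcmc"))
  if (is.null(config$outdir)) config$outdir <- "burnoutnet_run"
  config$seed <- as.integer(config$seed)
  class(config) <- c("pipeline_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full burnout-network analysis pipeline
#'
#' Executes, in order: cohort simulation (or CSV input, with MBI scoring if
#' only item responses are present), the descriptive report, the
#' association screen, Survey2Vector feature encoding and cosine-similarity
#' network inference, and the zero vs node-attribute ERGM comparison. All
#' artifacts are written under `config$outdir` and stamped with the config
#' hash and seed; reruns with the same config reproduce them.
#'
#' Artifacts: `table1.tsv`, `screen.json`, `edges.tsv`, `nodes.tsv`,
#' `ergm_zero.json`, `ergm_attr.json`, `ergm_attr.txt`, `comparison.json`,
#' `provenance.json`, `run.log`.
#'
#' @param config a [validate_config()]-acceptable configuration.
#' @param schema a [survey_schema()]; defaults to the airport-cohort schema.
#' @return (invisibly) list with the survey table, screen, network, fits,
#'   comparison and the artifact paths.
#' @export
run_pipeline <- function(config, schema = default_schema()) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  t0 <- proc.time()[["elapsed"]]
  logmsg <- function(stage, ...) {
    line <- sprintf("[%7.2fs] %-12s %s", proc.time()[["elapsed"]] - t0,
                    stage, paste0(...))
    writeLines(line, log_con); message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  ## stage 1: survey
  survey <- run_stage("survey", {
    if (!is.null(config$simulate)) {
      cfg <- simulation_config(
        n_respondents = config$simulate$n,
        burnout_prevalence = config$simulate$prevalence %||% (728 / 5794),
        effect_sizes = config$simulate$effects %||% list(),
        seed = stage_seeds[1]
      )
      generate_survey(schema, cfg)
    } else {
      read_survey(config$input, schema)
    }
  })
  bcol <- schema$burnout_label_name
  if (!bcol %in% names(survey)) {
    survey[[bcol]] <- run_stage("scoring",
      score_mbi_table(survey,
                      boundaries = config$mbi_boundaries %||% c(3, 3, 3))$label)
    logmsg("scoring", "burnout labels scored from MBI items")
  }
  logmsg("survey", sprintf("N = %d respondents, %d high burnout",
                           nrow(survey), sum(survey[[bcol]] == "high")))

  ## stage 2: descriptive report + screen
  report <- run_stage("report", table1_report(survey, schema))
  write_report(report, file.path(config$outdir, "table1.tsv"), "tsv")
  screen <- run_stage("screen",
                      screen_variables(survey, schema, config$screen_alpha))
  jsonlite::write_json(
    list(alpha = screen$alpha, results = screen$results,
         selected = screen$selected),
    file.path(config$outdir, "screen.json"), auto_unbox = TRUE, digits = NA)
  logmsg("screen", sprintf("%d/%d variables significant at alpha = %g",
                           sum(screen$results$significant),
                           nrow(screen$results), config$screen_alpha))

  ## stage 3: network inference
  net <- run_stage("network", {
    selected <- if (config$feature_mode == "significant")
      unlist(screen$selected, use.names = FALSE) else NULL
    if (config$feature_mode == "significant" && !length(selected)) {
      logmsg("network", "no significant variables; falling back to all")
      selected <- NULL
    }
    feats <- encode_features(survey, schema, selected)
    sim <- cosine_similarity_matrix(feats)
    t_use <- if (!is.null(config$threshold)) config$threshold
      else calibrate_threshold(sim, config$target_avg_degree)
    threshold_network(sim, t_use, status = survey[[bcol]])
  })
  write_network(net, file.path(config$outdir, "edges.tsv"),
                file.path(config$outdir, "nodes.tsv"))
  s <- network_summary(net)
  logmsg("network", sprintf("t = %.4f: %d edges, avg degree %.2f, density %.4g",
                            net$threshold_used, s$n_edges, s$avg_degree,
                            s$density))

  ## stage 4: ERGM fits + comparison
  fits <- run_stage("ergm", {
    spec0 <- ergm_spec("edges")
    spec1 <- ergm_spec(c("edges", "nodefactor", "nodematch"),
                       attribute = bcol)
    if (config$ergm_method == "exact") {
      list(zero = fit_exact(net, spec0), attr = fit_exact(net, spec1))
    } else {
      ctl <- mh_control(seed = stage_seeds[2])
      list(zero = fit_mcmcmle(net, spec0, ctl),
           attr = fit_mcmcmle(net, spec1, ctl))
    }
  })
  write_ergm_fit(fits$zero, file.path(config$outdir, "ergm_zero.json"))
  write_ergm_fit(fits$attr, file.path(config$outdir, "ergm_attr.json"),
                 file.path(config$outdir, "ergm_attr.txt"))
  comparison <- run_stage("compare", compare_models(fits$zero, fits$attr))
  jsonlite::write_json(
    list(criteria = comparison$criteria, selected = comparison$selected,
         selected_aic = comparison$selected_aic,
         selected_bic = comparison$selected_bic,
         tie = comparison$tie, disagreement = comparison$disagreement),
    file.path(config$outdir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  logmsg("ergm", sprintf("method %s; selected model: %s",
                         config$ergm_method,
                         if (is.na(comparison$selected)) "(criteria disagree)"
                         else comparison$selected))

  ## provenance
  provenance <- list(
    package = "burnoutnet",
    version = as.character(utils::packageVersion("burnoutnet")),
    config = unclass(config), config_hash = config_hash(config),
    seed = config$seed, stage_seeds = stage_seeds,
    n_respondents = nrow(survey), n_edges = s$n_edges
  )
  jsonlite::write_json(provenance,
                       file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("done", "all artifacts written to ", config$outdir)
  invisible(list(survey = survey, report = report, screen = screen,
                 network = net, fits = fits, comparison = comparison,
                 provenance = provenance,
                 artifacts = file.path(config$outdir,
                   c("table1.tsv", "screen.json", "edges.tsv", "nodes.tsv",
                     "ergm_zero.json", "ergm_attr.json", "ergm_attr.txt",
                     "comparison.json", "provenance.json", "run.log"))))
}
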