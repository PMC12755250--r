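#' Pipeline configuration
#'
#' Bundles and validates everything [run_pipeline()] needs.  A config can
#' also be loaded from a YAML or JSON file with [read_pipeline_config()].
#'
#' @param input path to the input CSV/TSV (header row of variable names).
#' @param output_dir directory for all artifacts (created if missing).
#' @param outcome name of the outcome variable (required).
#' @param genetic name of the polygenic-score variable, or `NULL`.
#' @param cluster_threshold absolute-correlation clustering cutoff in
#'   (0, 1), or `NULL` to skip the clustering/aggregation stage.
#' @param forbidden_edges extra forbidden edges (`"from->to"` strings) on
#'   top of the role-derived defaults.
#' @param epsilon,max_iterations search settings, see [search_config()].
#' @param bootstrap_B bootstrap resamples; 0 disables the bootstrap.
#' @param reporting_threshold bootstrap frequency cutoff for reporting.
#' @param seed master seed for the bootstrap.
#' @return class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir, outcome, genetic = NULL,
                            cluster_threshold = NULL,
                            forbidden_edges = NULL,
                            epsilon = 1e-9, max_iterations = NULL,
                            bootstrap_B = 100L,
                            reporting_threshold = 0.40, seed = 1L) {
  if (!is.character(input) || length(input) != 1L)
    stop("`input` must be a single file path")
  if (!is.character(outcome) || length(outcome) != 1L)
    stop("`outcome` must be a single variable name")
  if (!is.null(cluster_threshold) &&
      (cluster_threshold <= 0 || cluster_threshold >= 1))
    stop("`cluster_threshold` must lie in (0, 1)")
  structure(list(
    input = input, output_dir = output_dir, outcome = outcome,
    genetic = genetic, cluster_threshold = cluster_threshold,
    forbidden_edges = forbidden_edges, epsilon = epsilon,
    max_iterations = max_iterations, bootstrap_B = as.integer(bootstrap_B),
    reporting_threshold = reporting_threshold, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline config from YAML or JSON
#' @param path config file; `.yaml`/`.yml` parsed with the yaml package,
#'   anything else as JSON.
#' @param ... overrides applied on top of the file's values.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full discovery pipeline
#'
#' Standardize, optionally cluster and aggregate correlated variables,
#' learn the DAG by constrained hill climbing, quantify it as a path
#' model, trace all pathways into the outcome, decompose total effects,
#' and (optionally) bootstrap the whole procedure for edge stability.
#' All artifacts are written under `config$output_dir`:
#' `factors.tsv`/`loadings.tsv` (when clustering), `edges.tsv`,
#' `dag.dot`, `dag.graphml`, `trace.jsonl`, `effects.tsv`, `paths.tsv`,
#' `equations.txt`, `bootstrap.tsv`, and `manifest.json` recording the
#' package version, seed, config and any warnings.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`data`,
#'   `clusters`, `dag`, `model`, `effects`, `bootstrap`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  warnings <- character(0)

  raw <- read_variable_table(config$input, outcome = config$outcome,
                             genetic = config$genetic)
  data <- standardize(raw)

  clusters <- NULL
  parental <- setdiff(colnames(data), c(config$outcome, config$genetic))
  if (!is.null(config$cluster_threshold)) {
    # cluster only the behavior variables; outcome and genetic pass through
    behav <- data[, parental, drop = FALSE]
    behav <- variable_table(behav)
    clusters <- cluster_variables(correlation_matrix(behav),
                                  config$cluster_threshold)
    agg <- pca_aggregate(behav, clusters)
    keep <- unclass_table(data)[, c(config$outcome, config$genetic),
                                drop = FALSE]
    merged <- cbind(unclass_table(agg$factors), keep)
    roles <- stats::setNames(rep("predictor", ncol(merged)),
                             colnames(merged))
    roles[config$outcome] <- "outcome"
    if (!is.null(config$genetic)) roles[config$genetic] <- "genetic"
    data <- standardize(variable_table(merged, roles = roles))
    parental <- colnames(agg$factors)
    write_variable_table(agg$factors, out("factors.tsv"))
    write_loadings(agg, out("loadings.tsv"))
  }

  constraints <- default_constraints(
    colnames(data), outcome = config$outcome, genetic = config$genetic,
    parental_factors = parental)
  if (!is.null(config$forbidden_edges))
    constraints <- edge_constraints(
      rbind(constraints$forbidden, as_edge_matrix(config$forbidden_edges)),
      nodes = colnames(data))

  cfg <- search_config(epsilon = config$epsilon,
                       max_iterations = config$max_iterations)
  fit <- withCallingHandlers(
    hill_climb(data, constraints = constraints, config = cfg),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_dag(fit$dag, out("edges.tsv"))
  write_dag(fit$dag, out("dag.dot"), format = "dot")
  write_dag(fit$dag, out("dag.graphml"), format = "graphml")
  writeLines(vapply(seq_len(nrow(fit$trace)), function(i)
    jsonlite::toJSON(as.list(fit$trace[i, ]), auto_unbox = TRUE, digits = NA),
    character(1)), out("trace.jsonl"))

  model <- fit_path_model(fit$dag, data)
  effects <- total_effects(model, config$outcome)
  write_effects(effects, out("effects.tsv"), paths_path = out("paths.tsv"))
  write_equations(fit$dag, out("equations.txt"))

  boot <- NULL
  if (config$bootstrap_B > 0L) {
    boot <- bootstrap_dags(data, constraints = constraints, config = cfg,
                           B = config$bootstrap_B, seed = config$seed)
    reported <- filter_reported_edges(boot, config$reporting_threshold)
    write_bootstrap(reported, out("bootstrap.tsv"), model = model)
  }

  manifest <- list(
    package = "dagclimb",
    version = as.character(utils::packageVersion("dagclimb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    n_samples = nrow(data),
    variables = colnames(data),
    score = fit$score,
    n_edges = nrow(fit$dag$edges),
    converged = fit$converged,
    warnings = warnings
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(data = data, clusters = clusters, dag = fit$dag,
                 search = fit, model = model, effects = effects,
                 bootstrap = boot, manifest = manifest))
}
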