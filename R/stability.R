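#' Bootstrap edge-stability analysis
#'
#' Draws `B` resamples of the n rows with replacement, re-runs the whole
#' learn-and-fit procedure (re-standardize, [hill_climb()],
#' [fit_path_model()]) on each, and tallies, for every directed edge ever
#' learned, its appearance frequency and a 95% percentile interval (2.5th
#' and 97.5th percentiles) of its coefficient across the resamples in
#' which it appeared.  Conditioning the interval on presence is a
#' deliberate convention: an absent edge has no coefficient (see the
#' methods vignette for the selective-inference caveat).  Edge identity is
#' direction-sensitive: `X->Y` and `Y->X` are tallied separately.
#'
#' Per-resample seeds are drawn up-front from the master seed, so results
#' are reproducible and independent of execution order.  A resample on
#' which learning or fitting fails (e.g. a constant column after
#' resampling) is counted in `failures` and excluded from all tallies.
#'
#' @param data a standardized [variable_table()].
#' @param constraints an [edge_constraints()] or `NULL`.
#' @param config a [search_config()].
#' @param B number of bootstrap resamples (>= 2); default 100.
#' @param seed master integer seed.
#' @return class `bootstrap_summary`: list with `edges` (data frame:
#'   parent, child, frequency, ci_low, ci_high, n_present), `B`,
#'   `failures`, `seed`, and `reporting_threshold` (`NA` until
#'   [filter_reported_edges()] is applied).  Frequency is
#'   `n_present / B`; failed resamples contribute no appearances.
#' @export
bootstrap_dags <- function(data, constraints = NULL,
                           config = search_config(), B = 100L,
                           seed = 1L) {
  stopifnot(inherits(data, "variable_table"))
  if (B < 2L) stop("B must be at least 2")
  n <- nrow(data)
  roles <- variable_roles(data)
  set.seed(seed)
  resample_seeds <- sample.int(.Machine$integer.max - 1L, B)
  coefs <- new.env(parent = emptyenv())  # edge string -> coefficient vector
  failures <- 0L
  ok <- 0L
  for (b in seq_len(B)) {
    set.seed(resample_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      d <- standardize(variable_table(unclass_table(data)[idx, , drop = FALSE],
                                      roles = roles))
      fit <- hill_climb(d, constraints = constraints, config = config)
      model <- fit_path_model(fit$dag, d)
      list(dag = fit$dag, B = model$B)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    ok <- ok + 1L
    em <- res$dag$edges
    for (i in seq_len(nrow(em))) {
      key <- paste0(em[i, 1L], "->", em[i, 2L])
      prev <- get0(key, envir = coefs, inherits = FALSE)
      assign(key, c(prev, res$B[em[i, 2L], em[i, 1L]]), envir = coefs)
    }
  }
  if (ok == 0L) stop("all ", B, " bootstrap resamples failed")
  keys <- sort(ls(coefs))
  edges <- do.call(rbind, lapply(keys, function(k) {
    v <- coefs[[k]]
    ends <- strsplit(k, "->", fixed = TRUE)[[1L]]
    ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(parent = ends[1L], child = ends[2L],
               frequency = length(v) / B,
               ci_low = ci[1L], ci_high = ci[2L], n_present = length(v))
  }))
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0),
                        frequency = numeric(0), ci_low = numeric(0),
                        ci_high = numeric(0), n_present = integer(0))
  structure(list(edges = edges, B = B, n_ok = ok, failures = failures,
                 seed = seed, reporting_threshold = NA_real_),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("bootstrap_summary: B =", x$B,
      if (x$failures) paste0("(", x$failures, " failed)"), "\n")
  if (!is.na(x$reporting_threshold))
    cat("  reporting threshold:", x$reporting_threshold, "\n")
  df <- x$edges
  df$frequency <- round(df$frequency, 3)
  df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3)
  print(df)
  invisible(x)
}

#' Filter a bootstrap summary by appearance frequency
#'
#' Retains edges whose frequency is at or above the threshold (boundary
#' inclusive); the default 0.40 is the reporting rule of the framework.
#'
#' @param summary a [bootstrap_dags()] result.
#' @param threshold frequency cutoff in \[0, 1\].
#' @return the filtered `bootstrap_summary`, with `reporting_threshold`
#'   recorded.
#' @export
filter_reported_edges <- function(summary, threshold = 0.40) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must lie in [0, 1]")
  summary$edges <- summary$edges[summary$edges$frequency >= threshold, ,
                                 drop = FALSE]
  rownames(summary$edges) <- NULL
  summary$reporting_threshold <- threshold
  summary
}

#' Consistency of full-data coefficients with bootstrap intervals
#'
#' An effect is consistent when the coefficient estimated on the full
#' data falls inside (closed interval, endpoints included) the bootstrap
#' percentile interval of its edge.  Edges of the model that never
#' appeared in the bootstrap summary are not assessable and map to `NA`.
#'
#' @param summary a (typically filtered) [bootstrap_dags()] result.
#' @param model a [fit_path_model()] fitted on the full data.
#' @return named logical vector over the model's edges (`"from->to"`
#'   names): `TRUE`/`FALSE` for assessable edges, `NA` otherwise.
#' @export
consistency_check <- function(summary, model) {
  stopifnot(inherits(summary, "bootstrap_summary"),
            inherits(model, "path_model"))
  em <- model$dag$edges
  keys <- paste0(em[, 1L], "->", em[, 2L])
  skeys <- paste0(summary$edges$parent, "->", summary$edges$child)
  out <- stats::setNames(rep(NA, length(keys)), keys)
  for (i in seq_along(keys)) {
    j <- match(keys[i], skeys)
    if (is.na(j)) next
    beta <- model$B[em[i, 2L], em[i, 1L]]
    out[i] <- beta >= summary$edges$ci_low[j] &&
              beta <= summary$edges$ci_high[j]
  }
  out
}

#' Write a bootstrap edge table as TSV
#' @param summary a [bootstrap_dags()] result.
#' @param path destination file.
#' @param model optional full-data [fit_path_model()]; when given, a
#'   `consistent` column is added via [consistency_check()].
#' @return `path`, invisibly.
#' @export
write_bootstrap <- function(summary, path, model = NULL) {
  df <- summary$edges
  if (!is.null(model)) {
    cons <- consistency_check(summary, model)
    keys <- paste0(df$parent, "->", df$child)
    df$consistent <- unname(cons[keys])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare the edge sets of two learned DAGs
#'
#' Direction-sensitive comparison used for sensitivity analyses (e.g. a
#' model learned on a subgroup against the full-sample model): shared and
#' unique directed edges, the Jaccard overlap
#' `|shared| / |union|`, and the fraction of each model's edges that are
#' shared.  Two empty graphs compare as fully overlapping.
#'
#' @param a,b [dag_structure()] objects (or edge sets accepted by
#'   [dag_structure()]'s `edges` argument).
#' @return class `edge_set_comparison`: list with `shared`, `only_a`,
#'   `only_b` (character vectors of `"from->to"` strings), `jaccard`,
#'   `pct_a_shared`, `pct_b_shared` (all in \[0, 1\]).
#' @export
compare_edge_sets <- function(a, b) {
  ea <- if (inherits(a, "dag")) dag_edge_strings(a)
        else apply(as_edge_matrix(a), 1L, paste, collapse = "->")
  eb <- if (inherits(b, "dag")) dag_edge_strings(b)
        else apply(as_edge_matrix(b), 1L, paste, collapse = "->")
  ea <- unique(ea); eb <- unique(eb)
  shared <- sort(intersect(ea, eb))
  only_a <- sort(setdiff(ea, eb))
  only_b <- sort(setdiff(eb, ea))
  union_n <- length(shared) + length(only_a) + length(only_b)
  structure(list(
    shared = shared, only_a = only_a, only_b = only_b,
    jaccard = if (union_n == 0L) 1 else length(shared) / union_n,
    pct_a_shared = if (length(ea) == 0L) 1 else length(shared) / length(ea),
    pct_b_shared = if (length(eb) == 0L) 1 else length(shared) / length(eb)
  ), class = "edge_set_comparison")
}

#' @export
print.edge_set_comparison <- function(x, ...) {
  cat(sprintf(
    "edge_set_comparison: %d shared, %d only in A, %d only in B\n",
    length(x$shared), length(x$only_a), length(x$only_b)))
  cat(sprintf("  Jaccard overlap %.1f%%; %.1f%% of A shared, %.1f%% of B shared\n",
              100 * x$jaccard, 100 * x$pct_a_shared, 100 * x$pct_b_shared))
  invisible(x)
}

#' Write an edge-set comparison as TSV and JSON
#' @param comparison a [compare_edge_sets()] result.
#' @param tsv_path,json_path destinations (either may be `NULL`).
#' @return the comparison, invisibly.
#' @export
write_comparison <- function(comparison, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(comparison, "edge_set_comparison"))
  if (!is.null(tsv_path)) {
    df <- rbind(
      data.frame(set = "shared", edge = comparison$shared),
      data.frame(set = "only_a", edge = comparison$only_a),
      data.frame(set = "only_b", edge = comparison$only_b))
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(unclass(comparison), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(comparison)
}
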