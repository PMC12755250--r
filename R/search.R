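#' Blacklist of forbidden directed edges
#'
#' @param forbidden edge set in any form accepted by [dag_structure()]
#'   (2-column matrix/data frame, `"from->to"` strings, or `NULL`).
#' @param nodes optional node universe; if given, constraints referencing
#'   unknown nodes raise an error.
#' @return class `edge_constraints`: list with `forbidden`, a 2-column
#'   character matrix.
#' @export
edge_constraints <- function(forbidden = NULL, nodes = NULL) {
  em <- as_edge_matrix(forbidden)
  em <- unique(em)
  if (!is.null(nodes)) {
    unknown <- setdiff(c(em), nodes)
    if (length(unknown))
      stop("constraint references unknown node(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(forbidden = em), class = "edge_constraints")
}

#' @export
print.edge_constraints <- function(x, ...) {
  cat("edge_constraints:", nrow(x$forbidden), "forbidden edges\n")
  if (nrow(x$forbidden))
    cat(paste(" ", x$forbidden[, 1L], "-/->", x$forbidden[, 2L]), sep = "\n")
  invisible(x)
}

#' Default expert-knowledge constraints
#'
#' Encodes the two domain rules used throughout the framework: the outcome
#' is a sink (it may not influence any other variable), and the polygenic
#' score may not point into any aggregated parental behavior factor.
#' Deliberately nothing else is forbidden: in particular the genetic score
#' may affect the outcome, and parental factors may point into the genetic
#' score (such edges proxy the parents' own genotypes, not a causal action
#' on the child's DNA).
#'
#' @param nodes character vector of all node names.
#' @param outcome name of the outcome node, or `NULL`.
#' @param genetic name of the polygenic-score node, or `NULL`.
#' @param parental_factors names of the aggregated parental factors.
#' @return an [edge_constraints()] object.
#' @export
default_constraints <- function(nodes, outcome = NULL, genetic = NULL,
                                parental_factors = character(0)) {
  named <- c(outcome, genetic, parental_factors)
  unknown <- setdiff(named, nodes)
  if (length(unknown))
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  fb <- matrix(character(0), 0L, 2L)
  if (!is.null(outcome)) {
    others <- setdiff(nodes, outcome)
    fb <- rbind(fb, cbind(outcome, others))
  }
  if (!is.null(genetic) && length(parental_factors))
    fb <- rbind(fb, cbind(genetic, setdiff(parental_factors, genetic)))
  edge_constraints(fb, nodes = nodes)
}

is_forbidden <- function(constraints, from, to) {
  if (is.null(constraints) || !nrow(constraints$forbidden)) return(FALSE)
  any(constraints$forbidden[, 1L] == from & constraints$forbidden[, 2L] == to)
}

#' Search configuration
#'
#' @param epsilon minimal score improvement for a move to be accepted
#'   (default 1e-9, a guard against floating-point noise).
#' @param max_iterations iteration cap; `NULL` for the default `10 * p^2`
#'   chosen at search time.
#' @return class `search_config`.
#' @export
search_config <- function(epsilon = 1e-9, max_iterations = NULL) {
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("`epsilon` must be a positive number")
  if (!is.null(max_iterations) &&
      (!is.numeric(max_iterations) || max_iterations < 1))
    stop("`max_iterations` must be a positive integer or NULL")
  structure(list(epsilon = epsilon, max_iterations = max_iterations),
            class = "search_config")
}

#' Enumerate legal single-edge moves
#'
#' All additions of absent, non-forbidden, non-cycle-creating edges; all
#' removals of present edges; all reversals whose reversed direction is
#' not forbidden and whose application leaves the graph acyclic.  Moves
#' are returned in deterministic order — additions, then removals, then
#' reversals, each class sorted lexicographically by (from, to) — which
#' fixes the tie-break of the steepest-ascent search.
#'
#' @param dag a [dag_structure()].
#' @param constraints an [edge_constraints()] or `NULL`.
#' @return list of moves, each a list with `type` (`"add"`, `"remove"`,
#'   `"reverse"`), `from`, `to`.
#' @export
candidate_moves <- function(dag, constraints = NULL) {
  nodes <- dag$nodes
  present <- paste(dag$edges[, 1L], dag$edges[, 2L])
  moves <- list()
  # additions
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$from[i]; v <- pairs$to[i]
    if (paste(u, v) %in% present || paste(v, u) %in% present) next
    if (is_forbidden(constraints, u, v)) next
    if (dag_reachable(dag, v, u)) next  # would close a cycle
    moves[[length(moves) + 1L]] <- list(type = "add", from = u, to = v)
  }
  # removals
  if (nrow(dag$edges)) {
    ord <- order(dag$edges[, 1L], dag$edges[, 2L])
    for (i in ord)
      moves[[length(moves) + 1L]] <-
        list(type = "remove", from = dag$edges[i, 1L], to = dag$edges[i, 2L])
    # reversals
    for (i in ord) {
      u <- dag$edges[i, 1L]; v <- dag$edges[i, 2L]
      if (is_forbidden(constraints, v, u)) next
      g <- dag_remove_edge(dag, u, v)
      if (dag_reachable(g, u, v)) next  # reversed edge would close a cycle
      moves[[length(moves) + 1L]] <- list(type = "reverse", from = u, to = v)
    }
  }
  moves
}

# score delta of a move, touching only the affected local terms
move_delta <- function(dag, move, data, cache) {
  u <- move$from; v <- move$to
  pa_v <- dag_parents(dag, v)
  switch(move$type,
    add = local_score_cached(data, v, c(pa_v, u), cache) -
          local_score_cached(data, v, pa_v, cache),
    remove = local_score_cached(data, v, setdiff(pa_v, u), cache) -
             local_score_cached(data, v, pa_v, cache),
    reverse = {
      pa_u <- dag_parents(dag, u)
      (local_score_cached(data, v, setdiff(pa_v, u), cache) -
         local_score_cached(data, v, pa_v, cache)) +
      (local_score_cached(data, u, c(pa_u, v), cache) -
         local_score_cached(data, u, pa_u, cache))
    },
    stop("unknown move type: ", move$type))
}

apply_move <- function(dag, move) {
  switch(move$type,
    add = dag_add_edge(dag, move$from, move$to),
    remove = dag_remove_edge(dag, move$from, move$to),
    reverse = dag_reverse_edge(dag, move$from, move$to))
}

#' Hill-climb structure search
#'
#' Greedy steepest-ascent search over DAG space, starting from the empty
#' graph: at every iteration all legal single-edge additions, removals and
#' reversals are scored (via decomposable score deltas that touch only the
#' affected nodes), the best strictly improving move is applied, and the
#' search stops at a local optimum — no move improves the total score by
#' more than `epsilon` — or at the iteration cap.  Ties between equally
#' good moves are broken by the deterministic move ordering of
#' [candidate_moves()], so results are reproducible.
#'
#' @param data a standardized [variable_table()] with at least 2 variables
#'   and `n > p + 1` samples.
#' @param constraints an [edge_constraints()] blacklist, or `NULL`.
#' @param config a [search_config()].
#' @param cache optional [score_cache()] for `data`; one is created if
#'   missing.
#' @return class `hill_climb_result`: list with `dag` (the learned
#'   [dag_structure()]), `score` (its total BIC), `trace` (data frame with
#'   one row per accepted move: iteration, move, from, to, delta, score)
#'   and `converged` (`FALSE` if the iteration cap was hit, with a
#'   warning).
#' @export
hill_climb <- function(data, constraints = NULL, config = search_config(),
                       cache = NULL) {
  stopifnot(inherits(data, "variable_table"))
  nodes <- colnames(data)
  p <- length(nodes)
  if (p < 2L) stop("need at least 2 variables")
  if (nrow(data) <= p + 1L)
    stop("need n > p + 1 samples (n = ", nrow(data), ", p = ", p, ")")
  if (!is.null(constraints)) {
    unknown <- setdiff(c(constraints$forbidden), nodes)
    if (length(unknown))
      stop("constraint references unknown node(s): ",
           paste(unknown, collapse = ", "))
  }
  if (is.null(cache)) cache <- score_cache()
  max_iter <- config$max_iterations
  if (is.null(max_iter)) max_iter <- 10L * p^2
  dag <- dag_structure(nodes)
  score <- total_bic_score(dag, data, cache)
  trace <- data.frame(iteration = integer(0), move = character(0),
                      from = character(0), to = character(0),
                      delta = numeric(0), score = numeric(0))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    moves <- candidate_moves(dag, constraints)
    best <- NULL
    best_delta <- config$epsilon
    for (m in moves) {
      d <- move_delta(dag, m, data, cache)
      # a later move must beat the incumbent by more than epsilon:
      # score-equivalent alternatives (equal up to float noise) resolve
      # to the first move in the deterministic ordering
      if (d > best_delta + (if (is.null(best)) 0 else config$epsilon)) {
        best <- m
        best_delta <- d
      }
    }
    if (is.null(best)) {
      converged <- TRUE
      break
    }
    dag <- apply_move(dag, best)
    score <- score + best_delta
    trace <- rbind(trace, data.frame(
      iteration = it, move = best$type, from = best$from, to = best$to,
      delta = best_delta, score = score))
  }
  if (!converged)
    warning("hill_climb stopped at max_iterations = ", max_iter,
            " before reaching a local optimum")
  structure(list(dag = dag, score = score, trace = trace,
                 converged = converged),
            class = "hill_climb_result")
}

#' @export
print.hill_climb_result <- function(x, ...) {
  cat("hill_climb_result: score ", format(x$score), ", ",
      nrow(x$trace), " accepted moves",
      if (!x$converged) " (iteration cap hit)", "\n", sep = "")
  print(x$dag)
  invisible(x)
}
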