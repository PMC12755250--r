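#' Ordinary least squares fit of a node on its DAG parents
#'
#' Fits `node ~ intercept + parents` by QR-decomposition least squares
#' (never the normal equations: aggregated factors can be nearly
#' collinear).  This is the regression underlying the local BIC score of a
#' linear-Gaussian network: each node is modelled as a linear function of
#' its parents plus Gaussian noise.
#'
#' @param data a [variable_table()] (normally standardized).
#' @param node name of the child variable.
#' @param parents character vector of parent names; may be empty.
#' @return class `local_fit`: list with `node`, `parents`, `intercept`,
#'   `coefficients` (named by parent), `rss`, `n`, `k` (number of
#'   parents).
#' @export
fit_local_regression <- function(data, node, parents = character(0)) {
  stopifnot(inherits(data, "variable_table"))
  nm <- colnames(data)
  if (!node %in% nm) stop("unknown node: ", node)
  if (!all(parents %in% nm))
    stop("unknown parent(s): ", paste(setdiff(parents, nm), collapse = ", "))
  if (node %in% parents) stop("node cannot be its own parent")
  x <- unclass_table(data)
  n <- nrow(x)
  k <- length(parents)
  if (n <= k + 1L)
    stop("need n > k + 1 samples (n = ", n, ", k = ", k, ")")
  X <- cbind(`(Intercept)` = 1, x[, parents, drop = FALSE])
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design for node ", node, "; collinear parent(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrx, x[, node])
  res <- qr.resid(qrx, x[, node])
  structure(list(
    node = node,
    parents = parents,
    intercept = unname(coefs[1L]),
    coefficients = coefs[-1L],
    rss = sum(res^2),
    n = n,
    k = k
  ), class = "local_fit")
}

#' Local linear-Gaussian BIC score of a fitted node
#'
#' For a node with `k` parents fitted on `n` samples with residual sum of
#' squares `RSS`, the local score is
#' \deqn{-\frac{n}{2}\left[\ln(2\pi) + 1 + \ln\frac{RSS}{n}\right] -
#'       \frac{k+2}{2}\ln n,}
#' i.e. the maximized Gaussian log-likelihood minus a BIC penalty counting
#' `k` slopes, the intercept and the residual variance.  Natural
#' logarithms; larger (less negative) is better, and the search maximizes
#' this quantity.
#'
#' A perfectly collinear fit (`RSS/n` below `floor`) has no finite
#' log-likelihood; it raises an error unless `clamp = TRUE`, which clamps
#' the variance at `floor` for exploratory runs.
#'
#' @param fit a [fit_local_regression()] result.
#' @param floor variance floor for degeneracy detection (default 1e-12).
#' @param clamp clamp degenerate variances instead of erroring.
#' @return the local score, a single number.
#' @export
local_bic_score <- function(fit, floor = 1e-12, clamp = FALSE) {
  stopifnot(inherits(fit, "local_fit"))
  n <- fit$n
  v <- fit$rss / n
  if (v < floor) {
    if (!clamp)
      stop("degenerate fit for node ", fit$node,
           ": residual variance ", signif(v, 3), " below floor ", floor,
           " (perfect collinearity?)")
    v <- floor
  }
  -(n / 2) * (log(2 * pi) + 1 + log(v)) - ((fit$k + 2) / 2) * log(n)
}

#' Create an empty local-score cache
#'
#' The score is decomposable: the score of a DAG is the sum over nodes of
#' a local term depending only on (node, parent set).  Hill climbing
#' re-evaluates the same local terms many times, so they are memoized in
#' an environment keyed by the node and its sorted parent set.  A cache is
#' only valid for the dataset it was built against.
#'
#' @return class `score_cache`: an environment with `entries`, `hits`,
#'   `misses`.
#' @export
score_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  class(e) <- "score_cache"
  e
}

#' @export
print.score_cache <- function(x, ...) {
  cat("score_cache:", length(ls(x$entries)), "entries,",
      x$hits, "hits,", x$misses, "misses\n")
  invisible(x)
}

# canonical, parent-order-insensitive cache key
cache_key <- function(node, parents) {
  paste0(node, "|", paste(sort(parents), collapse = ","))
}

# memoized local score; the workhorse of search and total scoring
local_score_cached <- function(data, node, parents, cache = NULL) {
  if (is.null(cache))
    return(local_bic_score(fit_local_regression(data, node, parents)))
  key <- cache_key(node, parents)
  val <- get0(key, envir = cache$entries, inherits = FALSE)
  if (!is.null(val)) {
    cache$hits <- cache$hits + 1L
    return(val)
  }
  cache$misses <- cache$misses + 1L
  val <- local_bic_score(fit_local_regression(data, node, parents))
  assign(key, val, envir = cache$entries)
  val
}

#' Total BIC score of a DAG
#'
#' The sum of local scores over all nodes, each node fitted on its parents
#' in the graph.  With a [score_cache()] the local terms are memoized;
#' cached and cache-free results are bit-identical.
#'
#' @param dag a [dag_structure()] whose nodes are variables of `data`.
#' @param data a [variable_table()].
#' @param cache optional [score_cache()] built against `data`.
#' @return the total score, a single number.
#' @export
total_bic_score <- function(dag, data, cache = NULL) {
  stopifnot(inherits(dag, "dag"))
  if (!all(dag$nodes %in% colnames(data)))
    stop("DAG nodes missing from data: ",
         paste(setdiff(dag$nodes, colnames(data)), collapse = ", "))
  sum(vapply(dag$nodes, function(v)
    local_score_cached(data, v, dag_parents(dag, v), cache), numeric(1)))
}
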