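#' Cluster variables by absolute correlation
#'
#' Agglomerative hierarchical clustering (average linkage) on the distance
#' `1 - |r|`, with the tree cut so that two groups are merged only while
#' their linkage distance stays at or below `1 - threshold`.  A variable
#' whose absolute correlation with every other variable is below the
#' threshold therefore remains a singleton.  Used to collapse blocks of
#' strongly overlapping questionnaire scales before structure learning.
#'
#' @param corr a [correlation_matrix()].
#' @param threshold absolute-correlation cutoff in (0, 1); default 0.7.
#' @return an object of class `cluster_assignment`: a list with `clusters`
#'   (named list of character vectors partitioning the variables) and
#'   `threshold`.  Multi-variable clusters are labelled `F1`, `F2`, ... in
#'   order of their first member; singletons keep the variable name.
#' @export
cluster_variables <- function(corr, threshold = 0.7) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single number in (0, 1)")
  nm <- colnames(corr)
  if (length(nm) == 1L) {
    membership <- stats::setNames(1L, nm)
  } else {
    d <- stats::as.dist(1 - abs(unclass(corr)))
    tree <- stats::hclust(d, method = "average")
    membership <- stats::cutree(tree, h = 1 - threshold)
  }
  groups <- split(nm, membership)
  # deterministic labels: order clusters by first member's column position
  first_pos <- vapply(groups, function(g) match(g[1L], nm), integer(1))
  groups <- groups[order(first_pos)]
  k <- 0L
  labels <- vapply(groups, function(g) {
    if (length(g) == 1L) g else {
      k <<- k + 1L
      paste0("F", k)
    }
  }, character(1))
  names(groups) <- labels
  structure(list(clusters = groups, threshold = threshold),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment (|r| >= ", x$threshold, "):\n", sep = "")
  for (nm in names(x$clusters))
    cat("  ", nm, ": ", paste(x$clusters[[nm]], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Aggregate variable clusters by their first principal component
#'
#' Each multi-variable cluster of standardized columns is replaced by its
#' first principal component score; the fraction of within-cluster variance
#' it explains is the leading eigenvalue of the cluster's correlation
#' matrix divided by the cluster size.  Singleton clusters pass through
#' unchanged with variance explained 1.  Since the sign of an eigenvector
#' is arbitrary, each component is oriented so its loadings sum to a
#' positive number (ties broken by the first variable's loading), making
#' factor scores deterministic across platforms.
#'
#' @param data a standardized [variable_table()] (see [standardize()]).
#' @param clusters a [cluster_variables()] result (or compatible list).
#' @return class `aggregated_factors`: list with `factors` (a
#'   [variable_table()], n x q, one column per cluster), `loadings` (named
#'   list of named numeric vectors), and `variance_explained` (named
#'   numeric in (0, 1]).  Roles of singleton variables are preserved.
#' @export
pca_aggregate <- function(data, clusters) {
  stopifnot(inherits(data, "variable_table"))
  groups <- if (inherits(clusters, "cluster_assignment")) clusters$clusters
            else if (is.list(clusters) && !is.null(clusters$clusters))
              clusters$clusters
            else clusters
  unknown <- setdiff(unlist(groups), colnames(data))
  if (length(unknown))
    stop("cluster references unknown variable(s): ",
         paste(unknown, collapse = ", "))
  x <- unclass_table(data)
  n <- nrow(x)
  q <- length(groups)
  fac <- matrix(0, n, q, dimnames = list(NULL, names(groups)))
  loadings <- vector("list", q)
  names(loadings) <- names(groups)
  varexp <- stats::setNames(numeric(q), names(groups))
  roles <- stats::setNames(rep("predictor", q), names(groups))
  old_roles <- variable_roles(data)
  for (j in seq_len(q)) {
    vars <- groups[[j]]
    if (length(vars) == 1L) {
      fac[, j] <- x[, vars]
      loadings[[j]] <- stats::setNames(1, vars)
      varexp[j] <- 1
      roles[j] <- old_roles[vars]
      next
    }
    sub <- x[, vars, drop = FALSE]
    ev <- eigen(stats::cor(sub), symmetric = TRUE)
    v <- ev$vectors[, 1L]
    s <- sum(v)
    if (s < 0 || (s == 0 && v[1L] < 0)) v <- -v
    # score on centered columns so the factor has mean exactly zero
    fac[, j] <- scale(sub, center = TRUE, scale = FALSE) %*% v
    loadings[[j]] <- stats::setNames(v, vars)
    varexp[j] <- ev$values[1L] / length(vars)
  }
  structure(list(
    factors = variable_table(fac, roles = roles),
    loadings = loadings,
    variance_explained = varexp
  ), class = "aggregated_factors")
}

#' @export
print.aggregated_factors <- function(x, ...) {
  cat("aggregated_factors:", ncol(x$factors), "factors\n")
  for (nm in names(x$loadings)) {
    l <- x$loadings[[nm]]
    cat(sprintf("  %s (%.1f%% var): %s\n", nm,
                100 * x$variance_explained[nm],
                paste(sprintf("%s=%.3f", names(l), l), collapse = ", ")))
  }
  invisible(x)
}

#' Write factor loadings as TSV
#' @param factors an [pca_aggregate()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_loadings <- function(factors, path) {
  stopifnot(inherits(factors, "aggregated_factors"))
  rows <- do.call(rbind, lapply(names(factors$loadings), function(f) {
    l <- factors$loadings[[f]]
    data.frame(factor = f, variable = names(l), loading = unname(l),
               variance_explained = unname(factors$variance_explained[f]))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' LMG relative importance of regression predictors
#'
#' Decomposes the R-squared of the linear regression of `outcome` on
#' `predictors` into one nonnegative share per predictor: the average, over
#' all orderings of the predictors, of the increase in R-squared when that
#' predictor is appended after its predecessors.  Shares always sum to the
#' full-model R-squared.  Computed exactly by enumerating predictor
#' subsets with the corresponding ordering weights, which is algebraically
#' identical to averaging over all factorial orderings but needs only
#' `2^p` regressions; `p` is capped at 12.
#'
#' @param data a [variable_table()].
#' @param outcome name of the response variable.
#' @param predictors character vector of 1 to 12 predictor names, not
#'   containing `outcome`.
#' @return named numeric vector of LMG shares, one per predictor.
#' @export
lmg_importance <- function(data, outcome, predictors) {
  stopifnot(inherits(data, "variable_table"))
  nm <- colnames(data)
  if (!outcome %in% nm) stop("unknown outcome: ", outcome)
  if (!all(predictors %in% nm))
    stop("unknown predictor(s): ",
         paste(setdiff(predictors, nm), collapse = ", "))
  if (outcome %in% predictors) stop("outcome cannot be a predictor")
  p <- length(predictors)
  if (p < 1L) stop("need at least one predictor")
  if (p > 12L)
    stop("more than 12 predictors: exact all-orderings enumeration is ",
         "intractable; subsample orderings instead (not implemented)")
  x <- unclass_table(data)
  R <- stats::cor(x[, c(predictors, outcome), drop = FALSE])
  rxy <- R[predictors, outcome]
  Rxx <- R[predictors, predictors, drop = FALSE]
  # R^2 of outcome on a subset, via the correlation normal equations
  r2 <- function(idx) {
    if (!length(idx)) return(0)
    c_s <- rxy[idx]
    drop(crossprod(c_s, solve(Rxx[idx, idx, drop = FALSE], c_s)))
  }
  # subset weight s!(p-s-1)!/p! = share of orderings placing S before j
  lw <- lgamma(seq_len(p)) + lgamma(p - seq_len(p) + 1L) - lgamma(p + 1L)
  w <- exp(lw)  # w[s+1] for |S| = s, s = 0..p-1
  shares <- stats::setNames(numeric(p), predictors)
  for (mask in 0:(2^p - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    base <- r2(idx)
    for (j in setdiff(seq_len(p), idx))
      shares[j] <- shares[j] + w[length(idx) + 1L] * (r2(c(idx, j)) - base)
  }
  shares
}
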